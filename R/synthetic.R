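# Synthetic inputs with known ground truth: every analysis stage can be run
# and scored offline, without continuum-electrostatics runs, MD engines or
# sequence databases. Each generator is fully deterministic under its seed.

.ACID_PKA_RANGES <- list(ASP = c(2.5, 5.5), GLU = c(3.5, 5.8),
                         TYR = c(9.0, 11.0), CYS = c(8.0, 10.0))
.BASE_PKA_RANGES <- list(HIS = c(5.5, 7.5), LYS = c(9.5, 11.5),
                         ARG = c(11.0, 13.0))

#' Generate a titratable system with known ground truth
#'
#' Draws a set of ionizable residues with intrinsic pKas inside
#' per-residue-type ranges and a sparse symmetric coupling matrix: each pair
#' carries an interaction with the given density, with magnitude drawn
#' uniformly and sign set by the product of the ionized charges (like charges
#' repel, `W > 0`; unlike attract). Emulates the structure of
#' continuum-electrostatics output for a protein.
#'
#' @param n_sites number of titratable sites (>= 1).
#' @param interaction_density probability that a given pair is coupled, in
#'   `[0, 1]`.
#' @param coupling_range magnitude range of couplings, kcal mol^-1.
#' @param seed integer seed; identical seeds give identical systems.
#' @param chain chain identifier stamped on the sites.
#' @return list with `sites` (a [titratable_sites()] table, the intrinsic
#'   pKas being the ground truth), `W` (an [interaction_matrix()]), and
#'   `spec` (the parameters echoed back).
#' @export
gen_titration_system <- function(n_sites = 10L, interaction_density = 0.3,
                                 coupling_range = c(0.2, 1.5), seed = 1L,
                                 chain = "A") {
  if (n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  if (interaction_density < 0 || interaction_density > 1) {
    stop("interaction_density must be in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  types <- sample(c(names(.ACID_PKA_RANGES), names(.BASE_PKA_RANGES)),
                  n_sites, replace = TRUE)
  ranges <- c(.ACID_PKA_RANGES, .BASE_PKA_RANGES)
  pka <- vapply(types, function(t) stats::runif(1, ranges[[t]][1L],
                                                ranges[[t]][2L]), 0)
  sites <- titratable_sites(chain, types, seq_len(n_sites) + 10L,
                            round(pka, 2))
  charge <- ifelse(sites$kind == "acid", -1, 1)
  ia <- integer(); ib <- integer(); e <- numeric()
  if (n_sites >= 2L) {
    for (i in seq_len(n_sites - 1L)) {
      for (j in (i + 1L):n_sites) {
        if (stats::runif(1) < interaction_density) {
          mag <- stats::runif(1, coupling_range[1L], coupling_range[2L])
          ia <- c(ia, i); ib <- c(ib, j)
          e <- c(e, round(charge[i] * charge[j] * mag, 4))
        }
      }
    }
  }
  W <- interaction_matrix(sites$site_id[ia], sites$site_id[ib], e)
  list(sites = sites, W = W,
       spec = list(seed = as.integer(seed), n_sites = n_sites,
                   interaction_density = interaction_density,
                   coupling_range = coupling_range))
}

# clamp Gaussian jitter at 2 sd so programmed plateaus never stray across
# the rupture-detector hysteresis thresholds
.clamped_noise <- function(n, sd) {
  pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
}

#' Generate a trajectory with a programmed hydrogen-bond rupture
#'
#' Emulates the barrel-integrity traces of an activation simulation: a
#' donor-acceptor pair (His ND1 / Tyr HH) sits at a ~0.2 nm bound distance
#' with clamped Gaussian jitter, jumps to a broken plateau (drawn from
#' 0.5 / 0.7 nm unless given) at `rupture_frame`, and optionally re-forms at
#' `reform_frame`. Water oxygens are relocated per frame so that roughly
#' `contacts_pre` of them sit within 0.5 nm of the hydroxyl hydrogen before
#' the rupture and `contacts_post` after it (solvent influx accompanies
#' barrel opening). Alpha carbons carry per-residue jitter amplitudes, giving
#' a known fluctuation profile and matching pseudo B-factors.
#'
#' @param n_frames number of frames (>= 2).
#' @param rupture_frame 1-based frame of the rupture, or `NA` for a stable
#'   trajectory.
#' @param reform_frame optional 1-based frame at which the bond re-forms
#'   (`NA` = stays broken).
#' @param plateau broken-state distance, nm; default drawn from `c(0.5, 0.7)`.
#' @param baseline bound-state distance, nm.
#' @param noise_sd jitter of the monitored distance, nm.
#' @param contacts_pre,contacts_post programmed water-oxygen counts within
#'   0.5 nm of the hydroxyl hydrogen before/after rupture.
#' @param n_waters total water-oxygen roster (constant across frames).
#' @param n_residues alpha carbons in the toy protein scaffold.
#' @param seed integer seed.
#' @return list with `trajectory` (an [md_trajectory()]), `ground_truth`
#'   (programmed rupture/reform frames, reversibility flag, plateau, contact
#'   levels, per-residue jitter `sigma` and pseudo `bfactor`s), and `spec`.
#' @export
gen_trajectory <- function(n_frames = 1000L, rupture_frame = 600L,
                           reform_frame = NA, plateau = NULL,
                           baseline = 0.2, noise_sd = 0.015,
                           contacts_pre = 5L, contacts_post = 12L,
                           n_waters = 24L, n_residues = 30L, seed = 1L) {
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (!is.na(rupture_frame) &&
      (rupture_frame < 1L || rupture_frame > n_frames)) {
    stop("rupture_frame must lie in [1, n_frames] or be NA", call. = FALSE)
  }
  if (!is.na(reform_frame) && is.na(rupture_frame)) {
    stop("reform_frame given without rupture_frame", call. = FALSE)
  }
  if (!is.na(reform_frame) && reform_frame <= rupture_frame) {
    stop("reform_frame must come after rupture_frame", call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (is.null(plateau)) plateau <- sample(c(0.5, 0.7), 1L)

  broken <- rep(FALSE, n_frames)
  if (!is.na(rupture_frame)) {
    broken[rupture_frame:n_frames] <- TRUE
    if (!is.na(reform_frame)) broken[reform_frame:n_frames] <- FALSE
  }
  dist_nm <- ifelse(broken, plateau, baseline) +
    .clamped_noise(n_frames, noise_sd)

  # scaffold: ND1 donor fixed near the origin, hydroxyl H displaced along x
  # by the programmed distance; CA ring of radius 1 nm around them
  sigma <- stats::runif(n_residues, 0.005, 0.05)  # per-residue jitter, nm
  theta <- 2 * pi * seq_len(n_residues) / n_residues
  ca0 <- cbind(cos(theta), sin(theta), 0)

  prot <- data.frame(
    chain = "A",
    resname = c("HIS", "TYR", rep("GLY", n_residues)),
    resno = c(121L, 214L, seq_len(n_residues) + 300L),
    atom = c("ND1", "HH", rep("CA", n_residues)),
    stringsAsFactors = FALSE
  )
  wat <- data.frame(
    chain = "W", resname = "HOH",
    resno = seq_len(n_waters) + 1000L, atom = "OW",
    stringsAsFactors = FALSE
  )
  atoms <- rbind(prot, wat)
  natoms <- nrow(atoms)
  xyz <- matrix(NA_real_, n_frames, 3L * natoms)

  in_shell_n <- pmin(n_waters, pmax(0L, ifelse(broken, contacts_post,
                                               contacts_pre) +
                                      sample(c(-1L, 0L, 1L), n_frames,
                                             replace = TRUE,
                                             prob = c(.25, .5, .25))))
  for (f in seq_len(n_frames)) {
    nd1 <- c(0, 0, 0)
    hh <- c(dist_nm[f], 0, 0)
    ca <- ca0 + matrix(stats::rnorm(3L * n_residues, 0,
                                    rep(sigma, 3L) / sqrt(3)),
                       n_residues, 3L)
    k <- in_shell_n[f]
    # waters in the 0.5 nm shell of HH (placed at 0.25-0.45 nm), the rest
    # parked 1.5-2.5 nm away
    r <- c(stats::runif(k, 0.25, 0.45),
           stats::runif(n_waters - k, 1.5, 2.5))
    u <- matrix(stats::rnorm(3L * n_waters), n_waters, 3L)
    u <- u / sqrt(rowSums(u^2))
    wxyz <- sweep(u * r, 2L, hh, "+")
    co <- rbind(nd1, hh, ca, wxyz)
    xyz[f, ] <- as.vector(t(co))
  }
  traj <- md_trajectory(atoms, xyz)
  # pseudo temperature factors from the programmed jitter: B = 8 pi^2/3 <u^2>
  bfac <- 8 * pi^2 / 3 * (sigma * 10)^2  # A^2
  gt <- list(rupture_frame = if (is.na(rupture_frame)) NA_integer_
             else as.integer(rupture_frame),
             reform_frame = if (is.na(reform_frame)) NA_integer_
             else as.integer(reform_frame),
             reformed = !is.na(reform_frame),
             has_rupture = !is.na(rupture_frame),
             plateau = plateau, baseline = baseline,
             contacts_pre = contacts_pre, contacts_post = contacts_post,
             sigma = sigma, bfactor = bfac,
             resno = prot$resno[-(1:2)][seq_len(n_residues)])
  list(trajectory = traj, ground_truth = gt,
       spec = list(seed = as.integer(seed), n_frames = n_frames,
                   rupture_frame = rupture_frame,
                   reform_frame = reform_frame, plateau = plateau,
                   noise_sd = noise_sd, contacts_pre = contacts_pre,
                   contacts_post = contacts_post, n_waters = n_waters,
                   n_residues = n_residues))
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a grouped alignment with programmed contrast columns
#'
#' Builds a plant-like / diatom-like alignment around a gapless reference:
#' programmed positions carry a known classification (`conserved_all`,
#' `group_specific_substitution` with an ionizable substitute, or
#' `non_ionizable_substitution`, e.g. an aspartate replaced by leucine in the
#' diatom group), while background columns mutate independently at a stated
#' per-column rate. The ground-truth table is sufficient to score
#' [group_contrast()] recovery.
#'
#' @param n_columns alignment width.
#' @param n_plants,n_diatoms sequences per group (>= 1 each).
#' @param conserved_positions reference positions forced identical in all
#'   sequences (histidine, emulating an H168-like column).
#' @param ionizable_sub_positions positions with aspartate in plants and
#'   glutamate in diatoms (group-specific but still ionizable).
#' @param nonionizable_sub_positions positions with aspartate in plants and
#'   leucine in diatoms.
#' @param mutation_rate background per-sequence per-column substitution rate.
#' @param seed integer seed.
#' @return list with `alignment` (a [grouped_alignment()], reference
#'   `plant_1`), `ground_truth` (data.frame of programmed positions and
#'   classes) and `spec`.
#' @export
gen_alignment <- function(n_columns = 120L, n_plants = 3L, n_diatoms = 2L,
                          conserved_positions = c(40L),
                          ionizable_sub_positions = c(70L),
                          nonionizable_sub_positions = c(20L, 55L, 90L,
                                                         105L),
                          mutation_rate = 0.02, seed = 1L) {
  if (n_plants < 1L || n_diatoms < 1L) {
    stop("need at least one sequence per group", call. = FALSE)
  }
  if (n_columns < 1L) stop("alignment must have >= 1 column", call. = FALSE)
  prog <- c(conserved_positions, ionizable_sub_positions,
            nonionizable_sub_positions)
  if (anyDuplicated(prog)) {
    stop("programmed positions overlap", call. = FALSE)
  }
  if (length(prog) && max(prog) > n_columns) {
    stop("programmed positions exceed n_columns", call. = FALSE)
  }
  set.seed(as.integer(seed))
  ref <- sample(.AA20, n_columns, replace = TRUE)
  ref[conserved_positions] <- "H"
  ref[ionizable_sub_positions] <- "D"
  ref[nonionizable_sub_positions] <- "D"

  ids <- c(paste0("plant_", seq_len(n_plants)),
           paste0("diatom_", seq_len(n_diatoms)))
  groups <- stats::setNames(rep(c("plants", "diatoms"),
                                c(n_plants, n_diatoms)), ids)
  background <- setdiff(seq_len(n_columns), prog)
  seqs <- vapply(ids, function(id) {
    s <- ref
    if (groups[[id]] == "diatoms") {
      s[ionizable_sub_positions] <- "E"
      s[nonionizable_sub_positions] <- "L"
    }
    mut <- background[stats::runif(length(background)) < mutation_rate]
    if (length(mut)) {
      s[mut] <- vapply(s[mut], function(orig)
        sample(setdiff(.AA20, orig), 1L), "")
    }
    paste(s, collapse = "")
  }, "")
  # keep the reference itself unmutated so its numbering is the ground truth
  seqs[["plant_1"]] <- paste(ref, collapse = "")
  aln <- grouped_alignment(seqs, groups, "plant_1")
  gt <- data.frame(
    reference_position = c(conserved_positions, ionizable_sub_positions,
                           nonionizable_sub_positions),
    class = rep(c("conserved_all", "group_specific_substitution",
                  "non_ionizable_substitution"),
                c(length(conserved_positions),
                  length(ionizable_sub_positions),
                  length(nonionizable_sub_positions))),
    plant_residue = ref[c(conserved_positions, ionizable_sub_positions,
                          nonionizable_sub_positions)],
    diatom_residue = c(ref[conserved_positions],
                       rep("E", length(ionizable_sub_positions)),
                       rep("L", length(nonionizable_sub_positions))),
    stringsAsFactors = FALSE
  )
  gt <- gt[order(gt$reference_position), , drop = FALSE]
  rownames(gt) <- NULL
  list(alignment = aln, ground_truth = gt,
       spec = list(seed = as.integer(seed), n_columns = n_columns,
                   n_plants = n_plants, n_diatoms = n_diatoms,
                   mutation_rate = mutation_rate))
}

#' Packaged reference tables
#'
#' Small fixture tables shipped with the package: `"table1_pka"`, the five
#' activation-candidate residues of the inactive (pH 7) VDE structure with
#' their computed pKas and standard deviations; `"table2_activity"`, the
#' relative de-epoxidase activity (% of wild type, with SD, n = 5) of the
#' corresponding point and combination mutants, for reporting.
#'
#' @param name `"table1_pka"` or `"table2_activity"`.
#' @return `table1_pka`: a [titratable_sites()] table (5 rows);
#'   `table2_activity`: data.frame with `variant`, `activity_pct_wt`, `sd`.
#' @export
#' @examples
#' load_fixture("table1_pka")
load_fixture <- function(name) {
  files <- c(table1_pka = "table1_vde_ph7.tsv",
             table2_activity = "table2_activity.tsv")
  if (!name %in% names(files)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(files), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", files[[name]], package = "vdeswitch",
                      mustWork = TRUE)
  if (name == "table1_pka") read_pka_table(path)
  else utils::read.delim(path, stringsAsFactors = FALSE)
}

# ---- writers emitting the exact formats the analysis modules read ----

#' Write a pKa table in the pipeline TSV dialect
#' @param sites a [titratable_sites()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pka_table <- function(sites, path) {
  df <- sites[, c("chain", "residue_name", "residue_number", "pKa", "std")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interaction-energy table in the pipeline TSV dialect
#' @param W an [interaction_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(W, path) {
  p <- W$pairs
  sa <- strsplit(p$site_a, ":", fixed = TRUE)
  sb <- strsplit(p$site_b, ":", fixed = TRUE)
  df <- data.frame(
    chainA = vapply(sa, `[`, "", 1L), resA = vapply(sa, `[`, "", 2L),
    numA = vapply(sa, `[`, "", 3L),
    chainB = vapply(sb, `[`, "", 1L), resB = vapply(sb, `[`, "", 2L),
    numB = vapply(sb, `[`, "", 3L),
    energy_kcal = p$mean_energy, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a grouped alignment as FASTA plus group sidecar
#' @param aln a [grouped_alignment()].
#' @param fasta_path output FASTA path.
#' @param groups_path output TSV path (`sequence_id group`).
#' @return `fasta_path`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, groups_path) {
  con <- file(fasta_path, "w")
  for (id in names(aln$sequences)) {
    writeLines(c(paste0(">", id), aln$sequences[[id]]), con)
  }
  close(con)
  utils::write.table(
    data.frame(sequence_id = names(aln$sequences),
               group = as.character(aln$groups)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
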