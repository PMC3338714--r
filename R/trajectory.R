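# Structural-integrity metrics from trajectory frames: the hydrogen bond at
# the end of the lipocalin barrel (monitored as a donor-N to hydroxyl-H
# distance), solvent penetration of the hydrophobic core, cavity volume, and
# per-residue fluctuation (RMSF) against crystallographic B-factors.
#
# Coordinates are normalized to nm internally; PDB input (angstroms) is
# converted on load.

.SOLVENT_RESNAMES <- c("HOH", "WAT", "SOL", "TIP3", "TIP", "SPC")

# van der Waals radii by element, nm (Bondi); fallback 0.17
.VDW_NM <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
             P = 0.180)

#' Construct a trajectory object
#'
#' Frame-wise coordinates over a fixed atom roster. Coordinates are stored in
#' nm; one row of `xyz` per frame, columns `(x1, y1, z1, x2, ...)` as in the
#' bio3d convention.
#'
#' @param atoms data.frame with columns `chain`, `resname`, `resno`, `atom`
#'   (atom name); water is recognized by residue name (HOH/WAT/SOL/TIP3/SPC).
#' @param xyz numeric matrix, `n_frames` x `3 * nrow(atoms)`, in nm.
#' @param time_per_frame optional frame spacing, ps.
#' @return an `md_trajectory` object.
#' @export
md_trajectory <- function(atoms, xyz, time_per_frame = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("xyz must have 3 columns per atom (", 3L * nrow(atoms),
         "), got ", ncol(xyz), call. = FALSE)
  }
  atoms$is_solvent <- toupper(atoms$resname) %in% .SOLVENT_RESNAMES
  structure(list(atoms = atoms, xyz = xyz, n_frames = nrow(xyz),
                 time_per_frame = time_per_frame),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("Trajectory:", x$n_frames, "frame(s),", nrow(x$atoms), "atom(s) (",
      sum(!x$atoms$is_solvent), "protein /", sum(x$atoms$is_solvent),
      "solvent )\n")
  invisible(x)
}

#' Read a multi-model PDB as a trajectory
#'
#' Parses MODEL/ENDMDL blocks with [bio3d::read.pdb()] and converts the
#' coordinates from angstroms to nm. All models must share one atom roster.
#'
#' @param path path to a PDB file (single- or multi-model).
#' @param time_per_frame optional frame spacing, ps.
#' @return an `md_trajectory`.
#' @export
read_trajectory <- function(path, time_per_frame = NULL) {
  if (!file.exists(path)) {
    stop("trajectory file not found: ", path, call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    resname = pdb$atom$resid,
    resno = pdb$atom$resno,
    atom = pdb$atom$elety,
    stringsAsFactors = FALSE
  )
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  md_trajectory(atoms, xyz / 10, time_per_frame = time_per_frame)
}

#' Write a trajectory as multi-model PDB
#'
#' Emits standard fixed-column ATOM/HETATM records (solvent as HETATM), one
#' MODEL block per frame, coordinates converted from nm to angstroms. The
#' output round-trips through [read_trajectory()].
#'
#' @param traj an `md_trajectory`.
#' @param path output file path.
#' @param bfactor optional per-atom B-factor vector written to the
#'   temperature-factor column (recycled; default 0).
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, bfactor = 0) {
  a <- traj$atoms
  n <- nrow(a)
  bfactor <- rep_len(bfactor, n)
  rec <- ifelse(a$is_solvent, "HETATM", "ATOM  ")
  # PDB atom-name column convention: names of <= 3 chars start in column 14
  aname <- ifelse(nchar(a$atom) >= 4L, sprintf("%-4s", a$atom),
                  sprintf(" %-3s", a$atom))
  elem <- toupper(substr(a$atom, 1L, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    co <- matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE) * 10  # nm -> A
    lines <- sprintf(
      "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, seq_len(n), aname, a$resname, a$chain, a$resno,
      co[, 1L], co[, 2L], co[, 3L], 1.0, bfactor, elem)
    writeLines(c(sprintf("MODEL     %4d", f), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

# Resolve an atom selector "chain:resno:atomname" (or a list with fields
# chain, resno, atom) to a single atom index; errors name the selector.
.resolve_selector <- function(traj, sel) {
  if (is.character(sel) && length(sel) == 1L) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 3L) {
      stop("selector '", sel, "' must have the form chain:resno:atom",
           call. = FALSE)
    }
    sel <- list(chain = parts[1L], resno = as.integer(parts[2L]),
                atom = parts[3L])
  }
  a <- traj$atoms
  idx <- which(a$chain == sel$chain & a$resno == sel$resno &
                 a$atom == sel$atom)
  name <- paste(sel$chain, sel$resno, sel$atom, sep = ":")
  if (length(idx) == 0L) {
    stop("selector '", name, "' matches no atom", call. = FALSE)
  }
  if (length(idx) > 1L) {
    stop("selector '", name, "' is ambiguous (", length(idx), " atoms)",
         call. = FALSE)
  }
  idx
}

.atom_coords <- function(traj, idx) {
  traj$xyz[, c(3L * (idx - 1L) + 1L, 3L * (idx - 1L) + 2L, 3L * idx),
           drop = FALSE]
}

#' Per-frame distance between two atoms
#'
#' The hydrogen-bond monitor of the pipeline: e.g. the distance between the
#' His ND1 donor nitrogen and the Tyr hydroxyl hydrogen guarding the barrel.
#'
#' @param traj an `md_trajectory`.
#' @param atom_a,atom_b selectors, either `"chain:resno:atomname"` strings
#'   (e.g. `"A:121:ND1"`) or lists with fields `chain`, `resno`, `atom`; each
#'   must resolve to exactly one atom.
#' @return numeric vector of per-frame distances, nm.
#' @export
atom_distance_series <- function(traj, atom_a, atom_b) {
  ia <- .resolve_selector(traj, atom_a)
  ib <- .resolve_selector(traj, atom_b)
  sqrt(rowSums((.atom_coords(traj, ia) - .atom_coords(traj, ib))^2))
}

#' Per-frame solvent contacts around an atom
#'
#' Counts solvent atoms within a radius of a center atom, per frame; by
#' default only water oxygens are counted (set `oxygens_only = FALSE` to
#' count every solvent atom).
#'
#' @param traj an `md_trajectory`.
#' @param center atom selector (see [atom_distance_series()]).
#' @param radius contact radius, nm (>= 0); default 0.5.
#' @param oxygens_only count only solvent atoms whose name starts with O.
#' @return integer vector of per-frame counts.
#' @export
solvent_contact_series <- function(traj, center, radius = 0.5,
                                   oxygens_only = TRUE) {
  if (!is.finite(radius) || radius < 0) {
    stop("radius must be >= 0", call. = FALSE)
  }
  ic <- .resolve_selector(traj, center)
  sol <- which(traj$atoms$is_solvent)
  if (oxygens_only) {
    sol <- sol[startsWith(toupper(traj$atoms$atom[sol]), "O")]
  }
  if (!length(sol)) return(integer(traj$n_frames))
  cc <- .atom_coords(traj, ic)
  counts <- integer(traj$n_frames)
  cols <- as.vector(rbind(3L * (sol - 1L) + 1L, 3L * (sol - 1L) + 2L,
                          3L * sol))
  S <- traj$xyz[, cols, drop = FALSE]
  nsol <- length(sol)
  dx <- S[, seq(1L, 3L * nsol, by = 3L), drop = FALSE] - cc[, 1L]
  dy <- S[, seq(2L, 3L * nsol, by = 3L), drop = FALSE] - cc[, 2L]
  dz <- S[, seq(3L, 3L * nsol, by = 3L), drop = FALSE] - cc[, 3L]
  rowSums(dx^2 + dy^2 + dz^2 <= radius^2)
}

#' Detect hydrogen-bond rupture events in a distance series
#'
#' Hysteresis event detector: an event opens when the monitored distance
#' stays above `broken_thr` for at least `dwell` consecutive frames, and
#' closes (bond re-formed) when the distance stays below `formed_thr` for at
#' least `dwell` frames. Defaults separate a ~0.2 nm bound state from
#' 0.5-0.7 nm broken plateaus.
#'
#' @param series per-frame distances, nm.
#' @param formed_thr,broken_thr hysteresis thresholds, nm
#'   (`formed_thr < broken_thr`).
#' @param dwell minimum run length in frames.
#' @return data.frame with one row per event: `onset_frame` (first frame of
#'   the sustained break), `end_frame` (first frame of the sustained
#'   re-formation, `NA` while open), `reformed`.
#' @export
detect_rupture_events <- function(series, formed_thr = 0.25,
                                  broken_thr = 0.45, dwell = 50L) {
  if (formed_thr >= broken_thr) {
    stop("formed_thr must be < broken_thr (hysteresis)", call. = FALSE)
  }
  if (dwell < 1L) stop("dwell must be >= 1", call. = FALSE)
  lab <- ifelse(series > broken_thr, "B",
                ifelse(series < formed_thr, "F", "M"))
  r <- rle(lab)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  onset <- integer(); end <- integer(); reformed <- logical()
  open <- FALSE
  for (i in seq_along(r$values)) {
    if (!open && r$values[i] == "B" && r$lengths[i] >= dwell) {
      onset <- c(onset, start[i]); open <- TRUE
    } else if (open && r$values[i] == "F" && r$lengths[i] >= dwell) {
      end <- c(end, start[i]); reformed <- c(reformed, TRUE); open <- FALSE
    }
  }
  if (open) { end <- c(end, NA_integer_); reformed <- c(reformed, FALSE) }
  data.frame(onset_frame = onset, end_frame = end, reformed = reformed)
}

#' Grid-based cavity volume
#'
#' Probe-accessible volume of a cavity: a regular grid is laid over a
#' bounding box, cells overlapped by any protein-atom sphere (van der Waals
#' radius plus a water-sized probe of 0.14 nm) are blocked, and the free
#' cells 6-connected to a seed cell are flood-filled. The volume is the
#' filled-cell count times the cell volume. A coarse but convergent stand-in
#' for pocket-detection tools when only a before/after volume is needed.
#'
#' @param atoms data.frame with `x`, `y`, `z` (nm) and `atom` (atom name,
#'   first letter read as the element); pass protein atoms only. May have 0
#'   rows (empty box).
#' @param box numeric length-6: `xmin, xmax, ymin, ymax, zmin, zmax`, nm.
#' @param seed_point numeric length-3 inside the box and outside every atom.
#' @param grid_spacing cell edge, nm (> 0); default 0.05.
#' @param probe_radius probe radius added to each vdW radius, nm.
#' @return cavity volume in nm^3.
#' @export
cavity_volume <- function(atoms, box, seed_point, grid_spacing = 0.05,
                          probe_radius = 0.14) {
  stopifnot(length(box) == 6L, length(seed_point) == 3L)
  if (grid_spacing <= 0) stop("grid_spacing must be > 0", call. = FALSE)
  lo <- box[c(1L, 3L, 5L)]; hi <- box[c(2L, 4L, 6L)]
  if (any(seed_point < lo | seed_point > hi)) {
    stop("seed point lies outside the probe region", call. = FALSE)
  }
  nd <- pmax(1L, floor((hi - lo) / grid_spacing))
  centers <- lapply(1:3, function(d) lo[d] + (seq_len(nd[d]) - 0.5) *
                      grid_spacing)
  free <- array(TRUE, dim = nd)
  if (nrow(atoms)) {
    rad <- .VDW_NM[toupper(substr(atoms$atom, 1L, 1L))]
    rad[is.na(rad)] <- 0.17
    rad <- rad + probe_radius
    for (i in seq_len(nrow(atoms))) {
      p <- c(atoms$x[i], atoms$y[i], atoms$z[i])
      rg <- lapply(1:3, function(d) {
        which(abs(centers[[d]] - p[d]) <= rad[i])
      })
      if (any(lengths(rg) == 0L)) next
      dx2 <- (centers[[1L]][rg[[1L]]] - p[1L])^2
      dy2 <- (centers[[2L]][rg[[2L]]] - p[2L])^2
      dz2 <- (centers[[3L]][rg[[3L]]] - p[3L])^2
      blocked <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rad[i]^2
      free[rg[[1L]], rg[[2L]], rg[[3L]]] <-
        free[rg[[1L]], rg[[2L]], rg[[3L]]] & !blocked
    }
  }
  seed_idx <- pmin(pmax(1L, 1L + floor((seed_point - lo) / grid_spacing)),
                   nd)
  if (nrow(atoms)) {
    d2seed <- (atoms$x - seed_point[1L])^2 + (atoms$y - seed_point[2L])^2 +
      (atoms$z - seed_point[3L])^2
    if (any(d2seed <= (rad - probe_radius)^2)) {
      stop("seed point lies inside an atom", call. = FALSE)
    }
  }
  # seed cell blocked (but the point itself probe-accessible nowhere):
  # nothing to flood, the cavity has zero probe-accessible volume
  if (!free[seed_idx[1L], seed_idx[2L], seed_idx[3L]]) return(0)
  # flood fill (6-connectivity) by iterated dilation masked with free cells
  filled <- array(FALSE, dim = nd)
  filled[seed_idx[1L], seed_idx[2L], seed_idx[3L]] <- TRUE
  repeat {
    grown <- filled
    grown[-1L, , ] <- grown[-1L, , ] | filled[-nd[1L], , ]
    grown[-nd[1L], , ] <- grown[-nd[1L], , ] | filled[-1L, , ]
    grown[, -1L, ] <- grown[, -1L, ] | filled[, -nd[2L], ]
    grown[, -nd[2L], ] <- grown[, -nd[2L], ] | filled[, -1L, ]
    grown[, , -1L] <- grown[, , -1L] | filled[, , -nd[3L]]
    grown[, , -nd[3L]] <- grown[, , -nd[3L]] | filled[, , -1L]
    grown <- grown & free
    if (identical(grown, filled)) break
    filled <- grown
  }
  sum(filled) * grid_spacing^3
}

#' Per-residue RMSF of alpha carbons
#'
#' Root-mean-square fluctuation of each CA atom about its time-mean position,
#' after optional rigid-body superposition of every frame onto the first
#' (least-squares fit on the CA set, removing global rotation/translation).
#'
#' @param traj an `md_trajectory` with at least 2 frames.
#' @param atom_name atom name defining the selection (default `"CA"`).
#' @param fit superpose frames onto the first frame before computing
#'   fluctuations (default TRUE).
#' @return data.frame with `chain`, `resno`, `rmsf` (nm).
#' @export
rmsf <- function(traj, atom_name = "CA", fit = TRUE) {
  if (traj$n_frames < 2L) {
    stop("RMSF is undefined for a single frame", call. = FALSE)
  }
  sel <- which(traj$atoms$atom == atom_name & !traj$atoms$is_solvent)
  if (!length(sel)) {
    stop("no atoms named '", atom_name, "' in trajectory", call. = FALSE)
  }
  cols <- as.vector(rbind(3L * (sel - 1L) + 1L, 3L * (sel - 1L) + 2L,
                          3L * sel))
  xyz <- traj$xyz
  if (fit && length(sel) >= 3L) {
    xyz <- bio3d::fit.xyz(fixed = xyz[1L, ], mobile = xyz,
                          fixed.inds = cols, mobile.inds = cols)
  }
  X <- xyz[, cols, drop = FALSE]
  mu <- colMeans(X)
  dev2 <- sweep(X, 2L, mu)^2
  nsel <- length(sel)
  per_atom <- sqrt(colMeans(
    dev2[, seq(1L, 3L * nsel, 3L), drop = FALSE] +
    dev2[, seq(2L, 3L * nsel, 3L), drop = FALSE] +
    dev2[, seq(3L, 3L * nsel, 3L), drop = FALSE]))
  data.frame(chain = traj$atoms$chain[sel], resno = traj$atoms$resno[sel],
             rmsf = per_atom, stringsAsFactors = FALSE)
}

#' Correlation between simulated RMSF and crystallographic B-factors
#'
#' Pearson correlation between per-residue fluctuation and the temperature
#' factors of the reference structure, plus both series standardized
#' (deviation from mean in units of overall standard deviation).
#'
#' @param rmsf_values per-residue RMSF values.
#' @param bfactors per-residue temperature factors, same length (>= 3).
#' @return list with `r` (Pearson coefficient; `NA` flagged `"undefined"`
#'   when either series has zero variance), `rmsf_z`, `bfactor_z`.
#' @export
rmsf_bfactor_correlation <- function(rmsf_values, bfactors) {
  if (length(rmsf_values) != length(bfactors) || length(bfactors) < 3L) {
    stop("rmsf and B-factor series must have equal length >= 3",
         call. = FALSE)
  }
  if (stats::sd(rmsf_values) == 0 || stats::sd(bfactors) == 0) {
    return(list(r = structure(NA_real_, flag = "undefined"),
                rmsf_z = rep(NA_real_, length(rmsf_values)),
                bfactor_z = rep(NA_real_, length(bfactors))))
  }
  list(r = stats::cor(rmsf_values, bfactors),
       rmsf_z = as.numeric(scale(rmsf_values)),
       bfactor_z = as.numeric(scale(bfactors)))
}
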