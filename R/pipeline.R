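# Pipeline orchestration: validated run configuration, per-stage commands
# that read the declared file formats and write JSON + TSV/DOT reports, and
# a one-shot replay of the whole analysis. Every command is deterministic
# given (inputs, config, seed) and echoes its effective configuration into
# the report for provenance.

.default_config <- function() {
  list(
    pka_window = c(5.0, 7.0),
    pH_from = 7.0, pH_to = 5.2,
    network_cutoff = 0.2,
    display_threshold = 0.4,
    formed_thr = 0.25, broken_thr = 0.45, dwell = 50L,
    solvent_radius = 0.5,
    grid_spacing = 0.05,
    conservation_threshold = 1.0,
    seed = 1L
  )
}

#' Build a validated run configuration
#'
#' Merges user overrides into the pipeline defaults (pKa window `[5, 7]`,
#' pH transition 7 -> 5.2, network cutoff 0.2 and display threshold
#' 0.4 kcal mol^-1, rupture hysteresis 0.25/0.45 nm with 50-frame dwell,
#' solvent radius 0.5 nm, grid spacing 0.05 nm, strict conservation) and
#' validates the result before any stage runs.
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- .default_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  if (cfg$pka_window[1L] > cfg$pka_window[2L]) {
    stop("pka_window low must be <= high", call. = FALSE)
  }
  if (cfg$formed_thr >= cfg$broken_thr) {
    stop("formed_thr must be < broken_thr", call. = FALSE)
  }
  if (cfg$network_cutoff < 0 || cfg$display_threshold < cfg$network_cutoff) {
    stop("need 0 <= network_cutoff <= display_threshold", call. = FALSE)
  }
  if (cfg$solvent_radius <= 0 || cfg$grid_spacing <= 0) {
    stop("solvent_radius and grid_spacing must be > 0", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

.report <- function(stage, cfg, results) {
  list(stage = stage,
       tool = list(package = "vdeswitch",
                   version = as.character(utils::packageVersion("vdeswitch"))),
       config = unclass(cfg),
       results = results)
}

.write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Candidate-selection command
#'
#' Reads a pKa table, applies the activation-window selection and writes a
#' JSON report plus a TSV of the selected residues.
#'
#' @param pka_path pKa table (TSV dialect of [read_pka_table()]).
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @return the report list, invisibly; files `candidates.json` and
#'   `candidates.tsv` appear in `out_dir`.
#' @export
cmd_select <- function(pka_path, out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sites <- read_pka_table(pka_path)
  cs <- select_candidates(sites, window = config$pka_window,
                          pH_from = config$pH_from, pH_to = config$pH_to)
  rep <- .report("select", config, list(
    n_input_sites = nrow(sites),
    n_selected = nrow(cs$selected),
    window = cs$window,
    pH_from = cs$pH_from, pH_to = cs$pH_to,
    selected = cs$selected
  ))
  .write_report(rep, file.path(out_dir, "candidates.json"))
  utils::write.table(cs$selected, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}

#' Electrostatic node-map command
#'
#' Builds the interaction graph from an energy table, computes density,
#' k-cores and hubs, and writes the JSON report, the DOT rendering and a TSV
#' of core numbers. The report carries the density both of the analysis graph
#' (build cutoff) and of the displayed graph (display threshold).
#'
#' @param energy_path interaction-energy TSV
#'   (see [read_interaction_table()]).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param min_core hub extraction level (default 4).
#' @return the report list, invisibly; writes `netmap.json`, `netmap.dot`,
#'   `cores.tsv`.
#' @export
cmd_netmap <- function(energy_path, out_dir, config = run_config(),
                       min_core = 4L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- read_interaction_table(energy_path)
  g <- build_graph(rec, cutoff = config$network_cutoff)
  g_disp <- build_graph(rec, cutoff = config$display_threshold)
  cores <- k_core_decomposition(g)
  hubs <- interaction_hubs(g, min_core = min_core, cores = cores)
  dot <- export_dot(g, display_threshold = config$display_threshold)
  rep <- .report("netmap", config, list(
    n_nodes = nrow(g$nodes), n_edges = nrow(g$edges),
    density_analysis = as.numeric(graph_density(g)),
    n_nodes_display = nrow(g_disp$nodes),
    n_edges_display = nrow(g_disp$edges),
    density_display = as.numeric(graph_density(g_disp)),
    max_core = if (nrow(cores$nodes)) max(cores$nodes$core) else 0L,
    cores = cores$nodes,
    hubs = lapply(hubs, function(h) h$label)
  ))
  .write_report(rep, file.path(out_dir, "netmap.json"))
  writeLines(dot, file.path(out_dir, "netmap.dot"))
  utils::write.table(cores$nodes, file.path(out_dir, "cores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}

#' Trajectory-integrity command
#'
#' Reads a multi-model PDB, monitors a donor/acceptor distance, counts
#' solvent contacts, detects rupture events, and writes the per-frame series
#' (TSV) and the event report (JSON).
#'
#' @param traj_path multi-model PDB.
#' @param out_dir output directory.
#' @param atom_a,atom_b monitored pair selectors
#'   (default `"A:121:ND1"` / `"A:214:HH"`).
#' @param config a [run_config()].
#' @return the report list, invisibly; writes `series.tsv`, `traj.json`.
#' @export
cmd_traj <- function(traj_path, out_dir,
                     atom_a = "A:121:ND1", atom_b = "A:214:HH",
                     config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- read_trajectory(traj_path)
  d <- atom_distance_series(traj, atom_a, atom_b)
  contacts <- solvent_contact_series(traj, atom_b,
                                     radius = config$solvent_radius)
  events <- detect_rupture_events(d, formed_thr = config$formed_thr,
                                  broken_thr = config$broken_thr,
                                  dwell = config$dwell)
  series <- data.frame(frame = seq_along(d), distance_nm = d,
                       solvent_contacts = contacts)
  rep <- .report("traj", config, list(
    n_frames = traj$n_frames,
    monitored_pair = paste(atom_a, atom_b, sep = " / "),
    mean_distance_nm = mean(d),
    mean_contacts = mean(contacts),
    n_events = nrow(events),
    events = events
  ))
  utils::write.table(series, file.path(out_dir, "series.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_report(rep, file.path(out_dir, "traj.json"))
  invisible(rep)
}

#' Conservation-contrast command
#'
#' Reads an alignment plus group sidecar, computes per-column conservation,
#' the strict consensus and the group contrast at the requested reference
#' positions, and writes `conservation.tsv` + `conserve.json`.
#'
#' @param alignment_path aligned FASTA or Clustal file.
#' @param groups_path group sidecar TSV (`sequence_id group`).
#' @param positions reference residue numbers to contrast.
#' @param out_dir output directory.
#' @param reference_id reference sequence id (default: first sequence).
#' @param config a [run_config()].
#' @return the report list, invisibly.
#' @export
cmd_conserve <- function(alignment_path, groups_path, positions, out_dir,
                         reference_id = NULL, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_alignment(alignment_path, groups_path,
                        reference_id = reference_id)
  cons <- column_conservation(aln)
  cns <- consensus(aln, identity_threshold = config$conservation_threshold)
  mp <- map_to_reference(aln)
  contrast <- group_contrast(aln, positions,
                             threshold = config$conservation_threshold)
  percol <- data.frame(column = seq_len(aln$width),
                       reference_position = mp$column_to_residue,
                       conservation = cons,
                       consensus_char = strsplit(cns, "")[[1L]])
  rep <- .report("conserve", config, list(
    n_sequences = length(aln$sequences),
    n_columns = aln$width,
    groups = as.list(table(aln$groups)),
    mean_conservation = mean(cons, na.rm = TRUE),
    contrasts = contrast$contrasts,
    skipped_positions = contrast$skipped
  ))
  utils::write.table(percol, file.path(out_dir, "conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_report(rep, file.path(out_dir, "conserve.json"))
  invisible(rep)
}

#' Generate synthetic inputs on disk
#'
#' Runs the three generators under one seed and writes their outputs in
#' exactly the formats the analysis commands read: pKa TSV, interaction TSV,
#' multi-model PDB, FASTA + group TSV, plus a ground-truth JSON.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_frames trajectory length (default 800).
#' @return list of generated paths and ground truths, invisibly.
#' @export
cmd_simulate <- function(out_dir, seed = 1L, n_frames = 800L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tit <- gen_titration_system(seed = seed)
  write_pka_table(tit$sites, file.path(out_dir, "sites_pka.tsv"))
  write_interaction_table(tit$W, file.path(out_dir, "interactions.tsv"))
  trj <- gen_trajectory(n_frames = n_frames,
                        rupture_frame = round(n_frames * 0.6),
                        seed = seed)
  write_trajectory_pdb(trj$trajectory, file.path(out_dir, "trajectory.pdb"))
  alg <- gen_alignment(seed = seed)
  write_alignment(alg$alignment, file.path(out_dir, "alignment.fasta"),
                  file.path(out_dir, "groups.tsv"))
  gt <- list(titration = tit$spec,
             trajectory = trj$ground_truth[c("rupture_frame", "reform_frame",
                                             "reformed", "plateau",
                                             "contacts_pre",
                                             "contacts_post")],
             alignment = alg$ground_truth)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(dir = out_dir, titration = tit, trajectory = trj,
                 alignment = alg))
}

#' One-shot replay of the full pipeline
#'
#' Candidate selection on the packaged pKa table, then network, trajectory
#' and conservation stages on synthetic inputs generated under the given
#' seed, consolidated into one report. Byte-identical given the same
#' configuration and seed.
#'
#' @param out_dir output directory.
#' @param config a [run_config()]; its `seed` drives the generators.
#' @return the consolidated report, invisibly; writes `replay.json` and the
#'   per-stage outputs under `out_dir`.
#' @export
cmd_replay <- function(out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cmd_simulate(file.path(out_dir, "inputs"), seed = config$seed)
  sel <- cmd_select(system.file("extdata", "table1_vde_ph7.tsv",
                                package = "vdeswitch", mustWork = TRUE),
                    file.path(out_dir, "select"), config)
  net <- cmd_netmap(file.path(out_dir, "inputs", "interactions.tsv"),
                    file.path(out_dir, "netmap"), config, min_core = 2L)
  trj <- cmd_traj(file.path(out_dir, "inputs", "trajectory.pdb"),
                  file.path(out_dir, "traj"), config = config)
  cons <- cmd_conserve(
    file.path(out_dir, "inputs", "alignment.fasta"),
    file.path(out_dir, "inputs", "groups.tsv"),
    positions = sim$alignment$ground_truth$reference_position,
    out_dir = file.path(out_dir, "conserve"), config = config)
  activity <- load_fixture("table2_activity")
  rep <- .report("replay", config, list(
    select = sel$results, netmap = net$results, traj = trj$results,
    conserve = cons$results,
    activity_table = activity
  ))
  .write_report(rep, file.path(out_dir, "replay.json"))
  invisible(rep)
}
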