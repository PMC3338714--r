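# Trajectory integrity metrics: monitored distances, solvent contacts,
# rupture events, cavity volume and RMSF.

toy_atoms <- data.frame(
  chain = c("A", "A", "W", "W"),
  resname = c("HIS", "TYR", "HOH", "HOH"),
  resno = c(121L, 214L, 1001L, 1002L),
  atom = c("ND1", "HH", "OW", "OW"),
  stringsAsFactors = FALSE
)

test_that("atom distance series reproduces constructed geometries", {
  co <- rbind(c(0, 0, 0), c(0.2, 0, 0), c(1, 1, 1), c(2, 2, 2))
  traj <- static_trajectory(co, toy_atoms, n_frames = 100)
  d <- atom_distance_series(traj, "A:121:ND1", "A:214:HH")
  expect_equal(d, rep(0.2, 100))
  co2 <- co; co2[2, ] <- co2[1, ]
  traj2 <- static_trajectory(co2, toy_atoms, n_frames = 3)
  expect_equal(atom_distance_series(traj2, "A:121:ND1", "A:214:HH"),
               rep(0, 3))
  expect_error(atom_distance_series(traj, "A:9:CA", "A:214:HH"),
               "A:9:CA")
  dup <- toy_atoms; dup$atom[2] <- "ND1"; dup$resno[2] <- 121L
  dup$chain[2] <- "A"
  traj3 <- static_trajectory(co, dup, 2)
  expect_error(atom_distance_series(traj3, "A:121:ND1", "W:1001:OW"),
               "ambiguous")
})

test_that("a programmed rupture crosses the midpoint near its onset frame", {
  tr <- gen_trajectory(n_frames = 800, rupture_frame = 600, plateau = 0.55,
                       seed = 9)
  d <- atom_distance_series(tr$trajectory, "A:121:ND1", "A:214:HH")
  first_cross <- min(which(d > 0.45))
  expect_true(abs(first_cross - 600) <= 5)
})

test_that("solvent contacts equal a brute-force distance scan", {
  # five water oxygens placed at 0.3 nm
  n_w <- 5
  atoms <- data.frame(
    chain = c("A", rep("W", n_w)),
    resname = c("TYR", rep("HOH", n_w)),
    resno = c(214L, 1000L + seq_len(n_w)),
    atom = c("HH", rep("OW", n_w)))
  dirs <- diag(3)[c(1, 2, 3, 1, 2), ]
  co <- rbind(c(0, 0, 0), 0.3 * dirs)
  traj <- static_trajectory(co, atoms, 4)
  expect_equal(solvent_contact_series(traj, "A:214:HH", radius = 0.5),
               rep(5, 4))
  expect_equal(solvent_contact_series(traj, "A:214:HH", radius = 0),
               rep(0, 4))
  # random placements vs exhaustive scan
  set.seed(12)
  tr <- gen_trajectory(n_frames = 50, rupture_frame = 30, seed = 12)
  got <- solvent_contact_series(tr$trajectory, "A:214:HH", radius = 0.5)
  a <- tr$trajectory$atoms
  hh <- which(a$atom == "HH")
  ow <- which(a$resname == "HOH" & startsWith(a$atom, "O"))
  for (f in c(1, 10, 35, 50)) {
    co <- matrix(tr$trajectory$xyz[f, ], ncol = 3, byrow = TRUE)
    dd <- sqrt(colSums((t(co[ow, , drop = FALSE]) - co[hh, ])^2))
    expect_equal(got[f], sum(dd <= 0.5))
  }
})

test_that("rupture detection applies hysteresis and dwell suppression", {
  expect_equal(nrow(detect_rupture_events(rep(0.2, 500))), 0)
  # single-frame spike shorter than the dwell: suppressed
  spike <- rep(0.2, 300); spike[150] <- 0.6
  expect_equal(nrow(detect_rupture_events(spike)), 0)
  # clean break and reform
  s <- c(rep(0.2, 200), rep(0.6, 150), rep(0.2, 150))
  ev <- detect_rupture_events(s)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, 201)
  expect_equal(ev$end_frame, 351)
  expect_true(ev$reformed)
  # open event at the end of the series
  s2 <- c(rep(0.2, 200), rep(0.6, 150))
  ev2 <- detect_rupture_events(s2)
  expect_equal(nrow(ev2), 1)
  expect_false(ev2$reformed)
  expect_true(is.na(ev2$end_frame))
  expect_error(detect_rupture_events(s, formed_thr = 0.5, broken_thr = 0.3),
               "hysteresis")
})

test_that("generated rupture trajectories are recovered end to end", {
  for (seed in 1:5) {
    tr <- gen_trajectory(n_frames = 500, rupture_frame = 300,
                         reform_frame = if (seed %% 2) 420L else NA,
                         seed = seed)
    d <- atom_distance_series(tr$trajectory, "A:121:ND1", "A:214:HH")
    ev <- detect_rupture_events(d)
    expect_equal(nrow(ev), 1)
    expect_true(abs(ev$onset_frame - 300) <= 50)
    expect_equal(ev$reformed, tr$ground_truth$reformed)
  }
  none <- gen_trajectory(n_frames = 300, rupture_frame = NA, seed = 3)
  d0 <- atom_distance_series(none$trajectory, "A:121:ND1", "A:214:HH")
  expect_equal(nrow(detect_rupture_events(d0)), 0)
})

test_that("cavity volume matches analytic boxes and converges on refinement", {
  no_atoms <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                         atom = character())
  box <- c(0, 1, 0, 1, 0, 1)
  v <- cavity_volume(no_atoms, box, c(0.5, 0.5, 0.5), grid_spacing = 0.05)
  expect_equal(v, 1.0, tolerance = 0.05)
  # fully blocked box: zero volume (seed outside every atom sphere)
  wall <- expand.grid(x = seq(0.125, 0.875, 0.25),
                      y = seq(0.125, 0.875, 0.25),
                      z = seq(0.125, 0.875, 0.25))
  wall$atom <- "C"
  # probe cannot fit anywhere, but the seed interstice is outside every
  # van der Waals sphere: defined zero volume, not an error
  expect_equal(cavity_volume(wall, box, c(0.25, 0.25, 0.25),
                             grid_spacing = 0.1, probe_radius = 0.14), 0)
  # seed inside an atom is rejected
  one <- data.frame(x = 0.5, y = 0.5, z = 0.5, atom = "C")
  expect_error(cavity_volume(one, box, c(0.5, 0.5, 0.5)), "inside an atom")
  # grid refinement changes a toy cavity volume by < 5%
  corner <- data.frame(x = c(0, 1), y = c(0, 1), z = c(0, 0), atom = "C")
  v1 <- cavity_volume(corner, box, c(0.5, 0.5, 0.7), grid_spacing = 0.05)
  v2 <- cavity_volume(corner, box, c(0.5, 0.5, 0.7), grid_spacing = 0.025)
  expect_lt(abs(v2 - v1) / v1, 0.05)
})

test_that("RMSF matches closed forms and is frame-order invariant", {
  n_res <- 4
  atoms <- data.frame(chain = "A", resname = "GLY",
                      resno = 1:n_res, atom = "CA")
  base <- cbind(seq_len(n_res), 0, 0)
  # static trajectory: zero fluctuation everywhere
  expect_equal(rmsf(static_trajectory(base, atoms, 10), fit = FALSE)$rmsf,
               rep(0, n_res))
  # one atom alternating +/- d along y with equal dwell: rmsf = d
  d <- 0.07
  xyz <- do.call(rbind, lapply(1:20, function(f) {
    co <- base
    co[2, 2] <- if (f %% 2) d else -d
    as.vector(t(co))
  }))
  traj <- md_trajectory(atoms, xyz)
  r <- rmsf(traj, fit = FALSE)
  expect_equal(r$rmsf, c(0, d, 0, 0), tolerance = 1e-12)
  perm <- md_trajectory(atoms, xyz[sample(20), ])
  expect_equal(rmsf(perm, fit = FALSE)$rmsf, r$rmsf)
  expect_error(rmsf(static_trajectory(base, atoms, 1)), "single frame")
})

test_that("RMSF agrees with the bio3d reference implementation", {
  tr <- gen_trajectory(n_frames = 120, rupture_frame = NA, seed = 21)
  mine <- rmsf(tr$trajectory, fit = FALSE)
  sel <- which(tr$trajectory$atoms$atom == "CA")
  cols <- as.vector(rbind(3 * (sel - 1) + 1, 3 * (sel - 1) + 2, 3 * sel))
  ref <- bio3d::rmsf(tr$trajectory$xyz[, cols])
  # bio3d normalizes the time variance by n - 1; rescale to the n convention
  nf <- tr$trajectory$n_frames
  expect_equal(mine$rmsf, ref * sqrt((nf - 1) / nf), tolerance = 1e-9)
})

test_that("integrity metrics are invariant under rigid-body motion", {
  tr <- gen_trajectory(n_frames = 80, rupture_frame = 40, seed = 8)
  moved <- rigid_transform(tr$trajectory, seed = 99)
  expect_equal(
    atom_distance_series(moved, "A:121:ND1", "A:214:HH"),
    atom_distance_series(tr$trajectory, "A:121:ND1", "A:214:HH"),
    tolerance = 1e-10)
  expect_equal(
    solvent_contact_series(moved, "A:214:HH"),
    solvent_contact_series(tr$trajectory, "A:214:HH"))
  expect_equal(rmsf(moved)$rmsf, rmsf(tr$trajectory)$rmsf,
               tolerance = 1e-6)
})

test_that("RMSF/B-factor comparison follows the Pearson formula", {
  x <- c(0.1, 0.3, 0.2, 0.5, 0.4)
  expect_equal(rmsf_bfactor_correlation(x, 2 * x + 1)$r, 1.0)
  expect_equal(rmsf_bfactor_correlation(x, -3 * x + 2)$r, -1.0)
  set.seed(5)
  a <- stats::runif(10); b <- stats::runif(10)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- rmsf_bfactor_correlation(a, b)
  expect_equal(res$r, manual, tolerance = 1e-12)
  expect_equal(res$rmsf_z, (a - mean(a)) / stats::sd(a))
  flat <- rmsf_bfactor_correlation(rep(1, 5), a[1:5])
  expect_true(is.na(flat$r))
  expect_equal(attr(flat$r, "flag"), "undefined")
  expect_error(rmsf_bfactor_correlation(a, b[1:5]), "equal length")
})

test_that("trajectories survive a PDB round trip", {
  tr <- gen_trajectory(n_frames = 20, rupture_frame = 10, seed = 6)
  f <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr$trajectory, f)
  back <- read_trajectory(f)
  expect_equal(back$n_frames, 20)
  expect_equal(back$atoms$resno, tr$trajectory$atoms$resno)
  # PDB has 3 decimals in angstroms: 5e-5 nm quantization
  expect_lt(max(abs(back$xyz - tr$trajectory$xyz)), 1e-4)
  expect_equal(
    detect_rupture_events(atom_distance_series(back, "A:121:ND1",
                                               "A:214:HH"), dwell = 5),
    detect_rupture_events(atom_distance_series(tr$trajectory, "A:121:ND1",
                                               "A:214:HH"), dwell = 5))
})
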