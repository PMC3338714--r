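# Independent oracles used across tests: exhaustive definition checks and
# brute-force recomputations kept deliberately separate from the package's
# own code paths.

# Exhaustive k-core oracle: core(v) = max over all vertex subsets S
# containing v of the minimum degree of the subgraph induced by S.
# Bitmask enumeration, feasible up to ~12 nodes.
oracle_core_numbers <- function(n, edges_ij) {
  adj <- integer(n)  # bitmask adjacency
  if (nrow(edges_ij)) {
    for (r in seq_len(nrow(edges_ij))) {
      i <- edges_ij[r, 1L]; j <- edges_ij[r, 2L]
      adj[i] <- bitwOr(adj[i], bitwShiftL(1L, j - 1L))
      adj[j] <- bitwOr(adj[j], bitwShiftL(1L, i - 1L))
    }
  }
  popcnt <- vapply(0:(2^n - 1), function(x) sum(bitwAnd(x, 2^(0:(n - 1))) > 0),
                   numeric(1))
  core <- integer(n)
  for (S in seq_len(2^n - 1)) {
    members <- which(bitwAnd(S, bitwShiftL(1L, 0:(n - 1L))) > 0L)
    degs <- popcnt[bitwAnd(adj[members], S) + 1L]
    m <- min(degs)
    core[members] <- pmax(core[members], m)
  }
  core
}

# Random undirected simple graph as an interaction-record data.frame; every
# node appears as a residue so roles resolve. Returns both the record table
# and the plain (i, j) edge list.
random_graph_records <- function(n, p_edge = 0.35, energy_range = c(0.3, 2)) {
  res_pool <- c("ASP", "GLU", "HIS", "LYS", "ARG", "TYR")
  resn <- sample(res_pool, n, replace = TRUE)
  ij <- t(combn(n, 2))
  keep <- stats::runif(nrow(ij)) < p_edge
  if (!any(keep)) keep[1L] <- TRUE  # at least one edge
  ij <- ij[keep, , drop = FALSE]
  e <- stats::runif(nrow(ij), energy_range[1L], energy_range[2L]) *
    sample(c(-1, 1), nrow(ij), replace = TRUE)
  rec <- data.frame(
    chainA = "A", resA = resn[ij[, 1L]], numA = ij[, 1L],
    chainB = "A", resB = resn[ij[, 2L]], numB = ij[, 2L],
    energy_kcal = e, stringsAsFactors = FALSE
  )
  list(records = rec, edges = ij, n = n,
       ids = paste("A", resn, seq_len(n), sep = ":"))
}

# map package core assignment back onto 1..n node indexing (nodes with no
# edges are dropped by build_graph; their core is 0)
cores_by_index <- function(assignment, ids) {
  out <- integer(length(ids))
  hit <- match(assignment$nodes$site_id, ids)
  out[hit] <- assignment$nodes$core
  out
}

# tiny deterministic trajectory: atoms at fixed positions across frames
static_trajectory <- function(coords, atoms, n_frames = 10L) {
  xyz <- matrix(rep(as.vector(t(coords)), n_frames), nrow = n_frames,
                byrow = TRUE)
  md_trajectory(atoms, xyz)
}

# random rigid-body transform applied frame-wise to a trajectory
rigid_transform <- function(traj, seed = 1L) {
  set.seed(seed)
  n_atoms <- nrow(traj$atoms)
  xyz <- traj$xyz
  for (f in seq_len(traj$n_frames)) {
    th <- stats::runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    R <- Rz %*% Rx
    shift <- stats::runif(3, -2, 2)
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    xyz[f, ] <- as.vector(t(sweep(co %*% t(R), 2, shift, "+")))
  }
  md_trajectory(traj$atoms, xyz)
}
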