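# Interaction node maps: graph construction, density, k-cores, hubs, DOT
# export and inter-chain contact maps.

obs <- function(...) {
  # quick pairwise-observation rows: list(numA, numB, energy)
  rows <- list(...)
  data.frame(
    chainA = "A", resA = "ASP", numA = vapply(rows, `[[`, 0, 1),
    chainB = "A", resB = "ARG", numB = vapply(rows, `[[`, 0, 2),
    energy_kcal = vapply(rows, `[[`, 0, 3), stringsAsFactors = FALSE
  )
}

test_that("graph construction averages duplicates and applies the cutoff", {
  g <- build_graph(obs(c(1, 2, 0.5), c(1, 2, 0.7)), cutoff = 0.2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$mean_energy, 0.6)
  expect_equal(g$edges$n_observations, 2L)
  # below-threshold pair: no edge, and the nodes disappear with it
  g2 <- build_graph(obs(c(1, 2, 0.15)), cutoff = 0.2)
  expect_equal(nrow(g2$edges), 0)
  expect_equal(nrow(g2$nodes), 0)
  # orientation invariance: (A,B) and (B,A) are one pair
  rec <- obs(c(1, 2, 0.4))
  flipped <- rec[, c(4:6, 1:3, 7)]
  names(flipped) <- names(rec)
  both <- rbind(rec, flipped)
  g3 <- build_graph(both, cutoff = 0.2)
  expect_equal(nrow(g3$edges), 1)
  expect_equal(g3$edges$mean_energy, 0.4)
  expect_error(build_graph(obs(c(1, 2, 1))[, -7], cutoff = 0.2), "lack")
})

test_that("edge count and density are non-increasing in the cutoff", {
  set.seed(101)
  for (rep_i in 1:5) {
    rg <- random_graph_records(10)
    cuts <- c(0, 0.2, 0.4, 0.8, 1.6)
    ecount <- vapply(cuts, function(co)
      nrow(build_graph(rg$records, cutoff = co)$edges), 0)
    expect_true(all(diff(ecount) <= 0))
  }
})

test_that("graph density equals the direct pair-count formula", {
  # complete graph on 4 nodes
  k4 <- data.frame(chainA = "A", resA = "ASP", numA = c(1, 1, 1, 2, 2, 3),
                   chainB = "A", resB = "ASP", numB = c(2, 3, 4, 3, 4, 4),
                   energy_kcal = 1)
  expect_equal(graph_density(build_graph(k4, cutoff = 0.2)), 1.0)
  # edgeless graph (nodes kept explicitly)
  g0 <- build_graph(k4, cutoff = 2, keep_isolated = TRUE)
  expect_equal(nrow(g0$nodes), 4)
  expect_equal(graph_density(g0), 0.0)
  # random graphs against a brute-force recount
  set.seed(7)
  for (rep_i in 1:5) {
    rg <- random_graph_records(8)
    g <- build_graph(rg$records, cutoff = 0.2, keep_isolated = TRUE)
    n <- nrow(g$nodes)
    manual <- sum(abs(tapply(rg$records$energy_kcal,
                             paste(rg$records$numA, rg$records$numB),
                             mean)) > 0.2)
    expect_equal(graph_density(g), 2 * manual / (n * (n - 1)))
  }
  g1 <- build_graph(obs(c(1, 2, 0.1)), cutoff = 0, keep_isolated = FALSE)
  g1$nodes <- g1$nodes[1, , drop = FALSE]  # degenerate single-node graph
  expect_true(is.na(graph_density(g1)))
})

test_that("k-core decomposition matches canonical small graphs", {
  tri <- data.frame(chainA = "A", resA = "ASP", numA = c(1, 2, 3),
                    chainB = "A", resB = "ASP", numB = c(2, 3, 1),
                    energy_kcal = 1)
  kc <- k_core_decomposition(build_graph(tri, cutoff = 0.2))
  expect_equal(kc$nodes$core, rep(2L, 3))
  star <- data.frame(chainA = "A", resA = "HIS", numA = 1,
                     chainB = "A", resB = "ASP", numB = 2:6,
                     energy_kcal = -1)
  ks <- k_core_decomposition(build_graph(star, cutoff = 0.2))
  expect_equal(ks$nodes$core, rep(1L, 6))
})

test_that("k-core agrees with the exhaustive oracle and igraph on random graphs", {
  set.seed(2024)
  for (rep_i in 1:25) {
    n <- sample(4:12, 1)
    rg <- random_graph_records(n, p_edge = stats::runif(1, 0.15, 0.6))
    g <- build_graph(rg$records, cutoff = 0, keep_isolated = TRUE)
    got <- cores_by_index(k_core_decomposition(g), rg$ids)
    want <- oracle_core_numbers(n, rg$edges)
    expect_equal(got, want)
    # independent library cross-check
    ig <- igraph::graph_from_edgelist(rg$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
    expect_equal(got, as.integer(igraph::coreness(ig)))
  }
})

test_that("core numbers never increase when an edge is deleted", {
  set.seed(55)
  rg <- random_graph_records(10, p_edge = 0.4)
  g <- build_graph(rg$records, cutoff = 0, keep_isolated = TRUE)
  before <- cores_by_index(k_core_decomposition(g), rg$ids)
  for (drop_i in seq_len(min(5, nrow(g$edges)))) {
    g2 <- g
    g2$edges <- g$edges[-drop_i, , drop = FALSE]
    after <- cores_by_index(k_core_decomposition(g2), rg$ids)
    expect_true(all(after <= before))
  }
})

test_that("hub extraction returns connected components above the core level", {
  # two disjoint K5s
  k5 <- t(combn(5, 2))
  two_k5 <- data.frame(
    chainA = "A", resA = "ASP", numA = c(k5[, 1], k5[, 1] + 10),
    chainB = "A", resB = "ASP", numB = c(k5[, 2], k5[, 2] + 10),
    energy_kcal = 1)
  g <- build_graph(two_k5, cutoff = 0.2)
  hubs <- interaction_hubs(g, min_core = 4)
  expect_length(hubs, 2)
  expect_equal(vapply(hubs, nrow, 0L), c(5L, 5L))
  expect_length(interaction_hubs(g, min_core = 5), 0)
})

test_that("DOT export follows the pen-width formula and display threshold", {
  expect_equal(penwidth(4), 10.8)
  expect_equal(penwidth(-4), 10.8)
  expect_equal(penwidth(2), 2 * (11 - 0.2) / 4)
  expect_equal(penwidth(8), 10.8)  # clipped at the upper threshold
  recs <- obs(c(1, 2, 4.0), c(3, 4, 0.3), c(5, 6, -1.2))
  g <- build_graph(recs, cutoff = 0.2)
  dot <- export_dot(g, display_threshold = 0.4)
  edges <- parse_dot_edges(dot)
  # |E| = 0.3 edge analyzed but not rendered
  expect_equal(nrow(g$edges), 3)
  expect_equal(nrow(edges), 2)
  expect_equal(sort(edges$energy), c(-1.2, 4.0))
  expect_equal(edges$penwidth[edges$energy == 4], 10.8)
  expect_error(export_dot(g, display_threshold = 0.1), "cutoff")
})

test_that("DOT export is lossless above the display threshold", {
  set.seed(31)
  for (rep_i in 1:5) {
    rg <- random_graph_records(9, p_edge = 0.5)
    g <- build_graph(rg$records, cutoff = 0.2)
    dot <- export_dot(g, display_threshold = 0.4)
    back <- parse_dot_edges(dot)
    kept <- g$edges[abs(g$edges$mean_energy) > 0.4, ]
    expect_equal(nrow(back), nrow(kept))
    expect_equal(sort(back$energy), sort(round(kept$mean_energy, 6)))
    # determinism: same graph, same bytes
    expect_identical(dot, export_dot(g, display_threshold = 0.4))
  }
})

test_that("contact maps hold minimal inter-chain residue distances", {
  atoms <- data.frame(
    chain = c("A", "B"), resno = c(1, 1),
    x = c(0, 3), y = 0, z = 0, stringsAsFactors = FALSE)
  expect_equal(contact_map(atoms)[1, 1], 3.0)
  atoms$x <- c(1, 1)
  expect_equal(contact_map(atoms)[1, 1], 0.0)
  # brute-force oracle on random two-chain toy structures
  set.seed(77)
  toy <- data.frame(
    chain = rep(c("A", "B"), each = 15),
    resno = rep(rep(1:5, each = 3), 2),
    x = stats::rnorm(30), y = stats::rnorm(30), z = stats::rnorm(30))
  cm <- contact_map(toy)
  for (i in 1:5) for (j in 1:5) {
    a <- toy[toy$chain == "A" & toy$resno == i, c("x", "y", "z")]
    b <- toy[toy$chain == "B" & toy$resno == j, c("x", "y", "z")]
    dmin <- min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") -
                       2 * as.matrix(a) %*% t(as.matrix(b))))
    expect_equal(cm[i, j], dmin, tolerance = 1e-9)
  }
  expect_error(contact_map(toy, "A", "C"), "chain 'C'")
})
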