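# Electrostatic interaction node maps: residues as acid/base nodes, averaged
# pairwise interaction energies as signed weighted edges, analyzed with graph
# density, k-core decomposition and hub extraction, rendered via DOT.

#' Build an electrostatic interaction graph
#'
#' Averages duplicate pairwise energy observations (in either orientation) and
#' keeps an edge when the absolute mean energy exceeds the analysis cutoff.
#' Nodes are the sites incident to at least one retained edge, with acid/base
#' roles inferred from the residue name.
#'
#' @param records either the list returned by [read_interaction_table()] or a
#'   data.frame with columns `chainA resA numA chainB resB numB energy_kcal`.
#' @param cutoff analysis cutoff in kcal mol^-1 (default 0.2); edges are kept
#'   iff `|mean energy| > cutoff`.
#' @param keep_isolated keep nodes that lose all their edges (default FALSE).
#' @return an `interaction_graph`: `nodes` (site_id, label, chain, kind),
#'   `edges` (site_a, site_b, mean_energy, n_observations), `cutoff`.
#' @export
build_graph <- function(records, cutoff = 0.2, keep_isolated = FALSE) {
  if (cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  if (is.data.frame(records)) {
    need <- c("chainA", "resA", "numA", "chainB", "resB", "numB",
              "energy_kcal")
    miss <- setdiff(need, names(records))
    if (length(miss)) {
      stop("interaction records lack column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    id_a <- .site_id(records$chainA, records$resA, records$numA)
    id_b <- .site_id(records$chainB, records$resB, records$numB)
    sites <- unique(data.frame(
      site_id = c(id_a, id_b),
      chain = c(records$chainA, records$chainB),
      residue_name = toupper(c(records$resA, records$resB)),
      residue_number = as.integer(c(records$numA, records$numB)),
      stringsAsFactors = FALSE
    ))
    sites$kind <- residue_kind(sites$residue_name)
    W <- interaction_matrix(id_a, id_b, records$energy_kcal)
  } else if (is.list(records) && !is.null(records$matrix)) {
    sites <- records$sites
    W <- records$matrix
  } else {
    stop("records must be a data.frame of observations or the result of ",
         "read_interaction_table()", call. = FALSE)
  }
  edges <- W$pairs[abs(W$pairs$mean_energy) > cutoff, , drop = FALSE]
  rownames(edges) <- NULL
  used <- if (keep_isolated) sites$site_id else
    unique(c(edges$site_a, edges$site_b))
  nodes <- sites[sites$site_id %in% used, , drop = FALSE]
  nodes <- nodes[order(nodes$chain, nodes$residue_number), , drop = FALSE]
  nodes$label <- site_label(nodes)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("Electrostatic interaction graph: ", nrow(x$nodes), " node(s), ",
      nrow(x$edges), " edge(s) above |E| > ", x$cutoff, " kcal/mol\n",
      sep = "")
  invisible(x)
}

.as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$edges)) g$edges[, c("site_a", "site_b")] else
      data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = g$nodes$site_id)
  )
}

#' Graph density of an interaction map
#'
#' Fraction of possible residue pairs connected by a retained edge:
#' `2|E| / (|N| (|N| - 1))`.
#'
#' @param g an `interaction_graph`.
#' @return density in `[0, 1]`; `NA` with attribute `flag = "undefined"` for
#'   graphs with fewer than two nodes.
#' @export
graph_density <- function(g) {
  n <- nrow(g$nodes)
  if (n < 2L) return(structure(NA_real_, flag = "undefined"))
  2 * nrow(g$edges) / (n * (n - 1))
}

#' k-core decomposition of an interaction graph
#'
#' A node's core number is the largest k such that it belongs to a subgraph in
#' which every node has at least k neighbours. Computed by iterative pruning:
#' repeatedly delete all nodes of degree < k. Edge signs are ignored; an edge
#' is an edge once it survived the build cutoff. Cohesive subgroups at a core
#' level are the connected components of the induced subgraph (see
#' [interaction_hubs()]).
#'
#' @param g an `interaction_graph`.
#' @return a `core_assignment`: data.frame `nodes` with `site_id`, `label`,
#'   `core`.
#' @export
k_core_decomposition <- function(g) {
  ids <- g$nodes$site_id
  core <- stats::setNames(integer(length(ids)), ids)
  if (length(ids) && nrow(g$edges)) {
    adj <- .adj_list(ids, g$edges)
    deg <- lengths(adj)
    alive <- stats::setNames(rep(TRUE, length(ids)), ids)
    k <- 0L
    while (any(alive)) {
      repeat {
        victims <- names(which(alive & deg < k))
        if (!length(victims)) break
        core[victims] <- k - 1L
        alive[victims] <- FALSE
        for (v in victims) {
          for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
        }
      }
      k <- k + 1L
    }
    core[names(which(core < 0))] <- 0L
  }
  out <- data.frame(site_id = ids, label = g$nodes$label,
                    core = as.integer(core[ids]),
                    stringsAsFactors = FALSE)
  structure(list(nodes = out, graph = g), class = "core_assignment")
}

# adjacency list on character ids
.adj_list <- function(ids, edges) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(edges))) {
    a <- edges$site_a[i]; b <- edges$site_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' @export
print.core_assignment <- function(x, ...) {
  cat("k-core decomposition:", nrow(x$nodes), "node(s), max core",
      if (nrow(x$nodes)) max(x$nodes$core) else 0, "\n")
  tab <- table(x$nodes$core)
  for (k in rev(names(tab))) cat("  core ", k, ": ", tab[[k]],
                                 " node(s)\n", sep = "")
  invisible(x)
}

#' Extract interaction hubs at a minimum core level
#'
#' Hubs are the cohesive subgroups of strongly coupled residues: connected
#' components of the subgraph induced by all nodes whose core number is at
#' least `min_core`.
#'
#' @param g an `interaction_graph`.
#' @param min_core minimum core number (>= 1).
#' @param cores optional precomputed [k_core_decomposition()] of `g`.
#' @return list of hubs, each a data.frame (`site_id`, `label`, `core`),
#'   largest first; empty list when no node reaches `min_core`.
#' @export
interaction_hubs <- function(g, min_core = 4L, cores = NULL) {
  if (min_core < 1L) stop("min_core must be >= 1", call. = FALSE)
  if (is.null(cores)) cores <- k_core_decomposition(g)
  keep <- cores$nodes$site_id[cores$nodes$core >= min_core]
  if (!length(keep)) return(list())
  ig <- .as_igraph(g)
  sub <- igraph::induced_subgraph(ig, keep)
  comp <- igraph::components(sub)
  members <- split(names(comp$membership), comp$membership)
  hubs <- lapply(members, function(m) {
    df <- cores$nodes[match(m, cores$nodes$site_id), , drop = FALSE]
    df <- df[order(-df$core, df$site_id), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  unname(hubs[order(-vapply(hubs, nrow, 1L))])
}

#' Render an interaction graph as DOT
#'
#' Emits Graphviz DOT text for the node map: acid nodes red, base nodes blue;
#' stabilizing (negative-energy) edges green, destabilizing (positive) red.
#' Edges with `|E|` at or below the display threshold are omitted from the
#' rendering (they remain part of the analysis graph). Edge pen width scales
#' linearly with `|E|`:
#' `penwidth = |E| * (maxPenWidth - minPenWidth) / upperThreshold`
#' with `|E|` clipped at `upperThreshold` so widths never exceed the maximum.
#'
#' @param g an `interaction_graph`.
#' @param display_threshold kcal mol^-1; default 0.4. Must be at least the
#'   graph's build cutoff.
#' @param max_penwidth,min_penwidth,upper_threshold pen-width scaling
#'   constants (defaults 11 px, 0.2 px, 4 kcal mol^-1).
#' @param graph_name DOT graph identifier.
#' @return single character string of valid DOT, invisibly writable with
#'   [writeLines()].
#' @export
export_dot <- function(g, display_threshold = 0.4,
                       max_penwidth = 11, min_penwidth = 0.2,
                       upper_threshold = 4, graph_name = "nodemap") {
  if (display_threshold < g$cutoff) {
    stop("display_threshold must be >= the graph build cutoff (",
         g$cutoff, ")", call. = FALSE)
  }
  nodes <- g$nodes[order(g$nodes$site_id), , drop = FALSE]
  lab <- stats::setNames(nodes$label, nodes$site_id)
  node_lines <- sprintf(
    "  \"%s\" [style=filled, fillcolor=%s];",
    lab, ifelse(nodes$kind == "acid", "red",
                ifelse(nodes$kind == "base", "blue", "grey"))
  )
  e <- g$edges[abs(g$edges$mean_energy) > display_threshold, , drop = FALSE]
  e <- e[order(e$site_a, e$site_b), , drop = FALSE]
  pw <- penwidth(e$mean_energy, max_penwidth, min_penwidth, upper_threshold)
  edge_lines <- sprintf(
    "  \"%s\" -- \"%s\" [color=%s, penwidth=%.4f, energy=\"%.6f\"];",
    lab[e$site_a], lab[e$site_b],
    ifelse(e$mean_energy < 0, "green", "red"), pw, e$mean_energy
  )
  paste(c(sprintf("graph %s {", graph_name),
          "  node [shape=ellipse];",
          node_lines, edge_lines, "}"),
        collapse = "\n")
}

#' Edge pen width for DOT rendering
#'
#' @param energy signed interaction energy/energies, kcal mol^-1.
#' @param max_penwidth,min_penwidth,upper_threshold scaling constants; an
#'   absolute energy of `upper_threshold` maps to
#'   `upper_threshold * (max_penwidth - min_penwidth) / upper_threshold`
#'   (10.8 px with the defaults) and larger energies are clipped there.
#' @return pen width(s) in px.
#' @export
#' @examples
#' penwidth(4)    # 10.8
#' penwidth(-0.4)
penwidth <- function(energy, max_penwidth = 11, min_penwidth = 0.2,
                     upper_threshold = 4) {
  pmin(abs(energy), upper_threshold) *
    (max_penwidth - min_penwidth) / upper_threshold
}

#' Parse edges back out of emitted DOT text
#'
#' Inverse of [export_dot()] for round-trip checks: recovers the rendered
#' edge set (labels and signed energies) from the DOT text.
#'
#' @param dot DOT string produced by [export_dot()].
#' @return data.frame with `label_a`, `label_b`, `energy`, `penwidth`.
#' @export
parse_dot_edges <- function(dot) {
  lines <- strsplit(dot, "\n", fixed = TRUE)[[1L]]
  m <- regmatches(lines, regexec(
    "^\\s*\"([^\"]+)\" -- \"([^\"]+)\" \\[color=\\w+, penwidth=([0-9.]+), energy=\"(-?[0-9.]+)\"\\];",
    lines))
  hits <- m[lengths(m) == 5L]
  data.frame(
    label_a = vapply(hits, `[`, "", 2L),
    label_b = vapply(hits, `[`, "", 3L),
    penwidth = as.numeric(vapply(hits, `[`, "", 4L)),
    energy = as.numeric(vapply(hits, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
}

#' Inter-chain residue contact map
#'
#' Minimal inter-atomic distance (in angstroms) between every residue of one
#' chain and every residue of another, as used to display the dimer interface.
#'
#' @param atoms data.frame of atom records with columns `chain`, `resno`,
#'   `x`, `y`, `z` (coordinates in angstroms), e.g. the `atom` table of a
#'   [bio3d::read.pdb()] object.
#' @param chain_a,chain_b the two chain identifiers.
#' @return matrix of minimal distances, rows = residues of `chain_a`, columns
#'   = residues of `chain_b`, dimnames the residue numbers.
#' @export
contact_map <- function(atoms, chain_a = "A", chain_b = "B") {
  A <- atoms[atoms$chain == chain_a, , drop = FALSE]
  B <- atoms[atoms$chain == chain_b, , drop = FALSE]
  if (!nrow(A)) stop("chain '", chain_a, "' has no atoms", call. = FALSE)
  if (!nrow(B)) stop("chain '", chain_b, "' has no atoms", call. = FALSE)
  ra <- sort(unique(A$resno))
  rb <- sort(unique(B$resno))
  xa <- as.matrix(A[, c("x", "y", "z")])
  xb <- as.matrix(B[, c("x", "y", "z")])
  # all inter-atomic distances, then min-reduce by residue pair
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  ia <- factor(match(A$resno, ra), levels = seq_along(ra))
  ib <- factor(match(B$resno, rb), levels = seq_along(rb))
  pm <- tapply(as.vector(d), list(ia[row(d)], ib[col(d)]), min)
  matrix(as.numeric(pm), length(ra), length(rb), dimnames = list(ra, rb))
}
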