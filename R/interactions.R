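# Pairwise electrostatic coupling energies between ionized residues
# (the "mfe" dialect of continuum-electrostatics output, re-specified as TSV).

#' Build a symmetric site-site interaction matrix
#'
#' Stores pairwise electrostatic interaction energies between the *ionized*
#' forms of two titratable sites, in kcal mol^-1. Keys are unordered: an
#' observation for (A,B) and one for (B,A) refer to the same entry and are
#' averaged on construction. Self-pairs are rejected.
#'
#' @param site_a,site_b character vectors of site ids (as in
#'   [titratable_sites()]`$site_id`).
#' @param energy interaction energies, kcal mol^-1, finite.
#' @param temperature_K temperature used downstream, kelvin.
#' @return an `interaction_matrix` object: data.frame of unique unordered
#'   pairs with `mean_energy` and `n_observations`, plus the temperature.
#' @export
interaction_matrix <- function(site_a = character(), site_b = character(),
                               energy = numeric(), temperature_K = 298) {
  stopifnot(length(site_a) == length(site_b),
            length(site_a) == length(energy))
  energy <- as.numeric(energy)
  if (any(!is.finite(energy))) {
    stop("interaction energies must be finite", call. = FALSE)
  }
  if (any(site_a == site_b)) {
    stop("self-interaction pairs are not allowed", call. = FALSE)
  }
  if (length(site_a)) {
    lo <- pmin(site_a, site_b)
    hi <- pmax(site_a, site_b)
    key <- paste(lo, hi, sep = "|")
    mean_e <- tapply(energy, key, mean)
    n_obs <- tapply(energy, key, length)
    parts <- strsplit(names(mean_e), "|", fixed = TRUE)
    pairs <- data.frame(
      site_a = vapply(parts, `[`, "", 1L),
      site_b = vapply(parts, `[`, "", 2L),
      mean_energy = as.numeric(mean_e),
      n_observations = as.integer(n_obs),
      stringsAsFactors = FALSE
    )
  } else {
    pairs <- data.frame(site_a = character(), site_b = character(),
                        mean_energy = numeric(),
                        n_observations = integer(),
                        stringsAsFactors = FALSE)
  }
  pairs <- pairs[order(pairs$site_a, pairs$site_b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, temperature_K = temperature_K),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Interaction matrix:", nrow(x$pairs), "unordered pair(s), T =",
      x$temperature_K, "K\n")
  if (nrow(x$pairs)) print(utils::head(x$pairs, 10L), row.names = FALSE)
  invisible(x)
}

# Dense symmetric matrix (kcal/mol) over the given site ids; absent pairs -> 0.
.dense_W <- function(W, site_ids) {
  n <- length(site_ids)
  M <- matrix(0, n, n, dimnames = list(site_ids, site_ids))
  if (!is.null(W) && nrow(W$pairs)) {
    p <- W$pairs
    keep <- p$site_a %in% site_ids & p$site_b %in% site_ids
    p <- p[keep, , drop = FALSE]
    if (nrow(p)) {
      ia <- match(p$site_a, site_ids)
      ib <- match(p$site_b, site_ids)
      M[cbind(ia, ib)] <- p$mean_energy
      M[cbind(ib, ia)] <- p$mean_energy
    }
  }
  M
}

#' Read a pairwise interaction-energy table
#'
#' Tab-separated with header
#' `chainA resA numA chainB resB numB energy_kcal`; duplicate pairs (in either
#' orientation) are averaged on load. Also returns the sites named by the
#' table so a graph can be built without a separate pKa table.
#'
#' @param path path to a TSV file.
#' @param temperature_K temperature recorded on the matrix, kelvin.
#' @return list with `matrix` (an [interaction_matrix()]) and `sites`
#'   (data.frame of the distinct sites seen: `site_id`, `chain`,
#'   `residue_name`, `residue_number`, `kind`).
#' @export
read_interaction_table <- function(path, temperature_K = 298) {
  if (!file.exists(path)) {
    stop("interaction table not found: ", path, call. = FALSE)
  }
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("failed to parse interaction table '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  need <- c("chainA", "resA", "numA", "chainB", "resB", "numB", "energy_kcal")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("interaction table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  e <- suppressWarnings(as.numeric(tab$energy_kcal))
  if (any(!is.finite(e))) {
    stop("interaction table '", path, "': non-numeric energy at data line ",
         which(!is.finite(e))[1L], call. = FALSE)
  }
  id_a <- .site_id(tab$chainA, tab$resA, tab$numA)
  id_b <- .site_id(tab$chainB, tab$resB, tab$numB)
  sites <- unique(data.frame(
    site_id = c(id_a, id_b),
    chain = c(tab$chainA, tab$chainB),
    residue_name = toupper(c(tab$resA, tab$resB)),
    residue_number = as.integer(c(tab$numA, tab$numB)),
    stringsAsFactors = FALSE
  ))
  sites$kind <- residue_kind(sites$residue_name)
  sites <- sites[order(sites$chain, sites$residue_number), , drop = FALSE]
  rownames(sites) <- NULL
  list(matrix = interaction_matrix(id_a, id_b, e, temperature_K),
       sites = sites)
}
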