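# Microstate titration of interacting ionizable residues.
#
# Model: each site i is either neutral (x_i = 0) or ionized (x_i = 1).
# A microstate energy combines a per-site pH-dependent ionization penalty
# with pairwise electrostatic couplings between ionized sites:
#
#   E(x; pH) = sum_i x_i * eps_i(pH) + sum_{i<j} x_i x_j W_ij
#   eps_i = ln(10) kB T (pKa_i - pH)   for acids
#   eps_i = ln(10) kB T (pH - pKa_i)   for bases
#
# with kB T ~ 0.593 kcal/mol at 298 K. In the non-interacting limit the
# Boltzmann average over the two states of a single site reduces exactly to
# the Henderson-Hasselbalch protonated fraction 1/(1 + 10^(pH - pKa)).

#' Henderson-Hasselbalch protonated fraction
#'
#' Protonated fraction of an isolated titratable group at a given pH. The same
#' formula applies to acids and bases: it is the fraction carrying the proton;
#' the *charge* interpretation differs by kind (a protonated acid is neutral,
#' a protonated base is positive).
#'
#' @param pKa,pH finite numerics (vectorized, recycled).
#' @return fraction(s) in `[0, 1]`: `1 / (1 + 10^(pH - pKa))`.
#' @export
#' @examples
#' protonation_fraction(5.3, 5.3)  # 0.5 at half-titration
#' protonation_fraction(5.3, 7.0)
protonation_fraction <- function(pKa, pH) {
  if (any(!is.finite(pKa)) || any(!is.finite(pH))) {
    stop("pKa and pH must be finite", call. = FALSE)
  }
  1 / (1 + 10^(pH - pKa))
}

#' Protonation change across a pH transition
#'
#' Absolute change in Henderson-Hasselbalch protonated fraction between two pH
#' values; the quantity behind "changes protonation state by 50% or more"
#' statements about a pH drop.
#'
#' @param pKa,pH_from,pH_to finite numerics (vectorized).
#' @return `|f(pH_to) - f(pH_from)|`, in `[0, 1]`.
#' @export
#' @examples
#' delta_protonation(5.3, 7.0, 5.2)
delta_protonation <- function(pKa, pH_from, pH_to) {
  abs(protonation_fraction(pKa, pH_to) - protonation_fraction(pKa, pH_from))
}

# Per-site ionization penalties eps_i(pH), kcal/mol
.site_eps <- function(sites, pH, temperature_K) {
  kT <- .KB_KCAL * temperature_K
  sgn <- ifelse(sites$kind == "acid", 1, -1)
  log(10) * kT * sgn * (sites$pKa - pH)
}

#' Energy of one protonation microstate
#'
#' @param state integer/logical vector, one element per site; 1 means the site
#'   is ionized (charged), 0 neutral.
#' @param sites a [titratable_sites()] table.
#' @param W an [interaction_matrix()] or `NULL` for no coupling.
#' @param pH the pH at which the per-site terms are evaluated.
#' @param temperature_K temperature, kelvin.
#' @return microstate energy in kcal mol^-1 relative to the all-neutral state.
#' @export
microstate_energy <- function(state, sites, W = NULL, pH,
                              temperature_K = 298) {
  state <- as.numeric(state)
  if (length(state) != nrow(sites)) {
    stop("state vector length (", length(state),
         ") does not match number of sites (", nrow(sites), ")",
         call. = FALSE)
  }
  if (!all(state %in% c(0, 1))) {
    stop("state entries must be 0 (neutral) or 1 (ionized)", call. = FALSE)
  }
  eps <- .site_eps(sites, pH, temperature_K)
  M <- .dense_W(W, sites$site_id)
  sum(state * eps) + 0.5 * drop(state %*% M %*% state)
}

.new_titration_curve <- function(pH_grid, protonated, sites, method,
                                 mc_steps = NULL, seed = NULL) {
  structure(list(pH_grid = pH_grid, protonated_fraction = protonated,
                 sites = sites, method = method,
                 mc_steps = mc_steps, seed = seed),
            class = "titration_curve")
}

.check_grid <- function(pH_grid) {
  if (length(pH_grid) < 2L || any(diff(pH_grid) <= 0)) {
    stop("pH_grid must be strictly ascending with at least 2 points",
         call. = FALSE)
  }
}

#' Exact titration by microstate enumeration
#'
#' Boltzmann-weighted average ionization of every site at every grid pH,
#' summing over all `2^N` microstates. Exact, hence the oracle against which
#' the Monte-Carlo sampler is validated; limited to `N <= 20` sites.
#'
#' @param sites a [titratable_sites()] table (possibly 0 rows).
#' @param W an [interaction_matrix()] or `NULL`.
#' @param pH_grid strictly ascending pH values (>= 2 points).
#' @param temperature_K temperature, kelvin.
#' @return a `titration_curve`: matrix `protonated_fraction` of
#'   `length(pH_grid)` rows x `nrow(sites)` columns. Protonated fraction is
#'   derived from mean ionization by kind (acid: `1 - <x>`; base: `<x>`).
#' @export
enumerate_titration <- function(sites, W = NULL, pH_grid,
                                temperature_K = 298) {
  .check_grid(pH_grid)
  n <- nrow(sites)
  if (n == 0L) {
    return(.new_titration_curve(
      pH_grid, matrix(numeric(), length(pH_grid), 0), sites, "enumeration"))
  }
  if (n > 20L) {
    stop("enumerate_titration is limited to 20 sites (2^N states); ",
         "use mc_titration() for larger systems", call. = FALSE)
  }
  kT <- .KB_KCAL * temperature_K
  # all 2^n ionization vectors, one row per microstate
  S <- as.matrix(expand.grid(rep(list(c(0, 1)), n), KEEP.OUT.ATTRS = FALSE))
  colnames(S) <- sites$site_id
  M <- .dense_W(W, sites$site_id)
  Equad <- 0.5 * rowSums((S %*% M) * S)  # pairwise part, pH-independent
  prot <- matrix(NA_real_, length(pH_grid), n,
                 dimnames = list(NULL, sites$site_id))
  acid <- sites$kind == "acid"
  for (k in seq_along(pH_grid)) {
    E <- drop(S %*% .site_eps(sites, pH_grid[k], temperature_K)) + Equad
    w <- exp(-(E - min(E)) / kT)
    xbar <- colSums(S * w) / sum(w)
    prot[k, ] <- ifelse(acid, 1 - xbar, xbar)
  }
  .new_titration_curve(pH_grid, prot, sites, "enumeration")
}

#' Monte-Carlo titration (Metropolis single-flip sampling)
#'
#' Samples the microstate distribution at each grid pH with single-site-flip
#' Metropolis moves, discarding the first 20% of steps as burn-in. Replaces
#' exhaustive enumeration for systems beyond ~20 sites; for small systems it
#' agrees with [enumerate_titration()] to within sampling error.
#'
#' @inheritParams enumerate_titration
#' @param steps Metropolis steps per pH point (>= 1).
#' @param seed integer seed fixing the random stream; identical
#'   `(seed, steps)` give identical curves.
#' @param burn_in fraction of steps discarded before averaging.
#' @return a `titration_curve` with `method = "monte_carlo"`.
#' @export
mc_titration <- function(sites, W = NULL, pH_grid, steps = 1e5L,
                         seed = 1L, temperature_K = 298, burn_in = 0.2) {
  .check_grid(pH_grid)
  if (length(steps) != 1L || !is.finite(steps) || steps < 1) {
    stop("steps must be a single integer >= 1", call. = FALSE)
  }
  n <- nrow(sites)
  if (n == 0L) {
    return(.new_titration_curve(
      pH_grid, matrix(numeric(), length(pH_grid), 0), sites, "monte_carlo",
      mc_steps = as.integer(steps), seed = as.integer(seed)))
  }
  kT <- .KB_KCAL * temperature_K
  M <- .dense_W(W, sites$site_id)
  prot <- matrix(NA_real_, length(pH_grid), n,
                 dimnames = list(NULL, sites$site_id))
  acid <- sites$kind == "acid"
  set.seed(as.integer(seed))
  for (k in seq_along(pH_grid)) {
    eps <- .site_eps(sites, pH_grid[k], temperature_K)
    xbar <- mc_titration_chain(eps, M, as.integer(steps), kT, burn_in)
    prot[k, ] <- ifelse(acid, 1 - xbar, xbar)
  }
  .new_titration_curve(pH_grid, prot, sites, "monte_carlo",
                       mc_steps = as.integer(steps), seed = as.integer(seed))
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("Titration curve (", x$method, "): ", ncol(x$protonated_fraction),
      " site(s) over pH ", min(x$pH_grid), "-", max(x$pH_grid), " (",
      length(x$pH_grid), " points)\n", sep = "")
  if (!is.null(x$mc_steps)) {
    cat("  MC steps per pH:", x$mc_steps, " seed:", x$seed, "\n")
  }
  invisible(x)
}

#' Apparent pKa from a titration curve
#'
#' The pH at which a site's protonated fraction crosses 0.5, by linear
#' interpolation between the bracketing grid points. With site-site coupling
#' this apparent value shifts away from the intrinsic pKa.
#'
#' @param curve a `titration_curve`.
#' @param site_id site to read off (must be present in the curve).
#' @return single numeric; `NA` with attribute `flag = "out-of-range"` when
#'   the curve never crosses 0.5 inside the grid. If the curve crosses more
#'   than once (non-monotone), the lowest-pH crossing is returned with
#'   attribute `flag = "non-monotone"` and a warning.
#' @export
apparent_pKa <- function(curve, site_id) {
  stopifnot(inherits(curve, "titration_curve"))
  if (!site_id %in% colnames(curve$protonated_fraction)) {
    stop("site '", site_id, "' not present in titration curve", call. = FALSE)
  }
  f <- curve$protonated_fraction[, site_id]
  pH <- curve$pH_grid
  d <- f - 0.5
  hit <- which(d == 0)
  cross <- which(d[-length(d)] * d[-1L] < 0)
  n_crossings <- length(hit) + length(cross)
  if (n_crossings == 0L) {
    return(structure(NA_real_, flag = "out-of-range"))
  }
  # candidate pH at each crossing, exact hits first-class
  cand <- c(pH[hit],
            vapply(cross, function(i) {
              pH[i] + (0.5 - f[i]) * (pH[i + 1L] - pH[i]) / (f[i + 1L] - f[i])
            }, numeric(1)))
  res <- min(cand)
  if (n_crossings > 1L) {
    warning("titration curve for '", site_id,
            "' is non-monotone: reporting lowest-pH half-point")
    return(structure(res, flag = "non-monotone"))
  }
  res
}

#' Select pH-activation candidate residues
#'
#' The selection rule for putative activation-switch residues: sites whose
#' intrinsic pKa lies inside a closed window spanning the physiological pH
#' transition (default `[5.0, 7.0]`, the lumenal pH 7 -> 5.2 drop that
#' activates VDE). Each selected site is annotated with its
#' Henderson-Hasselbalch protonation change over the transition; the window is
#' the filter, the change an annotation (for a boundary pKa the change can be
#' below 0.5 even though the site is selected).
#'
#' @param sites a [titratable_sites()] table.
#' @param window numeric length-2, closed pKa window `(low, high)`.
#' @param pH_from,pH_to endpoints of the pH transition.
#' @param pad optional symmetric widening of the window (default 0).
#' @return a `candidate_set`: the selected rows (ordered by chain then residue
#'   number) with columns `label` and `delta_protonation` added, plus the
#'   window and transition used.
#' @export
#' @examples
#' tab <- load_fixture("table1_pka")
#' select_candidates(tab)
select_candidates <- function(sites, window = c(5.0, 7.0),
                              pH_from = 7.0, pH_to = 5.2, pad = 0) {
  stopifnot(length(window) == 2L)
  if (window[1L] > window[2L]) {
    stop("window low must be <= high", call. = FALSE)
  }
  lo <- window[1L] - pad
  hi <- window[2L] + pad
  keep <- nrow(sites) > 0 & sites$pKa >= lo & sites$pKa <= hi
  sel <- sites[keep, , drop = FALSE]
  sel <- sel[order(sel$chain, sel$residue_number), , drop = FALSE]
  sel$label <- site_label(sel)
  sel$delta_protonation <- delta_protonation(sel$pKa, pH_from, pH_to)
  rownames(sel) <- NULL
  sel <- as.data.frame(sel)
  class(sel) <- "data.frame"
  structure(list(selected = sel, window = c(lo, hi),
                 pH_from = pH_from, pH_to = pH_to),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Activation candidates: pKa window [", x$window[1L], ", ",
      x$window[2L], "], pH ", x$pH_from, " -> ", x$pH_to, "\n", sep = "")
  if (nrow(x$selected) == 0L) {
    cat("  (no sites selected)\n")
  } else {
    df <- x$selected[, c("label", "residue_name", "pKa", "std",
                         "delta_protonation")]
    df$delta_protonation <- round(df$delta_protonation, 3)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}
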