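#' @keywords internal
"_PACKAGE"

#' @useDynLib vdeswitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Boltzmann constant in kcal mol^-1 K^-1
.KB_KCAL <- 1.9872041e-3

ACID_RESIDUES <- c("ASP", "GLU", "TYR", "CYS", "CTR")
BASE_RESIDUES <- c("HIS", "LYS", "ARG", "NTR")

# One-letter codes for the residue types that can titrate (plus the common rest,
# used for display labels of non-ionizable substitutions)
.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             NTR = "n", CTR = "c", HOH = "w")

#' Acid/base role of an ionizable residue type
#'
#' Standard assignment used throughout the pipeline: ASP, GLU, TYR, CYS and the
#' C-terminus lose a proton when ionized (acids); HIS, LYS, ARG and the
#' N-terminus gain one (bases).
#'
#' @param residue_name character vector of 3-letter residue codes (or the
#'   pseudo-residues `NTR`/`CTR` for chain termini).
#' @return character vector, `"acid"` or `"base"`; `NA` for residues that do
#'   not titrate.
#' @export
#' @examples
#' residue_kind(c("ASP", "HIS", "GLY"))
residue_kind <- function(residue_name) {
  residue_name <- toupper(residue_name)
  out <- rep(NA_character_, length(residue_name))
  out[residue_name %in% ACID_RESIDUES] <- "acid"
  out[residue_name %in% BASE_RESIDUES] <- "base"
  out
}

.site_id <- function(chain, residue_name, residue_number) {
  paste(chain, toupper(residue_name), residue_number, sep = ":")
}

#' Compact display label for a titratable site
#'
#' Uses the field's one-letter convention (`D86`, `H168`), prefixed with the
#' chain identifier (`B-H121`) when more than one chain is in play.
#'
#' @param sites a `titratable_sites` table (see [titratable_sites()]).
#' @param force_chain always prefix the chain, even for single-chain input.
#' @return character vector of labels.
#' @export
site_label <- function(sites, force_chain = FALSE) {
  one <- .AA3TO1[toupper(sites$residue_name)]
  one[is.na(one)] <- "X"
  lab <- paste0(one, sites$residue_number)
  if (force_chain || length(unique(sites$chain)) > 1L) {
    lab <- paste0(sites$chain, "-", lab)
  }
  lab
}

#' Build a table of titratable sites
#'
#' The central residue table of the titration stage: one row per ionizable
#' group, identified by chain, 3-letter residue name and residue number
#' (1-based, mature-protein numbering), with its acid/base role and intrinsic
#' pKa (the pKa the site would have in the absence of site-site coupling).
#'
#' @param chain character vector of chain identifiers.
#' @param residue_name 3-letter residue codes.
#' @param residue_number integer residue numbers (>= 1).
#' @param pKa intrinsic pKa values (finite).
#' @param std optional per-site pKa standard deviations.
#' @param kind optional explicit `"acid"`/`"base"` roles; defaults to
#'   [residue_kind()] of `residue_name`, which must resolve for every row.
#' @return a `data.frame` of class `titratable_sites` with columns `site_id`,
#'   `chain`, `residue_name`, `residue_number`, `kind`, `pKa`, `std`.
#' @export
#' @examples
#' titratable_sites("A", c("ASP", "HIS"), c(86, 168), c(5.0, 7.0))
titratable_sites <- function(chain, residue_name, residue_number, pKa,
                             std = NA_real_, kind = NULL) {
  n <- length(residue_name)
  chain <- rep_len(as.character(chain), n)
  residue_name <- toupper(as.character(residue_name))
  residue_number <- as.integer(residue_number)
  pKa <- as.numeric(pKa)
  std <- rep_len(as.numeric(std), n)
  if (any(!is.finite(pKa))) {
    stop("intrinsic pKa values must be finite", call. = FALSE)
  }
  if (any(is.na(residue_number) | residue_number < 1L)) {
    stop("residue numbers must be integers >= 1", call. = FALSE)
  }
  if (is.null(kind)) {
    kind <- residue_kind(residue_name)
    if (anyNA(kind)) {
      bad <- unique(residue_name[is.na(kind)])
      stop("cannot infer acid/base kind for residue(s): ",
           paste(bad, collapse = ", "),
           "; pass `kind` explicitly", call. = FALSE)
    }
  } else {
    kind <- match.arg(rep_len(kind, n), c("acid", "base"), several.ok = TRUE)
  }
  out <- data.frame(
    site_id = .site_id(chain, residue_name, residue_number),
    chain = chain, residue_name = residue_name,
    residue_number = residue_number, kind = kind,
    pKa = pKa, std = std,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$site_id)) {
    stop("duplicate site identifiers in table", call. = FALSE)
  }
  class(out) <- c("titratable_sites", "data.frame")
  out
}

#' Read a per-residue pKa table
#'
#' Reads the tab-separated pKa dialect used throughout the pipeline, with
#' header `chain residue_name residue_number pKa std` (`std` optional).
#'
#' @param path path to a TSV file.
#' @return a [titratable_sites()] table.
#' @export
read_pka_table <- function(path) {
  if (!file.exists(path)) {
    stop("pKa table not found: ", path, call. = FALSE)
  }
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("failed to parse pKa table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("chain", "residue_name", "residue_number", "pKa")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("pKa table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$pKa))))
  if (length(bad)) {
    stop("pKa table '", path, "': non-numeric pKa at data line ", bad[1L],
         call. = FALSE)
  }
  titratable_sites(tab$chain, tab$residue_name, tab$residue_number,
                   as.numeric(tab$pKa),
                   std = if ("std" %in% names(tab)) as.numeric(tab$std)
                         else NA_real_)
}

#' @export
print.titratable_sites <- function(x, ...) {
  cat("Titratable sites:", nrow(x), "residue(s),",
      sum(x$kind == "acid"), "acid(s) /", sum(x$kind == "base"), "base(s)\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
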