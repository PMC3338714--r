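# Column conservation of a grouped multiple alignment, consensus, reference
# numbering, and the plant-versus-diatom contrast at candidate positions.

IONIZABLE_RESIDUES <- c("D", "E", "H", "K", "R", "Y", "C")

#' Construct a grouped multiple alignment
#'
#' @param sequences named character vector of aligned sequences (gap `-`),
#'   all the same length.
#' @param groups named character vector mapping sequence id -> group label
#'   (e.g. `"plants"`, `"diatoms"`); every sequence must be labelled.
#' @param reference_id id of the sequence whose ungapped 1-based numbering
#'   defines reference residue numbers (mature-protein convention).
#' @return a `grouped_alignment` object.
#' @export
grouped_alignment <- function(sequences, groups, reference_id) {
  if (!length(sequences)) stop("alignment is empty", call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named", call. = FALSE)
  }
  len <- nchar(sequences)
  if (length(unique(len)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(len), collapse = ", "), call. = FALSE)
  }
  if (!reference_id %in% names(sequences)) {
    stop("reference sequence '", reference_id, "' not in alignment",
         call. = FALSE)
  }
  missing_grp <- setdiff(names(sequences), names(groups))
  if (length(missing_grp)) {
    stop("no group label for sequence(s): ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  }
  structure(list(sequences = toupper(sequences),
                 groups = groups[names(sequences)],
                 reference_id = reference_id,
                 width = len[[1L]]),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat("Grouped alignment:", length(x$sequences), "sequence(s) x", x$width,
      "column(s); reference:", x$reference_id, "\n")
  print(table(x$groups))
  invisible(x)
}

#' Read an alignment with group labels
#'
#' Reads an aligned FASTA or Clustal file via
#' [Biostrings::readAAMultipleAlignment()] and a TSV sidecar with columns
#' `sequence_id group` assigning each sequence to a taxon group.
#'
#' @param alignment_path aligned FASTA or Clustal file.
#' @param groups_path TSV with header `sequence_id group`.
#' @param reference_id reference sequence id; defaults to the first sequence.
#' @param format `"fasta"` or `"clustal"`; guessed from the file when
#'   omitted.
#' @return a [grouped_alignment()].
#' @export
read_alignment <- function(alignment_path, groups_path,
                           reference_id = NULL, format = NULL) {
  if (!file.exists(alignment_path)) {
    stop("alignment file not found: ", alignment_path, call. = FALSE)
  }
  if (is.null(format)) {
    first <- readLines(alignment_path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  aln <- Biostrings::readAAMultipleAlignment(alignment_path, format = format)
  seqs <- as.character(Biostrings::unmasked(aln))
  gtab <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "group")
  if (!all(need %in% names(gtab))) {
    stop("group table '", groups_path,
         "' must have columns sequence_id and group", call. = FALSE)
  }
  groups <- stats::setNames(gtab$group, gtab$sequence_id)
  if (is.null(reference_id)) reference_id <- names(seqs)[1L]
  grouped_alignment(seqs, groups, reference_id)
}

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
}

# modal residue and its non-gap frequency for one column of characters
.column_mode <- function(chars) {
  chars <- chars[chars != "-"]
  if (!length(chars)) return(list(residue = NA_character_, freq = NA_real_))
  tab <- sort(table(chars), decreasing = TRUE)
  # deterministic tie-break: alphabetical among equally frequent residues
  top <- names(tab)[tab == tab[[1L]]]
  list(residue = sort(top)[1L], freq = tab[[1L]] / length(chars))
}

#' Per-column conservation of an alignment
#'
#' Frequency of the modal residue among the non-gap characters of each
#' column. All-gap columns are undefined (`NA`), never 0.
#'
#' @param aln a [grouped_alignment()].
#' @return numeric vector of length `aln$width`, fractions in `[0, 1]` or
#'   `NA` for all-gap columns.
#' @export
column_conservation <- function(aln) {
  M <- .aln_matrix(aln)
  apply(M, 2L, function(col) .column_mode(col)$freq)
}

#' Consensus sequence at an identity threshold
#'
#' Per column, the modal (non-gap) residue when its frequency reaches the
#' threshold, else `"."`. The default threshold 1.0 gives the strict 100%
#' identity consensus.
#'
#' @param aln a [grouped_alignment()].
#' @param identity_threshold required modal frequency, in `(0, 1]`.
#' @return single consensus string; all-gap columns become `"."`.
#' @export
consensus <- function(aln, identity_threshold = 1.0) {
  M <- .aln_matrix(aln)
  chars <- apply(M, 2L, function(col) {
    m <- .column_mode(col)
    if (!is.na(m$freq) && m$freq >= identity_threshold) m$residue else "."
  })
  paste(chars, collapse = "")
}

#' Map alignment columns to reference residue numbers
#'
#' Bijection between the non-gap columns of the reference sequence and its
#' 1-based ungapped residue numbering; reference gap columns map to `NA`.
#'
#' @param aln a [grouped_alignment()].
#' @return list with `column_to_residue` (integer vector, length
#'   `aln$width`, `NA` at reference gaps) and `residue_to_column` (integer
#'   vector, one entry per reference residue).
#' @export
map_to_reference <- function(aln) {
  ref <- strsplit(aln$sequences[[aln$reference_id]], "", fixed = TRUE)[[1L]]
  nongap <- ref != "-"
  col_to_res <- rep(NA_integer_, length(ref))
  col_to_res[nongap] <- seq_len(sum(nongap))
  list(column_to_residue = col_to_res,
       residue_to_column = which(nongap))
}

#' Group contrast at reference positions
#'
#' Classifies candidate positions by how taxon groups differ there:
#' `conserved_all` when a single residue is modal (at the threshold) in every
#' group; otherwise `group_specific_substitution`; upgraded to
#' `non_ionizable_substitution` when at least one group's modal residue falls
#' outside the ionizable set -- the pattern behind plant aspartates being
#' replaced by non-ionizable residues in diatoms.
#'
#' @param aln a [grouped_alignment()].
#' @param positions reference residue numbers to classify.
#' @param ionizable_set one-letter codes counted as ionizable (default
#'   D, E, H, K, R, Y, C).
#' @param threshold within-group modal frequency required to call a group's
#'   residue (default 1.0, strict).
#' @return list with `contrasts` (data.frame: `reference_position`, `column`,
#'   one `modal_<group>` column per group, `classification`) and `skipped`
#'   (positions that could not be mapped).
#' @export
group_contrast <- function(aln, positions,
                           ionizable_set = IONIZABLE_RESIDUES,
                           threshold = 1.0) {
  mp <- map_to_reference(aln)
  n_ref <- length(mp$residue_to_column)
  ok <- positions >= 1L & positions <= n_ref
  skipped <- positions[!ok]
  positions <- positions[ok]
  M <- .aln_matrix(aln)
  rownames(M) <- names(aln$sequences)
  grp_levels <- sort(unique(aln$groups))
  rows <- lapply(positions, function(p) {
    col <- mp$residue_to_column[p]
    modal <- vapply(grp_levels, function(g) {
      m <- .column_mode(M[aln$groups == g, col])
      if (!is.na(m$freq) && m$freq >= threshold) m$residue else NA_character_
    }, character(1))
    called <- modal[!is.na(modal)]
    cls <- if (length(called) == length(grp_levels) &&
               length(unique(called)) == 1L) {
      "conserved_all"
    } else if (any(!is.na(modal) & !(modal %in% ionizable_set))) {
      "non_ionizable_substitution"
    } else {
      "group_specific_substitution"
    }
    c(list(reference_position = p, column = col),
      stats::setNames(as.list(modal), paste0("modal_", grp_levels)),
      list(classification = cls))
  })
  contrasts <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(contrasts)) {
    contrasts <- data.frame(reference_position = integer(),
                            column = integer(),
                            classification = character())
  }
  list(contrasts = contrasts, skipped = skipped)
}
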