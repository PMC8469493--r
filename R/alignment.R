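#' Multiple sequence alignments
#'
#' An `msa` is a minimal aligned-sequence container: unique sequence ids
#' and equal-length rows of characters over `A`-`Z` and the gap character
#' `-` (optionally `.`).  FASTA input/output goes through Biostrings.
#'
#' @param seqs character vector of aligned rows, equal length.
#' @param ids character vector of unique sequence ids (defaults to
#'   `names(seqs)`).
#' @return an object of class `msa`.
#' @export
msa <- function(seqs, ids = names(seqs)) {
  seqs <- toupper(as.character(seqs))
  if (!length(seqs)) stop("alignment must contain at least one sequence")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  if (length(unique(nchar(seqs))) != 1L)
    stop("all aligned rows must have the same length")
  structure(list(ids = as.character(ids), seqs = unname(seqs)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Alignment:", length(x$ids), "sequences x", nchar(x$seqs[1]),
      "columns\n")
  invisible(x)
}

#' @export
dim.msa <- function(x) c(length(x$ids), nchar(x$seqs[1]))

#' Read an aligned FASTA file
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return an [msa()].
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  msa(as.character(ss), ids = names(ss))
}

#' Write an alignment to FASTA
#'
#' @param aln an [msa()].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Remove gap-rich alignment columns
#'
#' Deletes every column whose gap fraction is at or above
#' `gap_fraction`, emulating the trimming step applied after alignment:
#' a gap shared by 10\% or more of the sequences removes the column.  The
#' threshold is inclusive (`>=`), so with 10 sequences a single gap
#' (fraction exactly 0.10) already removes the column, while with 20
#' sequences one gap (0.05) keeps it.  Retained columns keep their
#' original order; the operation is idempotent.
#'
#' @param aln an [msa()].
#' @param gap_fraction removal threshold in (0, 1]; default 0.10.
#' @param dots_as_gaps also treat `.` as a gap character (dialect
#'   tolerance; default `FALSE`).
#' @return the trimmed [msa()].
#' @examples
#' a <- msa(c("AC-A", "ACCA", "AC-A"))
#' dim(trim_gap_columns(a))
#' @export
trim_gap_columns <- function(aln, gap_fraction = 0.10, dots_as_gaps = FALSE) {
  if (!inherits(aln, "msa")) aln <- msa(aln)
  if (gap_fraction <= 0 || gap_fraction > 1)
    stop("'gap_fraction' must be in (0, 1]")
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  gap <- m == "-"
  if (dots_as_gaps) gap <- gap | m == "."
  frac <- colMeans(gap)
  keep <- frac < gap_fraction
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  if (!sum(keep)) out <- rep("", length(aln$ids))
  msa(out, ids = aln$ids)
}
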