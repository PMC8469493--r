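#' Read a tabular BLAST hit file (outfmt 6)
#'
#' Parses the standard 12-column tab-separated BLAST output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`, no header, `#` comment lines ignored) and attaches the
#' per-query hit rank: the 1-based order of appearance within each query,
#' which is how BLAST emits hits (by decreasing bit score).  Ties are never
#' re-sorted; the source-file order is authoritative.
#'
#' @param path path to the tabular hit file.
#' @return a `blast_hits` data frame with columns `query_id`, `subject_id`,
#'   `evalue`, `bitscore`, `rank` (plus the remaining outfmt-6 columns).
#' @export
read_blast_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("query_id", "subject_id", "pident",
                                        "length", "mismatch", "gapopen",
                                        "qstart", "qend", "sstart", "send",
                                        "evalue", "bitscore"))
  as_blast_hits(df)
}

#' Coerce a data frame to a validated BLAST hit table
#'
#' Requires columns `query_id`, `subject_id`, `evalue`, `bitscore`.  A
#' `rank` column is accepted if present (must be unique and contiguous per
#' query) and otherwise derived from row order within each query.
#'
#' @param df a data frame of hits in source-file order.
#' @return a `blast_hits` data frame.
#' @export
as_blast_hits <- function(df) {
  need <- c("query_id", "subject_id", "evalue", "bitscore")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$evalue < 0))
    stop("negative e-value in hit table")
  if (is.null(df$rank)) {
    df$rank <- stats::ave(seq_len(nrow(df)), df$query_id,
                          FUN = seq_along)
  } else {
    ok <- tapply(df$rank, df$query_id,
                 function(r) identical(sort(as.integer(r)), seq_along(r)))
    if (nrow(df) && !all(unlist(ok)))
      stop("ranks must be unique and contiguous within each query")
  }
  df$rank <- as.integer(df$rank)
  class(df) <- c("blast_hits", "data.frame")
  df
}

#' Filter BLAST hits by rank and e-value
#'
#' Implements the candidate-homolog recovery rule: per query, keep the
#' first `max_rank` hits, or all hits with e-value below `evalue_cutoff`.
#' The default reading (`rule = "union"`) keeps a hit if \emph{either}
#' criterion holds, maximising recall of candidate homologs; the stricter
#' single-criterion readings are available as `"rank"` and `"evalue"`.
#' Relative order is always preserved and the output is a subset of the
#' input (the filter is idempotent).
#'
#' @param hits a `blast_hits` table (see [as_blast_hits()]).
#' @param max_rank keep hits with per-query rank `<= max_rank`
#'   (default 1000).
#' @param evalue_cutoff keep hits with `evalue < evalue_cutoff` (strict;
#'   default `1e-10`).
#' @param rule `"union"` (default), `"rank"` or `"evalue"`.
#' @return the retained `blast_hits` rows, original order.
#' @examples
#' h <- as_blast_hits(data.frame(query_id = "q", subject_id = paste0("s", 1:5),
#'                               evalue = c(1e-20, 1e-3, 1e-12, 0.1, 1),
#'                               bitscore = 5:1))
#' filter_blast_hits(h, max_rank = 2)
#' @export
filter_blast_hits <- function(hits, max_rank = 1000, evalue_cutoff = 1e-10,
                              rule = c("union", "rank", "evalue")) {
  rule <- match.arg(rule)
  # a previously filtered table keeps its original (possibly sparse)
  # ranks, so only construct/validate when ranks are absent
  if (!inherits(hits, "blast_hits") || is.null(hits$rank))
    hits <- as_blast_hits(hits)
  if (any(hits$evalue < 0)) stop("negative e-value in hit table")
  if (max_rank < 1) stop("'max_rank' must be a positive integer")
  if (evalue_cutoff <= 0) stop("'evalue_cutoff' must be positive")
  by_rank <- hits$rank <= max_rank
  by_eval <- hits$evalue < evalue_cutoff
  keep <- switch(rule,
                 union  = by_rank | by_eval,
                 rank   = by_rank,
                 evalue = by_eval)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("blast_hits", "data.frame")
  out
}
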