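#' Sum homeologous gene copies onto their reference genes
#'
#' Allopolyploid genomes (e.g. \emph{Camelina sativa}, \emph{Brassica
#' napus}) carry several homeologous copies of each reference gene; their
#' expression values are summed per sample before any cross-gene
#' comparison.  Rows without a map entry pass through unchanged.
#'
#' @param expr numeric matrix, genes x samples (non-negative).
#' @param map data frame with columns `homeolog`, `reference` (see
#'   [read_table()] schema `"homeolog_map"`).
#' @param missing how to handle map homeologs absent from the table:
#'   `"zero"` (default; contribute zero, with a warning) or `"error"`.
#' @return numeric matrix with one row per reference gene (plus the
#'   unmapped pass-through genes), same columns.
#' @export
sum_homeologs <- function(expr, map, missing = c("zero", "error")) {
  missing <- match.arg(missing)
  if (any(expr < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(map$homeolog))
    stop("each homeolog must map to exactly one reference gene")
  absent <- setdiff(map$homeolog, rownames(expr))
  if (length(absent)) {
    if (missing == "error")
      stop("homeolog(s) absent from expression table: ",
           paste(absent, collapse = ", "))
    warning("homeolog(s) absent from expression table, treated as zero: ",
            paste(absent, collapse = ", "))
  }
  mapped <- rownames(expr) %in% map$homeolog
  passthrough <- expr[!mapped, , drop = FALSE]
  refs <- unique(as.character(map$reference))
  summed <- matrix(0, nrow = length(refs), ncol = ncol(expr),
                   dimnames = list(refs, colnames(expr)))
  present <- map[map$homeolog %in% rownames(expr), , drop = FALSE]
  for (i in seq_len(nrow(present))) {
    r <- as.character(present$reference[i])
    summed[r, ] <- summed[r, ] + expr[as.character(present$homeolog[i]), ]
  }
  rbind(passthrough, summed)
}

#' Kinetic SUM: total expression over the developmental kinetic
#'
#' Sums each gene's expression over all seed-development samples and
#' ranks genes by that SUM (descending; ties broken lexicographically by
#' gene id for determinism).
#'
#' @param expr numeric matrix, genes x samples.
#' @return named numeric vector of SUM values with attribute `"rank"`
#'   (integer, 1 = highest SUM).
#' @export
kinetic_sum <- function(expr) {
  if (is.null(dim(expr)) || ncol(expr) < 1L)
    stop("expression table needs at least one sample")
  s <- rowSums(expr)
  ord <- order(-s, rownames(expr))
  rk <- integer(length(s))
  rk[ord] <- seq_along(s)
  attr(s, "rank") <- rk
  s
}

#' Relative SUM percentage against the top-10 reference
#'
#' The mean kinetic SUM of the 10 most-expressed genes is used as the
#' species reference, and every gene's SUM is expressed as a percentage
#' of it: `SUM% = 100 * SUM / mean(SUM of ranks 1..10)`.  By
#' construction the mean SUM% of the ten reference genes is exactly 100.
#' With fewer than 10 genes the reference falls back to the mean over all
#' genes and the result is flagged.
#'
#' @param sums named numeric vector of per-gene SUMs (from
#'   [kinetic_sum()]), or a genes x samples matrix (summed internally).
#' @return an `expression_summary` data frame with columns `gene`, `SUM`,
#'   `rank`, `SUM_pct`, `color` (hex heatmap colour); the reference value
#'   is in attribute `"reference"` and `"reference_all_genes"` flags the
#'   <10-gene fallback.
#' @examples
#' s <- stats::setNames(c(100, 90, 80, 70, 60, 50, 40, 30, 20, 10, 55),
#'                      paste0("g", 1:11))
#' relative_sum_percent(s)$SUM_pct
#' @export
relative_sum_percent <- function(sums) {
  if (is.matrix(sums)) sums <- kinetic_sum(sums)
  if (is.null(names(sums))) stop("'sums' must be named by gene id")
  ord <- order(-sums, names(sums))
  rk <- integer(length(sums))
  rk[ord] <- seq_along(sums)
  fallback <- length(sums) < 10L
  ref_set <- if (fallback) seq_along(sums) else ord[1:10]
  reference <- mean(sums[ref_set])
  if (reference == 0) stop("degenerate expression table: reference SUM is 0")
  pct <- 100 * sums / reference
  out <- data.frame(gene = names(sums), SUM = as.numeric(sums), rank = rk,
                    SUM_pct = as.numeric(pct),
                    color = heatmap_hex(pct),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "reference_all_genes") <- fallback
  class(out) <- c("expression_summary", "data.frame")
  out
}

#' Heatmap colour for a SUM% value
#'
#' Piecewise-linear blue-yellow-red scale with the published anchors:
#' 0 is blue, 1 is yellow, 40 is red; interpolation is linear in the
#' value within each segment and values above 40 are clamped to red.
#'
#' @param sum_percent numeric vector of non-negative SUM% values.
#' @return integer matrix with columns `r`, `g`, `b` in 0..255, one row
#'   per value.
#' @examples
#' heatmap_color(c(0, 1, 40, 100))
#' @export
heatmap_color <- function(sum_percent) {
  if (any(sum_percent < 0)) stop("SUM% values must be non-negative")
  blue <- c(0, 0, 255); yellow <- c(255, 255, 0); red <- c(255, 0, 0)
  one <- function(v) {
    if (v <= 1) blue + (yellow - blue) * v else
      if (v >= 40) red else
        yellow + (red - yellow) * (v - 1) / 39
  }
  out <- t(vapply(sum_percent, one, numeric(3)))
  out <- round(out)
  storage.mode(out) <- "integer"
  colnames(out) <- c("r", "g", "b")
  out
}

#' @rdname heatmap_color
#' @return `heatmap_hex()` returns the same colours as `"#RRGGBB"` hex
#'   strings.
#' @export
heatmap_hex <- function(sum_percent) {
  rgb <- heatmap_color(sum_percent)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' @export
print.expression_summary <- function(x, ...) {
  cat("Expression summary:", nrow(x), "genes; top-10 reference SUM =",
      format(attr(x, "reference")), "\n")
  if (isTRUE(attr(x, "reference_all_genes")))
    cat("  NOTE: <10 genes, reference computed over all genes\n")
  print.data.frame(utils::head(x, 12), ...)
  if (nrow(x) > 12) cat("  ...", nrow(x) - 12, "more rows\n")
  invisible(x)
}

#' Full expression summarisation for one species
#'
#' [sum_homeologs()] (when a map is given) followed by [kinetic_sum()]
#' and [relative_sum_percent()].
#'
#' @param expr numeric matrix, genes x samples.
#' @param homeolog_map optional homeolog map data frame.
#' @param missing passed to [sum_homeologs()].
#' @return an `expression_summary` data frame.
#' @export
summarize_expression <- function(expr, homeolog_map = NULL,
                                 missing = "zero") {
  if (!is.null(homeolog_map))
    expr <- sum_homeologs(expr, homeolog_map, missing = missing)
  relative_sum_percent(kinetic_sum(expr))
}
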