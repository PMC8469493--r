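#' Precision and recall of a delimited ortholog set
#'
#' Compares an [ortholog call][call_orthologs()] against a simulated
#' family's ground truth (leaves whose MRCA with the focal copy is a
#' speciation event, outgroup leaves excluded).
#'
#' @param call an `ortholog_call`.
#' @param truth character vector of ground-truth ortholog leaf labels.
#' @return named numeric vector `c(precision, recall)`.
#' @export
delimitation_accuracy <- function(call, truth) {
  pred <- call$ortholog_leaves
  tp <- length(intersect(pred, truth))
  c(precision = if (length(pred)) tp / length(pred) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}

#' Run the full delimitation on a simulated gene family
#'
#' @param fam a [simulate_gene_family()] result with a surviving focal
#'   copy.
#' @param smap a [species_map()]; defaults to the fixture map.
#' @param ... passed to [call_orthologs()].
#' @return an `ortholog_call`.
#' @export
call_orthologs_sim <- function(fam, smap, ...) {
  if (is.null(fam$tree))
    stop("simulated family has fewer than 2 surviving leaves")
  if (is.na(fam$focal_leaf))
    stop("simulated family has no focal-species leaf")
  gene <- sub("^[^|]*\\|", "", fam$focal_leaf)
  call_orthologs(fam$tree, gene, smap, focal_leaf = fam$focal_leaf, ...)
}

#' Benchmark ortholog delimitation over a duplication/loss rate grid
#'
#' For each `(lambda, mu)` rate pair, simulates `n_families` gene
#' families on the species fixture (conditioned on focal-species
#' survival), runs the full rooting/extraction/delimitation pipeline,
#' and reports mean precision and recall against the simulator's
#' ground-truth ortholog sets.  Families whose outgroup goes fully
#' extinct cannot be rooted; they are skipped and counted in `n_failed`
#' (skip-and-log, never a silent drop).
#'
#' @param rates data frame with columns `lambda`, `mu` (one row per
#'   grid point).
#' @param n_families replicate families per grid point.
#' @param seed integer seed; the full grid is reproducible bit-exactly.
#' @param fixture a [species_tree_fixture()].
#' @return data frame: `lambda`, `mu`, `n_families`, `n_failed`,
#'   `mean_precision`, `mean_recall`, `seed`.
#' @examples
#' \donttest{
#' benchmark_delimitation(data.frame(lambda = 0, mu = 0), n_families = 5,
#'                        seed = 1)
#' }
#' @export
benchmark_delimitation <- function(rates, n_families = 200, seed = 1,
                                   fixture = species_tree_fixture()) {
  stopifnot(all(c("lambda", "mu") %in% names(rates)))
  set.seed(seed)
  out <- lapply(seq_len(nrow(rates)), function(i) {
    lam <- rates$lambda[i]; mu <- rates$mu[i]
    prec <- rec <- numeric(0)
    failed <- 0L
    for (r in seq_len(n_families)) {
      fam <- simulate_gene_family(fixture, lam, mu,
                                  family_id = sprintf("f%03d", r))
      res <- tryCatch(call_orthologs_sim(fam, fixture$map),
                      error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1L; next }
      acc <- delimitation_accuracy(res, fam$truth)
      prec <- c(prec, acc["precision"])
      rec <- c(rec, acc["recall"])
    }
    data.frame(lambda = lam, mu = mu, n_families = n_families,
               n_failed = failed,
               mean_precision = mean(prec), mean_recall = mean(rec),
               seed = seed)
  })
  do.call(rbind, out)
}
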