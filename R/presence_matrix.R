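#' Build the genes-by-species copy-number presence matrix
#'
#' Tabulates a list of [ortholog calls][call_orthologs()] into the
#' genes x species matrix of ortholog copy numbers: cell `(g, s)` is the
#' number of leaves of species `s` in gene `g`'s delimited ortholog set
#' (0 = absence).  Species columns are caller-chosen (typically the
#' studied ingroup species; rooting outgroups are normally excluded since
#' their leaves never enter an ortholog set), and each species may carry a
#' phenotype (`myxospermous`, `non-myxospermous`, `unknown`) while each
#' gene may carry a functional category.
#'
#' @param calls list of `ortholog_call` objects.
#' @param species character vector of species codes (matrix columns).
#' @param genes optional character vector fixing row order; defaults to
#'   the calls' gene ids.  A gene without a call gets an all-zero row.
#' @param phenotypes optional data frame with columns `species`,
#'   `phenotype` (see [read_table()] schema `"phenotype"`).
#' @param categories optional data frame with columns `gene`, `category`.
#' @return an object of class `presence_matrix` with fields `counts`
#'   (integer matrix), `phenotype` (factor per species) and `category`
#'   (character per gene).
#' @export
build_presence_matrix <- function(calls, species, genes = NULL,
                                  phenotypes = NULL, categories = NULL) {
  ids <- vapply(calls, function(cl) cl$gene_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate gene ids in calls: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(genes)) genes <- ids
  species <- as.character(species)
  counts <- matrix(0L, nrow = length(genes), ncol = length(species),
                   dimnames = list(genes, species))
  for (cl in calls) {
    if (!cl$gene_id %in% genes) next
    cc <- cl$copy_counts[names(cl$copy_counts) %in% species]
    counts[cl$gene_id, names(cc)] <- as.integer(cc)
  }
  phen <- factor(rep("unknown", length(species)),
                 levels = c("myxospermous", "non-myxospermous", "unknown"))
  names(phen) <- species
  if (!is.null(phenotypes)) {
    hit <- match(species, phenotypes$species)
    phen[!is.na(hit)] <- as.character(phenotypes$phenotype[hit[!is.na(hit)]])
  }
  cat_by_gene <- stats::setNames(rep(NA_character_, length(genes)), genes)
  if (!is.null(categories)) {
    hit <- match(genes, categories$gene)
    cat_by_gene[!is.na(hit)] <-
      as.character(categories$category[hit[!is.na(hit)]])
  }
  structure(list(counts = counts, phenotype = phen,
                 category = cat_by_gene),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Presence matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "species\n")
  cat("  copies 1..", max(x$counts), "; absences: ",
      sum(x$counts == 0L), " cells\n", sep = "")
  cat("  phenotyped species:",
      sum(x$phenotype != "unknown"), "of", length(x$phenotype), "\n")
  invisible(x)
}

#' @export
summary.presence_matrix <- function(object, ...) {
  pres <- object$counts >= 1L
  data.frame(species = colnames(object$counts),
             phenotype = as.character(object$phenotype),
             n_present = colSums(pres),
             presence_fraction = colMeans(pres),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Heatmap of a presence matrix
#'
#' Base-graphics image mirroring the published encoding: absence in
#' yellow, presence in a light-blue to dark-purple gradient with copy
#' number.
#'
#' @param x a `presence_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.presence_matrix <- function(x, ...) {
  m <- x$counts
  top <- max(2L, max(m))
  pal <- c("#FFEE55",
           grDevices::colorRampPalette(c("#9FD8FF", "#3C1361"))(top))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, zlim = c(0, top), axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.5)
  invisible(x)
}

#' Per-gene presence-by-phenotype contrast
#'
#' For each gene, cross-tabulates ortholog presence (copy count >= 1)
#' against the seed-mucilage phenotype over the phenotyped species
#' (species with unknown phenotype are excluded), and reports the
#' difference in presence proportions (myxospermous minus
#' non-myxospermous).  No hypothesis test is attached: the 2x2 tables are
#' emitted so any test can be applied downstream.
#'
#' @param pm a [build_presence_matrix()] result.
#' @return a data frame of class `gene_contrast` with columns `gene`,
#'   `present_myxo`, `absent_myxo`, `present_nonmyxo`, `absent_nonmyxo`,
#'   `prop_diff`; the list of 2x2 tables is in attribute `"tables"`.
#' @export
contrast_by_phenotype <- function(pm) {
  keep <- pm$phenotype != "unknown"
  phen <- droplevels(pm$phenotype[keep])
  if (length(unique(phen)) < 2L)
    stop("degenerate contrast: need both phenotypes among scored species")
  pres <- pm$counts[, keep, drop = FALSE] >= 1L
  myxo <- phen == "myxospermous"
  tabs <- vector("list", nrow(pres))
  out <- data.frame(gene = rownames(pres),
                    present_myxo = rowSums(pres[, myxo, drop = FALSE]),
                    absent_myxo = sum(myxo) -
                      rowSums(pres[, myxo, drop = FALSE]),
                    present_nonmyxo = rowSums(pres[, !myxo, drop = FALSE]),
                    absent_nonmyxo = sum(!myxo) -
                      rowSums(pres[, !myxo, drop = FALSE]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$prop_diff <- out$present_myxo / sum(myxo) -
    out$present_nonmyxo / sum(!myxo)
  for (i in seq_len(nrow(out))) {
    tabs[[i]] <- matrix(c(out$present_myxo[i], out$absent_myxo[i],
                          out$present_nonmyxo[i], out$absent_nonmyxo[i]),
                        nrow = 2,
                        dimnames = list(c("present", "absent"),
                                        c("myxospermous",
                                          "non-myxospermous")))
  }
  names(tabs) <- out$gene
  attr(out, "tables") <- tabs
  class(out) <- c("gene_contrast", "data.frame")
  out
}

#' Per-category presence summaries
#'
#' Groups genes by functional category and summarises ortholog presence
#' per category and phenotype: the mean presence fraction (over genes and
#' species of that phenotype) plus the per-category count of absences
#' (losses).  Genes with no category are bucketed as `"uncategorized"`
#' with a warning.
#'
#' @param pm a [build_presence_matrix()] result.
#' @return a data frame with one row per category: `category`, `n_genes`,
#'   `presence_myxo`, `presence_nonmyxo`, `presence_all`, `n_losses`.
#' @export
group_by_category <- function(pm) {
  cats <- pm$category
  if (anyNA(cats) || any(!nzchar(cats))) {
    warning("genes without a category bucketed as 'uncategorized'")
    cats[is.na(cats) | !nzchar(cats)] <- "uncategorized"
  }
  pres <- pm$counts >= 1L
  myxo <- pm$phenotype == "myxospermous"
  nonmyxo <- pm$phenotype == "non-myxospermous"
  ucats <- unique(cats)
  res <- lapply(ucats, function(cc) {
    rows <- pres[cats == cc, , drop = FALSE]
    data.frame(category = cc, n_genes = nrow(rows),
               presence_myxo = if (any(myxo))
                 mean(rows[, myxo, drop = FALSE]) else NA_real_,
               presence_nonmyxo = if (any(nonmyxo))
                 mean(rows[, nonmyxo, drop = FALSE]) else NA_real_,
               presence_all = mean(rows),
               n_losses = sum(!rows),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
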