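#' Ortholog-calling workflow over a set of gene-family trees
#'
#' Runs [call_orthologs()] on every gene-family tree, tabulates the calls
#' into the presence matrix, and (when phenotypes are available for both
#' phenotype classes) computes the per-gene phenotype contrasts and the
#' per-category summaries.  Families that fail (missing outgroup or focal
#' leaf, unresolvable rooting) are skipped and logged per gene, never
#' silently dropped.
#'
#' @param trees named list of `"phylo"` trees (names = toolbox gene ids)
#'   or a character vector of newick file paths (gene id = file base
#'   name).
#' @param smap a [species_map()].
#' @param species species codes forming the matrix columns.
#' @param phenotypes,categories optional tables (see [read_table()]).
#' @param outdir optional output directory; when given,
#'   `ortholog_calls.tsv`, `presence_matrix.tsv` and (if computed)
#'   `phenotype_contrast.tsv`, `category_summary.tsv` are written.
#' @return (invisibly) a list with `calls`, `matrix`, `contrast`,
#'   `categories`, `failed` (named character vector of error messages).
#' @export
run_ortholog_pipeline <- function(trees, smap, species, phenotypes = NULL,
                                  categories = NULL, outdir = NULL) {
  if (is.character(trees)) {
    paths <- trees
    trees <- lapply(paths, read_newick)
    names(trees) <- sub("\\.(nwk|newick|tre|tree)$", "", basename(paths))
  }
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    stop("'trees' must be named by toolbox gene id")
  calls <- list()
  failed <- character(0)
  for (g in names(trees)) {
    res <- tryCatch(call_orthologs(trees[[g]], g, smap),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) failed[g] <- res else calls[[g]] <- res
  }
  pm <- build_presence_matrix(calls, species = species,
                              genes = names(trees),
                              phenotypes = phenotypes,
                              categories = categories)
  contrast <- NULL
  catsum <- NULL
  if (!is.null(phenotypes) &&
      length(unique(pm$phenotype[pm$phenotype != "unknown"])) >= 2L)
    contrast <- contrast_by_phenotype(pm)
  if (!is.null(categories))
    catsum <- suppressWarnings(group_by_category(pm))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(do.call(rbind, lapply(calls, as.data.frame)),
              file.path(outdir, "ortholog_calls.tsv"))
    write_tsv(pm$counts, file.path(outdir, "presence_matrix.tsv"))
    if (!is.null(contrast))
      write_tsv(as.data.frame(contrast),
                file.path(outdir, "phenotype_contrast.tsv"))
    if (!is.null(catsum))
      write_tsv(catsum, file.path(outdir, "category_summary.tsv"))
  }
  invisible(list(calls = calls, matrix = pm, contrast = contrast,
                 categories = catsum, failed = failed))
}

#' Expression-summary workflow over one or more species tables
#'
#' Applies homeolog summation (where a map is supplied), the kinetic
#' SUM, ranking, top-10 reference and SUM% to each species table, and
#' assembles the combined per-gene SUM% matrix used for the cross-species
#' heatmap.
#'
#' @param tables named list of expression matrices (genes x samples), one
#'   per species, or named character vector of TSV paths.
#' @param homeolog_maps optional named list of homeolog maps (names
#'   matching `tables`).
#' @param outdir optional output directory; writes
#'   `expression_summary_<species>.tsv` and `sum_percent_matrix.tsv`.
#' @return (invisibly) a list with `summaries` (per species) and
#'   `sum_percent` (genes x species data frame of SUM%).
#' @export
run_expression_pipeline <- function(tables, homeolog_maps = NULL,
                                    outdir = NULL) {
  if (is.character(tables)) {
    paths <- tables
    tables <- lapply(paths, read_table, schema = "expression")
    if (is.null(names(paths)))
      names(tables) <- sub("\\.tsv$", "", basename(paths))
  }
  if (is.null(names(tables))) stop("'tables' must be named by species")
  summaries <- lapply(names(tables), function(sp) {
    summarize_expression(tables[[sp]],
                         homeolog_map = homeolog_maps[[sp]])
  })
  names(summaries) <- names(tables)
  genes <- sort(unique(unlist(lapply(summaries, function(s) s$gene))))
  mat <- sapply(summaries, function(s)
    s$SUM_pct[match(genes, s$gene)])
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, names(tables)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (sp in names(summaries))
      write_tsv(as.data.frame(summaries[[sp]]),
                file.path(outdir, paste0("expression_summary_", sp,
                                         ".tsv")))
    write_tsv(mat, file.path(outdir, "sum_percent_matrix.tsv"))
  }
  invisible(list(summaries = summaries, sum_percent = mat))
}
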