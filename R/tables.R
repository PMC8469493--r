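#' Read a typed pipeline table
#'
#' All tabular side inputs of the pipeline are UTF-8 TSV files with a
#' header row; `#`-prefixed lines are comments.  `read_table()` validates
#' the mandatory columns of the requested schema, types them, and keeps
#' any extra columns as opaque metadata.
#'
#' Schemas:
#' \describe{
#'   \item{`species_map`}{columns `leaf`, `species` — explicit leaf-label
#'     to species-code mapping.}
#'   \item{`phenotype`}{columns `species`, `phenotype` with levels
#'     `myxospermous`, `non-myxospermous`, `unknown` (seed-mucilage
#'     extrusion ability per species).}
#'   \item{`homeolog_map`}{columns `homeolog`, `reference` — many-to-one
#'     map from homeologous gene copies to their reference gene.}
#'   \item{`expression`}{column `gene` plus one numeric column per sample;
#'     returned as a numeric matrix (genes x samples).}
#'   \item{`toolbox_genes`}{columns `gene`, `category` — the focal-species
#'     toolbox gene list with functional categories.}
#' }
#'
#' @param path TSV file path.
#' @param schema one of `"species_map"`, `"phenotype"`, `"homeolog_map"`,
#'   `"expression"`, `"toolbox_genes"`.
#' @return a typed data frame (or numeric matrix for `"expression"`).
#' @export
read_table <- function(path, schema = c("species_map", "phenotype",
                                        "homeolog_map", "expression",
                                        "toolbox_genes")) {
  schema <- match.arg(schema)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- switch(schema,
                 species_map   = c("leaf", "species"),
                 phenotype     = c("species", "phenotype"),
                 homeolog_map  = c("homeolog", "reference"),
                 expression    = "gene",
                 toolbox_genes = c("gene", "category"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema '", schema, "': missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), need)

  if (schema == "expression") {
    genes <- as.character(df$gene)
    if (anyDuplicated(genes)) stop("duplicate gene ids in expression table")
    m <- as.matrix(df[, extra, drop = FALSE])
    storage.mode(m) <- "double"
    if (any(m < 0, na.rm = TRUE))
      stop("expression values must be non-negative")
    rownames(m) <- genes
    return(m)
  }
  if (schema == "phenotype") {
    lev <- c("myxospermous", "non-myxospermous", "unknown")
    bad <- setdiff(unique(df$phenotype), lev)
    if (length(bad))
      stop("unknown phenotype level(s): ", paste(bad, collapse = ", "))
    df$phenotype <- factor(df$phenotype, levels = lev)
  }
  if (schema == "homeolog_map" && anyDuplicated(df$homeolog))
    stop("each homeolog must map to exactly one reference gene")
  out <- df[, need, drop = FALSE]
  if (length(extra)) attr(out, "extra") <- df[, extra, drop = FALSE]
  attr(out, "schema") <- schema
  out
}

#' Write a data frame as pipeline TSV
#'
#' @param x data frame or matrix.
#' @param path output path.
#' @param rowname_col when `x` is a matrix, the header of the rownames
#'   column (default `"gene"`).
#' @export
write_tsv <- function(x, path, rowname_col = "gene") {
  if (is.matrix(x)) {
    x <- data.frame(rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
    names(x)[1] <- rowname_col
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
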