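#' Leaf-to-species mapping with declared species roles
#'
#' A `species_map` ties gene-tree leaf labels to species codes and declares
#' the three species roles the delimitation algorithm needs: the outgroup
#' species used for rooting (non-Brassicaceae, e.g. \emph{Medicago
#' truncatula} `Mtru` and \emph{Linum usitatissimum} `Lusi`), the
#' early-diverging anchor species that bounds the ortholog sub-clade
#' (\emph{Aethionema arabicum} `Aara`), and the focal species whose toolbox
#' gene seeds the search (\emph{Arabidopsis thaliana} `Atha`).
#'
#' When `mapping` is `NULL` the leaf-label convention
#' `"SPECIESCODE|geneID"` is assumed: the species code is everything before
#' the first `"|"` (a label without `"|"` is its own species code).  An
#' explicit mapping (named character vector, names = leaf labels) overrides
#' the convention for the labels it covers.
#'
#' @param outgroup character vector of outgroup species codes (>= 1).
#' @param anchor character vector of anchor species codes (usually one).
#' @param focal single focal species code.
#' @param mapping optional named character vector, leaf label -> species code.
#'
#' @return an object of class `species_map`.
#' @examples
#' sm <- species_map(outgroup = c("Mtru", "Lusi"), anchor = "Aara",
#'                   focal = "Atha")
#' leaf_species(c("Atha|MUM4", "Mtru|g001"), sm)
#' @export
species_map <- function(outgroup, anchor, focal, mapping = NULL) {
  outgroup <- as.character(outgroup)
  anchor <- as.character(anchor)
  focal <- as.character(focal)
  if (length(focal) != 1L)
    stop("'focal' must be a single species code")
  codes <- c(outgroup, anchor, focal)
  if (any(!nzchar(codes)) || anyNA(codes))
    stop("species codes must be non-empty")
  if (length(intersect(outgroup, anchor)) || focal %in% c(outgroup, anchor))
    stop("outgroup, anchor and focal species codes must be pairwise distinct")
  if (!is.null(mapping)) {
    if (is.null(names(mapping)) || anyDuplicated(names(mapping)))
      stop("'mapping' must be a named vector with unique leaf labels")
    mapping <- vapply(mapping, as.character, character(1))
  }
  structure(list(outgroup = outgroup, anchor = anchor, focal = focal,
                 mapping = mapping),
            class = "species_map")
}

#' @export
print.species_map <- function(x, ...) {
  cat("Leaf-species map\n")
  cat("  outgroup:", paste(x$outgroup, collapse = ", "), "\n")
  cat("  anchor:  ", paste(x$anchor, collapse = ", "), "\n")
  cat("  focal:   ", x$focal, "\n")
  if (!is.null(x$mapping))
    cat("  explicit mapping for", length(x$mapping), "leaves\n")
  else
    cat("  leaf convention: SPECIESCODE|geneID\n")
  invisible(x)
}

#' Species code of each leaf label
#'
#' @param labels character vector of leaf labels.
#' @param smap a [species_map()].
#' @return character vector of species codes, same length as `labels`.
#' @export
leaf_species <- function(labels, smap) {
  sp <- sub("\\|.*$", "", labels)
  if (!is.null(smap$mapping)) {
    hit <- labels %in% names(smap$mapping)
    sp[hit] <- unname(smap$mapping[labels[hit]])
  }
  sp
}

is_outgroup_leaf <- function(labels, smap)
  leaf_species(labels, smap) %in% smap$outgroup

is_anchor_leaf <- function(labels, smap)
  leaf_species(labels, smap) %in% smap$anchor
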