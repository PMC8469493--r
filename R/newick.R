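#' Read a newick tree file
#'
#' Thin, validating wrapper around [ape::read.tree()].  Trees are returned
#' as `ape` `"phylo"` objects, the substrate of all tree operations in this
#' package.  Branch lengths and internal-node labels (bootstrap supports)
#' are preserved.  Unrooted trees (basal multifurcation) are accepted and
#' can be queried with [ape::is.rooted()].
#'
#' @param path path to a newick file, or a newick string ending in `";"`.
#' @return a `"phylo"` tree.
#' @section Errors:
#' Duplicate leaf labels raise an error naming the offending label;
#' malformed newick (unbalanced parentheses, missing terminal `";"`) raises
#' a parse error reporting the character offset of the problem.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_newick <- function(path) {
  txt <- if (grepl(";\\s*$", path[1]) && !file.exists(path[1])) {
    path[1]
  } else {
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  .check_newick_syntax(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree))
    stop("newick parse error: ape could not interpret the string")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf label: '", dup[1], "'")
  tree
}

# cheap structural scan so parse failures carry a character offset
.check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth,
         " unclosed '(' at end of string (character ", length(chars), ")")
  if (!grepl(";", txt, fixed = TRUE))
    stop("newick parse error: missing terminal ';' at character ",
         length(chars))
  invisible(TRUE)
}

#' Write a tree to newick
#'
#' @param tree a `"phylo"` tree.
#' @param path output path; when `NULL` the newick string is returned.
#' @return invisibly, the newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

# tip indices below each node (tips index themselves); list over all nodes
.node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  out <- vector("list", nnode)
  out[seq_len(ntip)] <- as.list(seq_len(ntip))
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge)))
    out[[edge[i, 1]]] <- c(out[[edge[i, 1]]], out[[edge[i, 2]]])
  out
}

# parent lookup: parent[node] = parent node id, 0 for the root
.parents <- function(tree) {
  nnode <- length(tree$tip.label) + tree$Nnode
  p <- integer(nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}
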