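#' Root a gene-family tree on its outgroup
#'
#' Places the root on the branch separating the outgroup species
#' (non-Brassicaceae rooting taxa, e.g. \emph{M. truncatula} and
#' \emph{L. usitatissimum}) from the ingroup.  When the outgroup leaves do
#' not form a clade on the unrooted tree — common in gene families with
#' ancient duplications — the root is placed on the edge maximising
#' (outgroup leaves on the outgroup side) minus (ingroup leaves on that
#' side); ties are broken deterministically by the edge topologically
#' closest to the first outgroup leaf in input order.
#'
#' @param tree a `"phylo"` tree (rooted trees are unrooted first).
#' @param smap a [species_map()].
#' @return a rooted `"phylo"` tree with attribute
#'   `outgroup_monophyletic` (logical).  Leaf set and ingroup bipartitions
#'   are unchanged.
#' @section Errors:
#' A tree without any outgroup leaf raises `"outgroup absent"`; such
#' families are reported unresolvable rather than silently rooted.
#' @export
root_on_outgroup <- function(tree, smap) {
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  tips <- tree$tip.label
  og <- is_outgroup_leaf(tips, smap)
  if (!any(og))
    stop("outgroup absent: no leaf from species {",
         paste(smap$outgroup, collapse = ", "), "}")
  if (sum(!og) < 2L)
    stop("need at least two ingroup leaves to root")
  ntip <- length(tips)
  tipsets <- .node_tipsets(tree)
  edge <- tree$edge

  # each edge offers two candidate outgroup sides: the tipset below its
  # child and the complement
  n_edge <- nrow(edge)
  sides <- vector("list", 2L * n_edge)
  side_edge <- integer(2L * n_edge)
  for (i in seq_len(n_edge)) {
    below <- tipsets[[edge[i, 2L]]]
    sides[[2L * i - 1L]] <- below
    sides[[2L * i]] <- setdiff(seq_len(ntip), below)
    side_edge[c(2L * i - 1L, 2L * i)] <- i
  }
  score <- vapply(sides, function(s) sum(og[s]) - sum(!og[s]), numeric(1))
  proper <- lengths(sides) >= 1L & lengths(sides) < ntip
  score[!proper] <- -Inf
  best <- which(score == max(score))
  if (length(best) > 1L) {
    first_og <- which(og)[1L]
    topo <- tree
    topo$edge.length <- rep(1, n_edge)
    d <- ape::dist.nodes(topo)[first_og, ]
    edist <- vapply(best, function(j)
      min(d[edge[side_edge[j], 1L]], d[edge[side_edge[j], 2L]]), numeric(1))
    best <- best[order(edist, best)][1L]
  }
  side <- sides[[best]]
  rooted <- ape::root(tree, outgroup = tips[side], resolve.root = TRUE,
                      edgelabel = TRUE)
  attr(rooted, "outgroup_monophyletic") <- setequal(side, which(og))
  attr(rooted, "outgroup_side") <- tips[side]
  rooted
}

#' Extract the focal clade of a rooted gene-family tree
#'
#' Walks rootward from the focal leaf and returns the maximal clade that
#' contains it but no outgroup leaf: the focal gene's side of the tree up
#' to (but excluding) the rooting taxa.  Paralogous ingroup sub-clades are
#' deliberately retained at this stage; [delimit_ortholog_subclade()]
#' separates them.
#'
#' @param tree a rooted `"phylo"` tree (see [root_on_outgroup()]).
#' @param focal_leaf leaf label of the focal-species toolbox gene.
#' @param smap a [species_map()].
#' @return a `"phylo"` clade; a single-leaf clade (the focal leaf is
#'   sister to an outgroup leaf) is returned as a `"phylo_tip"` stub with
#'   a `tip.label` field.
#' @export
extract_focal_clade <- function(tree, focal_leaf, smap) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ti <- match(focal_leaf, tree$tip.label)
  if (is.na(ti)) stop("focal leaf '", focal_leaf, "' not in tree")
  og <- is_outgroup_leaf(tree$tip.label, smap)
  tipsets <- .node_tipsets(tree)
  par <- .parents(tree)
  node <- ti
  repeat {
    p <- par[node]
    if (p == 0L || any(og[tipsets[[p]]])) break
    node <- p
  }
  leaves <- tree$tip.label[tipsets[[node]]]
  if (length(leaves) == 1L)
    return(structure(list(tip.label = leaves), class = "phylo_tip"))
  if (node == length(tree$tip.label) + 1L) tree else
    ape::extract.clade(tree, node)
}

#' Leaf labels of a clade
#'
#' Works for both regular `"phylo"` clades and the single-leaf
#' `"phylo_tip"` stubs returned by [extract_focal_clade()].
#'
#' @param clade a `"phylo"` or `"phylo_tip"` object.
#' @return character vector of leaf labels.
#' @export
clade_leaves <- function(clade) {
  clade$tip.label
}

#' Delimit the ortholog sub-clade bounded by the closest anchor sequence
#'
#' Within the focal clade, the ortholog set of the focal toolbox gene is
#' the \emph{smallest} clade containing the focal leaf and at least one
#' anchor-species sequence (the early-diverging Brassicaceae species,
#' \emph{A. arabicum} by default).  "Closest" is interpreted topologically:
#' the walk from the focal leaf rootward stops at the first node whose
#' leaf set includes an anchor leaf.  A patristic interpretation (anchor
#' leaf at minimal branch-length distance from the focal leaf) is
#' available via `anchor_choice = "patristic"`.  When the clade contains
#' no anchor sequence at all the whole clade is returned with
#' `fallback_used = TRUE`: species lacking anchor co-orthologs are still
#' scored rather than dropped.
#'
#' @param clade a `"phylo"` clade from [extract_focal_clade()] (or a
#'   whole rooted tree free of outgroup leaves).
#' @param focal_leaf leaf label of the focal toolbox gene.
#' @param smap a [species_map()].
#' @param gene_id toolbox gene identifier recorded in the call (defaults
#'   to the gene part of `focal_leaf`).
#' @param anchor_choice `"topological"` (default) or `"patristic"`.
#' @return an object of class `ortholog_call`: the ortholog leaf set,
#'   per-species copy counts and provenance flags.
#' @export
delimit_ortholog_subclade <- function(clade, focal_leaf, smap,
                                      gene_id = NULL,
                                      anchor_choice = c("topological",
                                                        "patristic")) {
  anchor_choice <- match.arg(anchor_choice)
  if (is.null(gene_id))
    gene_id <- sub("^[^|]*\\|", "", focal_leaf)
  if (inherits(clade, "phylo_tip")) {
    if (!focal_leaf %in% clade$tip.label)
      stop("focal leaf '", focal_leaf, "' not in clade")
    return(new_ortholog_call(gene_id, focal_leaf, clade$tip.label, smap,
                             anchor_found = FALSE, fallback_used = TRUE))
  }
  tips <- clade$tip.label
  ti <- match(focal_leaf, tips)
  if (is.na(ti)) stop("focal leaf '", focal_leaf, "' not in clade")
  anc <- is_anchor_leaf(tips, smap)
  tipsets <- .node_tipsets(clade)
  par <- .parents(clade)

  if (!any(anc)) {
    return(new_ortholog_call(gene_id, focal_leaf, tips, smap,
                             anchor_found = FALSE, fallback_used = TRUE))
  }
  if (anchor_choice == "topological") {
    node <- ti
    while (!any(anc[tipsets[[node]]])) node <- par[node]
  } else {
    d <- ape::dist.nodes(clade)[ti, which(anc)]
    a_star <- which(anc)[which.min(d)]
    node <- ape::getMRCA(clade, c(ti, a_star))
  }
  new_ortholog_call(gene_id, focal_leaf, tips[tipsets[[node]]], smap,
                    anchor_found = TRUE, fallback_used = FALSE)
}

#' Construct an ortholog call record
#'
#' @param gene_id toolbox gene id.
#' @param focal_leaf focal leaf label (must belong to the ortholog set).
#' @param ortholog_leaves character vector of delimited leaf labels.
#' @param smap a [species_map()].
#' @param anchor_found,fallback_used,outgroup_found,outgroup_monophyletic
#'   provenance flags.
#' @return an `ortholog_call`.
#' @export
new_ortholog_call <- function(gene_id, focal_leaf, ortholog_leaves, smap,
                              anchor_found = FALSE, fallback_used = FALSE,
                              outgroup_found = NA,
                              outgroup_monophyletic = NA) {
  if (!focal_leaf %in% ortholog_leaves)
    stop("focal leaf must belong to the ortholog set")
  counts <- table(leaf_species(ortholog_leaves, smap))
  copy_counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(gene_id = gene_id,
                 focal_leaf = focal_leaf,
                 ortholog_leaves = ortholog_leaves,
                 copy_counts = copy_counts,
                 flags = list(outgroup_found = outgroup_found,
                              outgroup_monophyletic = outgroup_monophyletic,
                              anchor_found = anchor_found,
                              fallback_used = fallback_used)),
            class = "ortholog_call")
}

#' @export
print.ortholog_call <- function(x, ...) {
  cat("Ortholog call for", x$gene_id, "\n")
  cat("  focal leaf:     ", x$focal_leaf, "\n")
  cat("  orthologs:      ", length(x$ortholog_leaves), "leaves in",
      length(x$copy_counts), "species\n")
  fl <- unlist(x$flags)
  cat("  flags:          ",
      paste(names(fl), fl, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ortholog_call <- function(x, ...) {
  data.frame(gene = x$gene_id, focal_leaf = x$focal_leaf,
             n_orthologs = length(x$ortholog_leaves),
             n_species = length(x$copy_counts),
             outgroup_found = x$flags$outgroup_found,
             outgroup_monophyletic = x$flags$outgroup_monophyletic,
             anchor_found = x$flags$anchor_found,
             fallback_used = x$flags$fallback_used,
             stringsAsFactors = FALSE)
}

#' Full ortholog-calling pipeline for one gene family
#'
#' Composition of [root_on_outgroup()], [extract_focal_clade()] and
#' [delimit_ortholog_subclade()]: roots the gene-family tree on the
#' outgroup branch, extracts the clade containing the focal toolbox gene
#' up to the outgroup sequences, and delimits the ortholog sub-clade
#' bounded by the closest anchor-species sequence.
#'
#' @param tree a `"phylo"` gene-family tree.
#' @param toolbox_gene toolbox gene id; the focal leaf is the
#'   focal-species leaf named `"<focal>|<toolbox_gene>"` (or, if the tree
#'   has exactly one focal-species leaf, that leaf).
#' @param smap a [species_map()].
#' @param anchor_choice passed to [delimit_ortholog_subclade()].
#' @param focal_leaf optional explicit focal leaf label, bypassing the
#'   gene-id search (useful for simulated families).
#' @return an `ortholog_call`; errors from any step are annotated with
#'   the toolbox gene id.
#' @export
call_orthologs <- function(tree, toolbox_gene, smap,
                           anchor_choice = "topological",
                           focal_leaf = NULL) {
  res <- tryCatch({
    if (is.null(focal_leaf))
      focal_leaf <- .find_focal_leaf(tree, toolbox_gene, smap)
    else if (!focal_leaf %in% tree$tip.label)
      stop("focal leaf '", focal_leaf, "' not in tree")
    rooted <- root_on_outgroup(tree, smap)
    clade <- extract_focal_clade(rooted, focal_leaf, smap)
    call <- delimit_ortholog_subclade(clade, focal_leaf, smap,
                                      gene_id = toolbox_gene,
                                      anchor_choice = anchor_choice)
    call$flags$outgroup_found <- TRUE
    call$flags$outgroup_monophyletic <- attr(rooted, "outgroup_monophyletic")
    call
  }, error = function(e) {
    stop(toolbox_gene, ": ", conditionMessage(e), call. = FALSE)
  })
  res
}

.find_focal_leaf <- function(tree, toolbox_gene, smap) {
  tips <- tree$tip.label
  focal <- tips[leaf_species(tips, smap) == smap$focal]
  if (!length(focal))
    stop("no leaf from focal species '", smap$focal, "'")
  gene_part <- sub("^[^|]*\\|", "", focal)
  hit <- focal[gene_part == toolbox_gene | focal == toolbox_gene]
  if (length(hit) == 1L) return(hit)
  if (length(hit) > 1L)
    stop("ambiguous focal leaf for '", toolbox_gene, "': ",
         paste(hit, collapse = ", "))
  # "gene.copy" convention: several focal copies of the same family;
  # the lowest-sorting copy seeds the call (the simulator's convention)
  pre <- focal[startsWith(gene_part, paste0(toolbox_gene, "."))]
  if (length(pre)) return(sort(pre)[1L])
  if (length(focal) == 1L) return(focal)
  stop("focal-species leaf for toolbox gene '", toolbox_gene,
       "' not found")
}
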