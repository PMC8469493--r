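#' Brassicaceae-like species tree fixture
#'
#' A fixed, rooted, ultrametric 34-species tree of depth 1.0 emulating the
#' study design: two non-Brassicaceae outgroup species (`Mtru`, `Lusi`)
#' sister to everything else, an early-diverging anchor clade (`Aara`,
#' `Agra`, the \emph{Aethionema} species), and three ingroup lineages of
#' ten species each mirroring the major Brassicaceae lineages (lineage 1
#' carries the focal species `Atha`).  Topology is the stated study
#' structure; branch lengths are declared fixture constants.
#'
#' @return an object of class `species_fixture` with fields `tree`
#'   (`"phylo"`, ultrametric, depth 1), `species` (all 34 codes),
#'   `ingroup`, `lineages` (named list), and the default [species_map()].
#' @examples
#' fx <- species_tree_fixture()
#' fx$map
#' @export
species_tree_fixture <- function() {
  l1 <- c("Atha", "Alyr", "Ahal", "Csat", "Crub", "Cgra", "Cbur", "Bstr",
          "Cori", "Aalp")
  l2 <- c("Bnap", "Bnig", "Bole", "Brap", "Bjun", "Rsat", "Scar", "Spin",
          "Tarv", "Esal")
  l3 <- c("Sirr", "Dsop", "Lala", "Chir", "Cfle", "Npav", "Ipin", "Dstr",
          "Ttet", "Mmac")
  node <- function(age, ...) list(age = age, children = list(...))
  ladder <- function(tips, crown, step = 0.045) {
    ages <- seq(crown, by = -step, length.out = length(tips) - 1L)
    nd <- node(ages[length(ages)], tips[1L], tips[2L])
    for (i in seq(3L, length(tips)))
      nd <- node(ages[length(tips) - i + 1L], nd, tips[i])
    nd
  }
  root <- node(1.0,
               node(0.5, "Mtru", "Lusi"),
               node(0.85,
                    node(0.30, "Aara", "Agra"),
                    node(0.70,
                         ladder(l1, 0.50),
                         node(0.65,
                              ladder(l2, 0.50),
                              ladder(l3, 0.50)))))
  render <- function(nd, parent_age) {
    if (is.character(nd))
      return(sprintf("%s:%.6f", nd, parent_age))
    kids <- paste(vapply(nd$children, render, character(1),
                         parent_age = nd$age), collapse = ",")
    sprintf("(%s):%.6f", kids, parent_age - nd$age)
  }
  kids <- paste(vapply(root$children, render, character(1),
                       parent_age = root$age), collapse = ",")
  tree <- read_newick(sprintf("(%s);", kids))
  species <- tree$tip.label
  smap <- species_map(outgroup = c("Mtru", "Lusi"), anchor = "Aara",
                      focal = "Atha")
  structure(list(tree = tree, species = species,
                 ingroup = setdiff(species, c("Mtru", "Lusi")),
                 lineages = list(anchor = c("Aara", "Agra"),
                                 lineage1 = l1, lineage2 = l2,
                                 lineage3 = l3),
                 map = smap),
            class = "species_fixture")
}

#' @export
print.species_fixture <- function(x, ...) {
  cat("Species tree fixture:", length(x$species),
      "species (ultrametric, depth 1)\n")
  cat("  outgroup:", paste(x$map$outgroup, collapse = ", "),
      "| anchor clade:", paste(x$lineages$anchor, collapse = ", "),
      "| focal:", x$map$focal, "\n")
  invisible(x)
}

#' Simulate a gene family by duplication and loss along the species tree
#'
#' One gene lineage enters the species-tree root; along every
#' species-tree branch each gene lineage duplicates as a Poisson process
#' with rate `lambda` and dies at rate `mu` (a linear birth-death process
#' per branch, so expected copy number per species is
#' `exp((lambda - mu) * root-to-tip path length)`).  At every species-tree
#' node each surviving lineage speciates into both daughters.  Internal
#' gene-tree nodes are event-labelled `"S"` (speciation) or `"D"`
#' (duplication); unary nodes left by extinct sister lineages are
#' suppressed.  Leaves are labelled `"SPECIES|familyID.copy"`.
#'
#' The ground-truth ortholog set of the focal-species copy contains every
#' ingroup leaf whose most recent common ancestor with it is a speciation
#' node (outgroup leaves are the rooting device, not scored species, and
#' are excluded).
#'
#' @param fixture a [species_tree_fixture()] (or any list with fields
#'   `tree` and `map`).
#' @param lambda duplication rate per lineage per unit branch length.
#' @param mu loss rate per lineage per unit branch length.
#' @param family_id identifier used in leaf labels.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param require_focal resample until the focal species retains at least
#'   one copy (default `TRUE`); with `FALSE` extinct or focal-less
#'   families are returned as-is (needed for unbiased calibration).
#' @param max_retries retry cap before erroring when `require_focal`.
#' @param nni_moves number of random NNI rearrangements applied to the
#'   finished gene tree (topology noise; requires \pkg{phangorn};
#'   default 0).
#' @return an object of class `gene_family_sim`: `tree` (`"phylo"` with
#'   event node labels, or `NULL` if fewer than 2 leaves survive),
#'   `leaves`, `focal_leaf` (`NA` if none), `truth` (ground-truth
#'   ortholog labels incl. the focal leaf), `n_retries`, and the rates.
#' @export
simulate_gene_family <- function(fixture, lambda, mu, family_id = "fam",
                                 seed = NULL, require_focal = TRUE,
                                 max_retries = 1000L, nni_moves = 0L) {
  if (lambda < 0 || mu < 0) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  sp_tree <- fixture$tree
  smap <- fixture$map
  for (try in seq_len(if (require_focal) max_retries else 1L)) {
    fam <- .sim_family_once(sp_tree, lambda, mu, family_id)
    has_focal <- any(leaf_species(fam$leaves, smap) == smap$focal)
    if (!require_focal || has_focal) {
      fam$n_retries <- try - 1L
      if (nni_moves > 0L && !is.null(fam$tree)) {
        if (!requireNamespace("phangorn", quietly = TRUE))
          stop("'phangorn' is required for nni_moves > 0")
        fam$tree <- phangorn::rNNI(fam$tree, moves = nni_moves)
        fam$tree$node.label <- NULL  # event labels meaningless after NNI
      }
      focal_leaves <- fam$leaves[leaf_species(fam$leaves, smap) ==
                                   smap$focal]
      fam$focal_leaf <- if (length(focal_leaves))
        sort(focal_leaves)[1L] else NA_character_
      fam$truth <- .ground_truth(fam$struct, fam$focal_leaf, smap)
      fam$lambda <- lambda
      fam$mu <- mu
      class(fam) <- "gene_family_sim"
      return(fam)
    }
  }
  stop("family extinct before reaching the focal species after ",
       max_retries, " attempts")
}

# one unconditioned simulation pass
.sim_family_once <- function(sp_tree, lambda, mu, family_id) {
  ntip <- length(sp_tree$tip.label)
  kids <- vector("list", ntip + sp_tree$Nnode)
  elen <- numeric(ntip + sp_tree$Nnode)
  for (i in seq_len(nrow(sp_tree$edge))) {
    p <- sp_tree$edge[i, 1L]; ch <- sp_tree$edge[i, 2L]
    kids[[p]] <- c(kids[[p]], ch)
    elen[ch] <- sp_tree$edge.length[i]
  }
  copy_n <- stats::setNames(integer(ntip), sp_tree$tip.label)
  env <- environment()
  rate <- lambda + mu

  evolve <- function(sp_node, t_rem) {
    w <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (w >= t_rem) {
      nd <- at_node(sp_node)
      if (is.null(nd)) return(NULL)
      nd$blen <- nd$blen + t_rem
      return(nd)
    }
    if (stats::runif(1L) < lambda / rate) {
      c1 <- evolve(sp_node, t_rem - w)
      c2 <- evolve(sp_node, t_rem - w)
      if (is.null(c1) && is.null(c2)) return(NULL)
      if (is.null(c1)) { c2$blen <- c2$blen + w; return(c2) }
      if (is.null(c2)) { c1$blen <- c1$blen + w; return(c1) }
      return(list(type = "D", children = list(c1, c2), blen = w))
    }
    NULL
  }
  at_node <- function(sp_node) {
    if (is.null(kids[[sp_node]])) {          # species tip: a gene survives
      sp <- sp_tree$tip.label[sp_node]
      env$copy_n[sp] <- env$copy_n[sp] + 1L
      return(list(type = "leaf",
                  label = sprintf("%s|%s.%d", sp, family_id,
                                  env$copy_n[sp]),
                  blen = 0))
    }
    ch <- lapply(kids[[sp_node]], function(v) evolve(v, elen[v]))
    ch <- ch[!vapply(ch, is.null, logical(1))]
    if (!length(ch)) return(NULL)
    if (length(ch) == 1L) return(ch[[1L]])   # suppress unary speciation
    list(type = "S", children = ch, blen = 0)
  }

  root_struct <- at_node(ntip + 1L)
  leaves <- .struct_leaves(root_struct)
  tree <- NULL
  if (length(leaves) >= 2L) {
    nwk <- paste0(.struct_newick(root_struct, drop_blen = TRUE), ";")
    tree <- read_newick(nwk)
  }
  list(tree = tree, struct = root_struct, leaves = leaves,
       focal_leaf = NA_character_)
}

.struct_leaves <- function(nd) {
  if (is.null(nd)) return(character(0))
  if (nd$type == "leaf") return(nd$label)
  unlist(lapply(nd$children, .struct_leaves), use.names = FALSE)
}

.struct_newick <- function(nd, drop_blen = FALSE) {
  if (nd$type == "leaf")
    return(sprintf("%s:%.10g", nd$label, nd$blen))
  inner <- paste(vapply(nd$children, .struct_newick, character(1)),
                 collapse = ",")
  if (drop_blen) sprintf("(%s)%s", inner, nd$type)
  else sprintf("(%s)%s:%.10g", inner, nd$type, nd$blen)
}

# ground truth from the recorded event structure: walk the path from the
# root to the focal leaf; leaves branching off at "S" nodes are orthologs
.ground_truth <- function(struct, focal, smap) {
  if (is.null(struct) || is.na(focal)) return(character(0))
  truth <- focal
  nd <- struct
  repeat {
    if (nd$type == "leaf") break
    on_path <- vapply(nd$children,
                      function(ch) focal %in% .struct_leaves(ch),
                      logical(1))
    stopifnot(sum(on_path) == 1L)
    if (nd$type == "S") {
      off <- unlist(lapply(nd$children[!on_path], .struct_leaves),
                    use.names = FALSE)
      truth <- c(truth, off)
    }
    nd <- nd$children[[which(on_path)]]
  }
  truth <- truth[!is_outgroup_leaf(truth, smap)]
  sort(truth)
}

#' @export
print.gene_family_sim <- function(x, ...) {
  cat("Simulated gene family (lambda =", x$lambda, ", mu =", x$mu, ")\n")
  cat("  leaves:", length(x$leaves), "| focal leaf:", x$focal_leaf,
      "| true orthologs:", length(x$truth), "\n")
  invisible(x)
}

#' Expression-table fixture with designated top genes and homeolog splits
#'
#' Generates a genes x samples table of heavy-tailed (log-normal)
#' expression magnitudes in which ten designated genes are boosted so
#' that they are guaranteed to be the true top-10 by kinetic SUM, and
#' `n_homeolog_splits` randomly chosen genes are split into 2-3 homeologs
#' whose per-sample values sum exactly to the parent's.  The returned
#' homeolog map covers every row of the split table (identity rows for
#' unsplit genes), so [sum_homeologs()] reconstructs the unsplit table
#' exactly.
#'
#' @param n_genes number of reference genes (>= 10).
#' @param n_samples number of developmental-kinetic samples.
#' @param n_homeolog_splits number of genes to split into homeologs.
#' @param seed optional integer seed.
#' @return a list with fields `expr` (split table), `unsplit` (parent
#'   table), `map` (homeolog -> reference data frame), `top10`
#'   (designated top gene ids, in rank order).
#' @export
make_expression_fixture <- function(n_genes, n_samples = 6,
                                    n_homeolog_splits = 0, seed = NULL) {
  if (n_genes < 10) stop("'n_genes' must be at least 10")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  m <- matrix(stats::rlnorm(n_genes * n_samples, meanlog = 3, sdlog = 1.5),
              nrow = n_genes,
              dimnames = list(genes, paste0("stage", seq_len(n_samples))))
  top10 <- sample(genes, 10L)
  other_max <- max(rowSums(m[setdiff(genes, top10), , drop = FALSE]))
  for (i in seq_along(top10)) {
    target <- other_max * (1 + 0.05 * (11 - i))   # rank i gets the i-th SUM
    m[top10[i], ] <- m[top10[i], ] * target / sum(m[top10[i], ])
  }
  map <- data.frame(homeolog = genes, reference = genes,
                    stringsAsFactors = FALSE)
  expr <- m
  if (n_homeolog_splits > 0) {
    split_genes <- sample(genes, min(n_homeolog_splits, n_genes))
    rows <- list(); ids <- character(0)
    map_rows <- list()
    for (g in rownames(m)) {
      if (!g %in% split_genes) {
        rows[[length(rows) + 1L]] <- m[g, ]
        ids <- c(ids, g)
        map_rows[[length(map_rows) + 1L]] <-
          data.frame(homeolog = g, reference = g)
        next
      }
      k <- sample(2:3, 1L)
      p <- stats::runif(k); p <- p / sum(p)
      parts <- matrix(0, nrow = k, ncol = ncol(m))
      for (j in seq_len(k - 1L)) parts[j, ] <- m[g, ] * p[j]
      parts[k, ] <- m[g, ] - colSums(parts[seq_len(k - 1L), , drop = FALSE])
      # redefine the parent as the sequential floating-point sum of its
      # parts (the same order of additions sum_homeologs performs) so
      # that homeolog summation reconstructs it bit-exactly
      acc <- rep(0, ncol(m))
      for (j in seq_len(k)) acc <- acc + parts[j, ]
      m[g, ] <- acc
      hid <- paste0(g, "_h", seq_len(k))
      for (j in seq_len(k)) rows[[length(rows) + 1L]] <- parts[j, ]
      ids <- c(ids, hid)
      map_rows[[length(map_rows) + 1L]] <-
        data.frame(homeolog = hid, reference = g)
    }
    expr <- do.call(rbind, rows)
    rownames(expr) <- ids
    colnames(expr) <- colnames(m)
    map <- do.call(rbind, map_rows)
  }
  ord <- order(-rowSums(m)[top10])
  list(expr = expr, unsplit = m, map = map, top10 = top10[ord])
}

#' Gene-tree fixture reproducing the CESA9 pseudogenization pattern
#'
#' \emph{CESA9} is the study's striking loss case: an ortholog is found
#' only in the three \emph{Arabidopsis} species and in the
#' early-diverging anchor species.  This fixture builds a gene tree whose
#' focal sub-clade contains exactly `Atha`, `Alyr`, `Ahal` and `Aara`
#' sequences, next to a large paralog clade covering all ingroup species,
#' so [call_orthologs()] must yield presence in exactly those four
#' species.
#'
#' @param fixture a [species_tree_fixture()] (supplies the species codes).
#' @return a list with `tree` (`"phylo"`), `gene` (`"CESA9"`),
#'   `expected_species` (the four presence species).
#' @export
make_cesa9_fixture <- function(fixture = species_tree_fixture()) {
  keep <- c("Atha", "Alyr", "Ahal")
  true_clade <- sprintf("(((%s,%s):1,%s):1,%s):1",
                        "Atha|CESA9:1", "Alyr|CESA9:1", "Ahal|CESA9:1",
                        "Aara|CESA9:1")
  par_tips <- sprintf("%s|CESA9L.1:1", fixture$ingroup)
  par_clade <- par_tips[1L]
  for (i in seq(2L, length(par_tips)))
    par_clade <- sprintf("(%s,%s):1", par_clade, par_tips[i])
  nwk <- sprintf("((%s,%s):1,(Mtru|CESA9O.1:1,Lusi|CESA9O.1:1):1);",
                 true_clade, par_clade)
  list(tree = read_newick(nwk), gene = "CESA9",
       expected_species = c(keep, "Aara"))
}
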