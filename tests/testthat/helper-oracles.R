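# Independent oracles and generators used across the suite.  Everything
# here is deliberately written with different machinery than the package
# internals (plain recursion over the edge matrix, brute-force scans).

# ---- rooted tree shape enumeration -------------------------------------

shape_canon <- function(s) {
  if (is.character(s)) return("x")
  paste0("(", paste(sort(vapply(s, shape_canon, character(1))),
                    collapse = ","), ")")
}

# all rooted binary tree shapes with n leaves (unlabeled)
rooted_shapes <- function(n) {
  if (n == 1L) return(list("x"))
  out <- list()
  for (i in seq_len(n %/% 2L)) {
    for (a in rooted_shapes(i)) for (b in rooted_shapes(n - i))
      out <- c(out, list(list(a, b)))
  }
  out[!duplicated(vapply(out, shape_canon, character(1)))]
}

# label a shape's leaves L1..Ln left-to-right and render newick
shape_newick <- function(shape) {
  counter <- new.env()
  counter$i <- 0L
  render <- function(s) {
    if (is.character(s)) {
      counter$i <- counter$i + 1L
      return(paste0("L", counter$i))
    }
    paste0("(", paste(vapply(s, render, character(1)), collapse = ","), ")")
  }
  paste0(render(shape), ";")
}

# ---- brute-force clade oracle ------------------------------------------

# leaf sets of every node, by plain recursion over the edge matrix
all_clade_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], below))
  }
  nodes <- c(seq_len(ntip), ntip + seq_len(tree$Nnode))
  lapply(nodes, below)
}

# smallest clade containing the focal leaf and >= 1 anchor leaf;
# NULL when no such clade exists (the fallback branch)
oracle_delimit <- function(tree, focal, anchor_leaves) {
  sets <- all_clade_sets(tree)
  ok <- vapply(sets, function(s)
    focal %in% s && length(intersect(s, anchor_leaves)) > 0, logical(1))
  if (!any(ok)) return(NULL)
  cand <- sets[ok]
  sort(cand[[which.min(lengths(cand))]])
}

# species map for role-labeled leaves: species code equals the role
# ("F" focal, "A" anchor, "O" other); outgroup codes unused in these trees
role_smap <- function(labels, roles) {
  species_map(outgroup = "Zo", anchor = "A", focal = "F",
              mapping = stats::setNames(roles, labels))
}

# ---- alignment / blast generators and oracles --------------------------

rand_alignment <- function(nseq, ncol, pgap, alphabet = c("A", "C", "G",
                                                          "T")) {
  m <- matrix(sample(alphabet, nseq * ncol, replace = TRUE),
              nrow = nseq)
  gaps <- matrix(stats::runif(nseq * ncol) < pgap, nrow = nseq)
  m[gaps] <- "-"
  msa(apply(m, 1, paste, collapse = ""),
      ids = paste0("s", seq_len(nseq)))
}

msa_matrix <- function(aln) do.call(rbind, strsplit(aln$seqs, ""))

brute_trim <- function(aln, thresh) {
  m <- msa_matrix(aln)
  m[, colMeans(m == "-") < thresh, drop = FALSE]
}

rand_blast_table <- function(n_queries, max_hits) {
  rows <- do.call(rbind, lapply(seq_len(n_queries), function(q) {
    k <- sample.int(max_hits, 1)
    data.frame(query_id = paste0("q", q),
               subject_id = paste0("s", seq_len(k)),
               evalue = 10^stats::runif(k, -30, 1),
               bitscore = sort(stats::runif(k, 30, 500),
                               decreasing = TRUE))
  }))
  as_blast_hits(rows)
}

# ---- misc ---------------------------------------------------------------

# unrooted bipartitions of a tree as sorted "side|side" keys, for
# round-trip identity checks
bipartition_keys <- function(tree) {
  parts <- ape::prop.part(ape::unroot(tree))
  labs <- attr(parts, "labels")
  keys <- vapply(parts, function(p) {
    a <- sort(labs[p]); b <- sort(setdiff(labs, a))
    paste(min(paste(a, collapse = ","), paste(b, collapse = ",")),
          max(paste(a, collapse = ","), paste(b, collapse = ",")),
          sep = "|")
  }, character(1))
  sort(unique(keys))
}
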