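fx <- species_tree_fixture()
sm <- fx$map

# a call with the given per-species copy counts, built directly
toy_call <- function(gene, counts) {
  leaves <- unlist(mapply(function(sp, k)
    sprintf("%s|%s.%d", sp, gene, seq_len(k)),
    names(counts), counts, SIMPLIFY = FALSE))
  # make sure the focal species leads the leaf list when present
  new_ortholog_call(gene, leaves[1], leaves, sm)
}

test_that("build_presence_matrix is a pure tabulation", {
  species <- fx$ingroup
  calls <- lapply(sprintf("g%03d", 1:105), function(g)
    toy_call(g, stats::setNames(rep(1L, length(species)), species)))
  pm <- build_presence_matrix(calls, species)
  expect_equal(dim(pm$counts), c(105, 32))
  expect_true(all(pm$counts == 1L))

  # a 23-co-ortholog species lands at the top of the copy gradient
  big <- toy_call("dup", c(Atha = 1L, Bnap = 23L, Aara = 1L))
  pm2 <- build_presence_matrix(list(big), species)
  expect_equal(pm2$counts["dup", "Bnap"], 23L)
  expect_equal(max(pm2$counts), 23L)

  # total of the matrix equals the total of the copy counts
  set.seed(31)
  calls3 <- lapply(sprintf("r%02d", 1:20), function(g) {
    sp <- sample(species, sample(3:20, 1))
    toy_call(g, stats::setNames(sample(1:4, length(sp), TRUE), sp))
  })
  pm3 <- build_presence_matrix(calls3, species)
  expect_equal(sum(pm3$counts),
               sum(unlist(lapply(calls3, function(cl) cl$copy_counts))))

  # genes without calls get all-zero rows; duplicate ids are rejected
  pm4 <- build_presence_matrix(calls3[1], species,
                               genes = c("r01", "missing"))
  expect_true(all(pm4$counts["missing", ] == 0L))
  expect_error(build_presence_matrix(c(calls3[1], calls3[1]), species),
               "duplicate gene ids")
})

test_that("contrast_by_phenotype computes 2x2 tables and proportion differences", {
  species <- sprintf("S%02d", 1:27)
  phen <- data.frame(species = species,
                     phenotype = c(rep("myxospermous", 19),
                                   rep("non-myxospermous", 8)))
  # gene A present everywhere; gene B present in 10/19 myxo and 8/8 non-myxo
  callA <- toy_call("A", stats::setNames(rep(1L, 27), species))
  presB <- c(species[1:10], species[20:27])
  callB <- toy_call("B", stats::setNames(rep(1L, length(presB)), presB))
  pm <- build_presence_matrix(list(callA, callB), species,
                              phenotypes = phen)
  ct <- contrast_by_phenotype(pm)
  expect_equal(ct$prop_diff[ct$gene == "A"], 0)
  expect_equal(ct$prop_diff[ct$gene == "B"], 10 / 19 - 1)
  tabB <- attr(ct, "tables")$B
  expect_equal(unname(colSums(tabB)), c(19, 8))   # phenotype group sizes
  expect_equal(sum(tabB), 27)

  # species of unknown phenotype are excluded from the contrast
  phen2 <- phen; phen2$phenotype[1] <- "unknown"
  pm2 <- build_presence_matrix(list(callA, callB), species,
                               phenotypes = phen2)
  expect_equal(sum(attr(contrast_by_phenotype(pm2), "tables")$A), 26)

  # degenerate: a single phenotype class
  phen3 <- phen; phen3$phenotype <- "myxospermous"
  pm3 <- build_presence_matrix(list(callA), species, phenotypes = phen3)
  expect_error(contrast_by_phenotype(pm3), "degenerate contrast")
})

test_that("presence independent of phenotype yields small mean |difference|", {
  set.seed(41)
  species <- sprintf("S%02d", 1:30)
  phen <- data.frame(species = species,
                     phenotype = rep(c("myxospermous", "non-myxospermous"),
                                     15))
  diffs <- replicate(50, {
    calls <- lapply(sprintf("g%02d", 1:40), function(g) {
      sp <- species[stats::runif(30) < 0.7]
      if (!length(sp)) sp <- species[1]
      toy_call(g, stats::setNames(rep(1L, length(sp)), sp))
    })
    pm <- build_presence_matrix(calls, species, phenotypes = phen)
    mean(abs(contrast_by_phenotype(pm)$prop_diff))
  })
  expect_lt(mean(diffs), 0.2)
  # large-imbalance genes are rare under independence
  expect_lt(mean(diffs > 0.5), 0.05)
})

test_that("group_by_category summarises presence per functional category", {
  species <- sprintf("S%02d", 1:10)
  phen <- data.frame(species = species,
                     phenotype = rep(c("myxospermous", "non-myxospermous"),
                                     5))
  cats <- data.frame(gene = c("A", "B", "C"),
                     category = c("synthesis", "synthesis", "regulation"))
  callA <- toy_call("A", stats::setNames(rep(1L, 10), species))
  callB <- toy_call("B", stats::setNames(rep(1L, 10), species))
  callC <- toy_call("C", stats::setNames(rep(1L, 4), species[1:4]))
  pm <- build_presence_matrix(list(callA, callB, callC), species,
                              phenotypes = phen, categories = cats)
  gs <- group_by_category(pm)
  expect_equal(gs$presence_all[gs$category == "synthesis"], 1)
  expect_equal(gs$n_losses[gs$category == "regulation"], 6)
  expect_equal(gs$presence_all[gs$category == "regulation"], 0.4)

  # single category equals the global fraction
  cats1 <- data.frame(gene = c("A", "B", "C"), category = "all")
  pm1 <- build_presence_matrix(list(callA, callB, callC), species,
                               phenotypes = phen, categories = cats1)
  gs1 <- group_by_category(pm1)
  expect_equal(gs1$presence_all, mean(pm1$counts >= 1))

  # unlabelled genes warn and bucket as uncategorized
  pmna <- build_presence_matrix(list(callA, callC), species,
                                phenotypes = phen,
                                categories = cats[cats$gene == "A", ])
  expect_warning(gna <- group_by_category(pmna), "uncategorized")
  expect_true("uncategorized" %in% gna$category)

  # engineered differential loss between categories is recovered
  set.seed(53)
  lossy <- lapply(sprintf("L%02d", 1:20), function(g) {
    sp <- species[stats::runif(10) < 0.3]
    if (!length(sp)) sp <- species[1]
    toy_call(g, stats::setNames(rep(1L, length(sp)), sp))
  })
  stable <- lapply(sprintf("K%02d", 1:20), function(g)
    toy_call(g, stats::setNames(rep(1L, 10), species)))
  cats2 <- data.frame(gene = c(sprintf("L%02d", 1:20),
                               sprintf("K%02d", 1:20)),
                      category = rep(c("lossy", "stable"), each = 20))
  pm2 <- build_presence_matrix(c(lossy, stable), species,
                               phenotypes = phen, categories = cats2)
  gs2 <- group_by_category(pm2)
  expect_gt(gs2$presence_all[gs2$category == "stable"] -
              gs2$presence_all[gs2$category == "lossy"], 0.3)
})
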