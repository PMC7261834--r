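test_that("Weir-Cockerham theta matches an independently evaluated instance", {
  ## pop1: 12 AA, 26 AB, 12 BB; pop2: 50 AA -- theta evaluated by hand
  ## from the per-allele a/b/c components (scalar arithmetic)
  a1 <- c(rep(1L, 12), rep(1L, 26), rep(2L, 12), rep(1L, 50))
  a2 <- c(rep(1L, 12), rep(2L, 26), rep(2L, 12), rep(1L, 50))
  g <- genotype_matrix(matrix(a1, ncol = 1), matrix(a2, ncol = 1))
  p <- partition(rep(c("p1", "p2"), each = 50), ids = g$ids)
  res <- pairwise_fst(g, p)
  expect_equal(res$fst["p1", "p2"], 0.4951020408, tolerance = 1e-9)
  expect_equal(res$global, res$fst["p1", "p2"], tolerance = 1e-12)
})

test_that("theta hits its boundary cases", {
  fx <- fixed_difference_gm(10, 5)
  expect_equal(pairwise_fst(fx$g, fx$p)$fst[1, 2], 1)
  ## two groups from identical frequencies: |theta| small, possibly negative
  set.seed(8)
  g <- random_gm(400, 10, alleles = 4L, seed = 8)
  p <- partition(rep(c("a", "b"), each = 200), ids = g$ids)
  expect_lt(abs(pairwise_fst(g, p)$fst[1, 2]), 0.02)
})

test_that("theta permutation p is small for real structure, large under null", {
  fx <- fixed_difference_gm(8, 4)
  res <- pairwise_fst(fx$g, fx$p, n_perm = 99, seed = 2)
  expect_lt(res$p_values[1, 2], 0.05)
  g <- random_gm(60, 5, seed = 12)
  p <- partition(rep(c("a", "b"), each = 30), ids = g$ids)
  expect_gt(pairwise_fst(g, p, n_perm = 99, seed = 3)$p_values[1, 2], 0.05)
})

test_that("Nei standard distance matches direct evaluation", {
  ## single locus, p1 = (0.75, 0.25), p2 = (0.25, 0.75):
  ## I = 0.375/0.625 = 0.6, D = -ln 0.6
  g <- gm_from_calls(as.list(c("1/1", "1/1", "1/1", "2/2",
                               "2/2", "2/2", "2/2", "1/1")))
  p <- partition(rep(c("x", "y"), each = 4), ids = g$ids)
  D <- nei_distance(g, p)
  expect_equal(D["x", "y"], -log(0.6), tolerance = 1e-12)
  ## identical profiles
  g2 <- gm_from_calls(as.list(rep("1/2", 6)))
  p2 <- partition(rep(c("x", "y"), each = 3), ids = g2$ids)
  expect_equal(nei_distance(g2, p2)["x", "y"], 0)
  ## disjoint allele sets
  fx <- fixed_difference_gm(3, 2)
  expect_warning(Dx <- nei_distance(fx$g, fx$p), "no shared alleles")
  expect_equal(Dx[1, 2], Inf)
})

test_that("unbiased Nei variant shrinks distance for small samples", {
  set.seed(14)
  g <- random_gm(30, 8, alleles = 6L, seed = 14)
  p <- partition(rep(c("a", "b"), 15), ids = g$ids)
  d72 <- nei_distance(g, p, "standard_1972")[1, 2]
  d78 <- nei_distance(g, p, "unbiased_1978")[1, 2]
  expect_lt(d78, d72)
})

test_that("AMOVA partitions all variance between fixed groups and none under a null split", {
  fx <- fixed_difference_gm(6, 4)
  am <- amova(fx$g, fx$p)
  expect_equal(am$table$percent[1], 100)
  expect_equal(am$table$df, c(1, 22, 23), ignore_attr = TRUE) # 2N-1 scale
  ## random split of one panmictic sample
  g <- random_gm(200, 10, alleles = 5L, seed = 31)
  p <- partition(rep(c("a", "b"), 100), ids = g$ids)
  am0 <- amova(g, p, n_perm = 60, seed = 4)
  expect_lt(am0$table$percent[1], 3)
  expect_gt(am0$p_value, 0.05)
  expect_equal(sum(am0$table$percent[1:2]), 100, tolerance = 0.1)
  expect_error(amova(g, partition(rep("a", 200), ids = g$ids)), "2 groups")
})

test_that("AMOVA is invariant to allele relabeling", {
  g <- random_gm(40, 5, alleles = 4L, seed = 17)
  p <- partition(rep(c("a", "b"), 20), ids = g$ids)
  relab <- genotype_matrix(g$a1 * 10L + 3L, g$a2 * 10L + 3L)
  a1 <- amova(g, p); a2 <- amova(relab, p)
  expect_equal(a1$table$percent, a2$table$percent, tolerance = 1e-9)
})

test_that("simple-matching dissimilarity counts shared alleles per call", {
  g <- gm_from_calls(list("1/2", "1/3"))
  expect_equal(simple_matching_dissimilarity(g)[1, 2], 0.5)
  g2 <- gm_from_calls(list(c("1/2", "4/4"), c("1/2", "4/4")))
  expect_equal(simple_matching_dissimilarity(g2)[1, 2], 0)
  fx <- fixed_difference_gm(2, 3)
  expect_equal(simple_matching_dissimilarity(fx$g)[1, 3], 1)
  ## (1,2) vs (2,2): one shared allele of two
  g3 <- gm_from_calls(list("1/2", "2/2"))
  expect_equal(simple_matching_dissimilarity(g3)[1, 2], 0.5)
})

test_that("neighbor joining recovers an additive 4-leaf tree exactly", {
  ## tree: (A:1,B:2):1.5 -- (C:3,D:4)  => additive distances
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 1 + 1.5 + 3
  D["A", "D"] <- D["D", "A"] <- 1 + 1.5 + 4
  D["B", "C"] <- D["C", "B"] <- 2 + 1.5 + 3
  D["B", "D"] <- D["D", "B"] <- 2 + 1.5 + 4
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- nj_tree(D)$tree
  ## AB | CD split recovered
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
  ## branch lengths reproduce the distances exactly
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  expect_error(nj_tree(D[1:2, 1:2]), "3 leaves")
  D2 <- D; D2["A", "B"] <- D2["B", "A"] <- Inf
  expect_error(nj_tree(D2), "non-finite")
})

test_that("locus bootstrap gives full support for a clean split", {
  fx <- fixed_difference_gm(3, 6)
  grp4 <- partition(c("a1", "a1", "a2", "b1", "b1", "b2"), ids = fx$g$ids)
  d <- suppressWarnings(nei_distance(fx$g, grp4))
  d[!is.finite(d)] <- 5   # disjoint groups: cap for tree building
  tr <- nj_tree(d, boot_fun = function(idx) {
    dd <- suppressWarnings(nei_distance(gm_subset(fx$g, loci = idx), grp4))
    dd[!is.finite(dd)] <- 5
    dd
  }, n_loci_boot = 6, B = 50, seed = 5)
  expect_true(all(tr$support >= 99, na.rm = TRUE))
})

test_that("PCoA reproduces Euclidean configurations", {
  set.seed(6)
  xy <- cbind(rnorm(12), rnorm(12))
  d <- as.matrix(dist(xy))
  pc <- pcoa(d, n_axes = 2)
  expect_equal(as.matrix(dist(pc$coordinates)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  ## 1-D configuration: one dominant axis
  d1 <- as.matrix(dist(cbind(1:8)))
  pc1 <- pcoa(d1, n_axes = 3)
  expect_lt(max(abs(pc1$eigenvalues[-1])), 1e-8)
  expect_error(pcoa(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("PCoA axis 1 separates fixed clusters by a margin", {
  fx <- fixed_difference_gm(8, 5)
  d <- simple_matching_dissimilarity(fx$g)
  pc <- pcoa(d, 2)
  x <- pc$coordinates[, 1]
  expect_gt(min(abs(mean(x[1:8]) - x[9:16])), 0.1)
})
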