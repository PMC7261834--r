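test_that("per-locus summary matches hand-computed values", {
  ## calls {(A,A),(A,B)}: p = (0.75, 0.25)
  g <- gm_from_calls(list("1/1", "1/2"))
  ls <- locus_summary(g)
  expect_equal(ls$n_alleles, 2)
  expect_equal(ls$n_effective, 1.6)
  expect_equal(ls$ho, 0.5)
  expect_equal(ls$he, (4 / 3) * 0.375)   # unbiased, n = 2 individuals
  expect_equal(ls$shannon, -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(ls$major_allele_freq, 0.75)
})

test_that("monomorphic loci report no variation and undefined F_IS", {
  g <- gm_from_calls(list(c("2/2", "1/1"), c("2/2", "1/2")))
  ls <- locus_summary(g)
  expect_equal(ls$n_alleles[1], 1)
  expect_equal(ls$n_effective[1], 1)
  expect_equal(ls$shannon[1], 0)
  expect_equal(ls$ho[1], 0)
  expect_equal(ls$he[1], 0)
  expect_true(is.na(ls$fis[1]))
})

test_that("rarefied richness equals the exhaustive subsample mean", {
  ## 10 gene copies, counts (5, 3, 2), g = 5: enumerate all C(10,5) draws
  copies <- rep(1:3, c(5, 3, 2))
  subs <- combn(10, 5)
  oracle <- mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
  expect_equal(ssrdem:::rarefy_counts(c(5, 3, 2), 5), oracle)
  ## more instances with <= 12 copies against the same oracle
  set.seed(9)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    cnt <- as.vector(table(sample.int(k, sample(6:12, 1), replace = TRUE)))
    tot <- sum(cnt); gg <- sample(2:(tot - 1), 1)
    copies <- rep(seq_along(cnt), cnt)
    oracle <- mean(apply(combn(tot, gg), 2,
                         function(ix) length(unique(copies[ix]))))
    expect_equal(ssrdem:::rarefy_counts(cnt, gg), oracle, tolerance = 1e-12)
  }
})

test_that("rarefaction endpoints: full sample gives N_A, one copy gives 1", {
  expect_equal(ssrdem:::rarefy_counts(c(5, 3, 2), 10), 3)
  expect_equal(ssrdem:::rarefy_counts(c(5, 3, 2), 1), 1)
})

test_that("group summary counts private and unique alleles by definition", {
  ## allele 3 only in group B and only in one accession: private + unique
  g <- gm_from_calls(list("1/2", "1/1", "1/3", "1/1"))
  p <- partition(c("A", "A", "B", "B"), ids = g$ids)
  gs <- group_summary(g, p)
  expect_equal(unname(gs$private), c(1, 1))  # allele 2 in A, allele 3 in B
  expect_equal(unname(gs$unique), c(1, 1))
  ## identical-composition groups share everything
  g2 <- gm_from_calls(list("1/2", "1/2", "1/2", "1/2"))
  gs2 <- group_summary(g2, p)
  expect_equal(unname(gs2$private), c(0, 0))
})

test_that("null-allele estimator follows the closed form and floors at 0", {
  expect_equal(null_allele_rate(0.5, 0.5), 0)
  expect_equal(null_allele_rate(0.132, 0.299), (0.299 - 0.132) / 1.299)
  expect_equal(round(null_allele_rate(0.132, 0.299), 4), 0.1286)
  expect_equal(null_allele_rate(0.8, 0.3), 0)
})

test_that("effective allele count never exceeds observed allele count", {
  for (s in 1:10) {
    g <- random_gm(15, 6, alleles = 7L, missing_rate = 0.1, seed = s)
    ls <- locus_summary(g)
    expect_true(all(ls$n_effective <= ls$n_alleles + 1e-12))
    expect_true(all(ls$n_effective >= 1))
    expect_true(all(ls$allelic_richness <= ls$n_alleles + 1e-12))
  }
  ## equality iff equifrequent
  g <- gm_from_calls(list("1/2", "3/4"))
  ls <- locus_summary(g)
  expect_equal(ls$n_effective, ls$n_alleles)
})

test_that("unbiased H_E estimates 1 - sum(p^2) without bias", {
  freqs <- c(0.6, 0.3, 0.1)
  target <- 1 - sum(freqs^2)
  set.seed(5)
  hes <- vapply(1:600, function(i) {
    g <- hwe_locus_gm(12, freqs, seed = 10000 + i)
    locus_summary(g)$he
  }, 0)
  expect_lt(abs(mean(hes) - target), 3 * sd(hes) / sqrt(length(hes)) + 0.003)
})

test_that("F_IS permutation test holds its size under HWE", {
  ## small-scale check (the full 400-locus calibration runs in the
  ## acceptance suite)
  set.seed(11)
  ps <- vapply(1:60, function(i) {
    g <- hwe_locus_gm(40, c(0.5, 0.3, 0.2), seed = 5000 + i)
    unname(ssrdem:::fis_permutation_p(g, n_perm = 120)["p"])
  }, 0)
  expect_gt(mean(ps < 0.05), 0.0)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("null alleles inflate the deficit and Brookfield recovers modest rates", {
  ## one locus, two visible alleles + a null allele at frequency 0.08;
  ## the closed-form estimator is only near-unbiased for modest null
  ## frequencies when null homozygotes are scored missing
  n <- 2000
  r <- 0.08
  freqs <- c(c(0.55, 0.45) * (1 - r), r)  # highest code is the null
  ## tiny drift: cluster frequencies track the ancestral vector closely
  spec <- generator_spec(K = 1, loci = list(setNames(freqs, c(100, 102, 104))),
                         drift = 1e-4, admixture = matrix(1, n, 1),
                         null_allele_rate = 0.999, seed = 77)
  sim <- generate_genotypes(spec, sample_cluster_frequencies(spec))
  ls <- locus_summary(sim$genotypes)
  est <- null_allele_rate(ls$ho, ls$he)
  expect_gt(ls$he - ls$ho, 0)            # deficit inflated
  expect_gt(est, 0)
  expect_lt(abs(est - r), 0.05)
  ## no-null control shows no deficit signal
  spec0 <- generator_spec(K = 1, loci = list(setNames(freqs, c(100, 102, 104))),
                          drift = 1e-4, admixture = matrix(1, n, 1),
                          seed = 77)
  sim0 <- generate_genotypes(spec0, sample_cluster_frequencies(spec0))
  ls0 <- locus_summary(sim0$genotypes)
  expect_lt(null_allele_rate(ls0$ho, ls0$he), 0.02)
})
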