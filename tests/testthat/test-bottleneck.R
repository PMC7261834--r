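test_that("TPM parameters solve the stated step-size variance", {
  tp <- tpm_params(0.95, 12)
  ## geometric on {1, 2, ...}: var (1-g)/g^2 = 12  =>  g = 0.25
  expect_equal(tp$geom_prob, 0.25)
  expect_equal((1 - tp$geom_prob) / tp$geom_prob^2, 12)
  expect_error(tpm_params(1.2), "p_single")
})

test_that("monomorphic conditioning returns zero diversity exactly", {
  hq <- simulate_heq(50, 1, "iam", n_iter = 100)
  expect_equal(hq$mean, 0)
  expect_equal(hq$draws, rep(0, 100))
})

test_that("equilibrium gene diversity increases with the allele count", {
  ms <- vapply(c(2, 5, 10), function(k)
    simulate_heq(50, k, "iam", n_iter = 800, seed = k)$mean, 0)
  expect_true(all(diff(ms) > 0))
  draws2 <- simulate_heq(50, 2, "iam", n_iter = 800, seed = 2)
  draws5 <- simulate_heq(50, 5, "iam", n_iter = 800, seed = 5)
  se <- sqrt(draws2$sd^2 / 800 + draws5$sd^2 / 800)
  expect_gt(draws5$mean - draws2$mean, 3 * se)
})

test_that("size homoplasy makes SMM equilibrium diversity exceed IAM at fixed k", {
  ## conditional on the same allele count, stepwise mutation needs a higher
  ## mutation rate and yields more even frequencies, so H_eq(SMM) >
  ## H_eq(IAM); the IAM therefore detects heterozygosity excess most readily
  hi <- simulate_heq(50, 8, "iam", n_iter = 800, seed = 31)
  hs <- simulate_heq(50, 8, "smm", n_iter = 800, seed = 31)
  se <- sqrt(hi$sd^2 / 800 + hs$sd^2 / 800)
  expect_gt(hs$mean - hi$mean, 3 * se)
})

test_that("TPM with all-single-step mutations reproduces SMM draws", {
  ## same explicit theta so only the mutation-model math differs
  hs <- simulate_heq(40, 6, "smm", n_iter = 1500, seed = 8, theta = 8)
  ht <- simulate_heq(40, 6, "tpm", tpm = tpm_params(p_single = 1),
                     n_iter = 1500, seed = 9, theta = 8)
  expect_gt(suppressWarnings(ks.test(hs$draws, ht$draws)$p.value), 0.01)
})

test_that("H_eq draws stay in [0, 1) with positive spread for k >= 2", {
  hq <- simulate_heq(30, 4, "tpm", n_iter = 300, seed = 10)
  expect_true(all(hq$draws >= 0 & hq$draws < 1))
  expect_gt(hq$sd, 0)
})

test_that("the excess test is invariant to allele relabeling and locus order", {
  sc <- one_pop_scenario(n = 30, theta = 4)
  sim <- simulate_scenario(sc, n_loci = 8, seed = 21)
  g <- sim$genotypes
  cache <- new.env()
  p0 <- heterozygosity_excess_test(g, model = "iam", n_iter = 200, seed = 1,
                                   heq_cache = cache)$wilcoxon_p
  ## relabel alleles and shuffle loci
  g2 <- genotype_matrix(g$a1[, 8:1] * 3L + 1L, g$a2[, 8:1] * 3L + 1L)
  p1 <- heterozygosity_excess_test(g2, model = "iam", n_iter = 200, seed = 1,
                                   heq_cache = cache)$wilcoxon_p
  expect_equal(p0, p1)
})

test_that("no positive signed rank gives p = 1 for the classical statistic", {
  expect_equal(ssrdem:::.safe_wilcox_greater(rep(0, 10)), 1)
  expect_equal(ssrdem:::.safe_wilcox_greater(c(-0.2, -0.1, 0, -0.3)), 1)
})

test_that("too few usable loci is an error, not a silent answer", {
  g <- gm_from_calls(list(c("1/2", "1/1"), c("1/1", "1/1"), c("2/2", "1/1"),
                          c("1/2", "1/1")))
  expect_error(heterozygosity_excess_test(g, model = "iam", n_iter = 100),
               "fewer than 4")
})

test_that("mode-shift test bins pooled allele frequencies into ten classes", {
  ## frequencies {0.02,0.04,0.06,0.5,0.5}-like profile: L-shaped
  calls <- c(rep("1/2", 1), rep("3/3", 24))  # allele freqs 0.02,0.02,0.96
  g1 <- gm_from_calls(as.list(calls))
  ms1 <- mode_shift(g1)
  expect_equal(ms1$shape, "L-shaped")
  expect_equal(sum(ms1$histogram), 1)
  expect_length(ms1$histogram, 10)
  ## intermediate-frequency alleles dominate: shifted
  calls2 <- c(rep("1/2", 12), rep("1/1", 6), rep("2/2", 6), "1/3")
  g2 <- gm_from_calls(as.list(calls2))
  ms2 <- mode_shift(g2)
  expect_equal(ms2$shape, "shifted")
})

test_that("a severe founder event shifts the allele-frequency mode", {
  ## strong recent subsampling: 50-fold crash lasting long enough on the
  ## post-crash scale to purge rare alleles
  sc <- one_pop_scenario(n = 40, r = 0.02, change_time = 0.04, theta = 4)
  sim <- simulate_scenario(sc, n_loci = 25, seed = 14)
  expect_equal(mode_shift(sim$genotypes)$shape, "shifted")
  ## equilibrium sample keeps the L shape
  sc0 <- one_pop_scenario(n = 40, theta = 12)
  sim0 <- simulate_scenario(sc0, n_loci = 25, seed = 15)
  expect_equal(mode_shift(sim0$genotypes)$shape, "L-shaped")
})
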