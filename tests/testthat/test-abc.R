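test_that("scenario validation rejects inconsistent event orders", {
  expect_error(demographic_scenario(
    c(a = 5L, b = 5L), splits = data.frame(time = 0.5, from = "b", to = "c")),
    "invalid split")
  expect_error(demographic_scenario(
    c(a = 5L, b = 5L),
    splits = data.frame(time = 0.3, from = "b", to = "a"),
    admixture = data.frame(time = 0.4, target = "b", source = "a",
                           prop = 0.5)),
    "postdates a merge")
  expect_error(demographic_scenario(
    c(a = 5L, b = 5L),
    splits = data.frame(time = 0.3, from = "b", to = "a"),
    admixture = data.frame(time = 0.1, target = "b", source = "a",
                           prop = 1.5)),
    "proportions")
})

test_that("a stable panmictic population shows no inbreeding signal", {
  sc <- one_pop_scenario(n = 100, theta = 5, gsm = tpm_params())
  sim <- simulate_scenario(sc, n_loci = 25, seed = 3)
  ls <- locus_summary(sim$genotypes)
  expect_lt(abs(attr(ls, "multilocus")$fis), 0.05)
})

test_that("a deep split without migration produces strong differentiation", {
  sc <- demographic_scenario(c(a = 50L, b = 50L), r = 1, change_time = 0.05,
                             splits = data.frame(time = 2, from = "b",
                                                 to = "a"), theta = 5)
  sim <- simulate_scenario(sc, n_loci = 25, seed = 4)
  expect_gt(pairwise_fst(sim$genotypes, sim$partition)$global, 0.2)
})

test_that("a half-half admixture pulls the target between its parents", {
  ratios <- vapply(1:8, function(i) {
    sc <- demographic_scenario(
      c(a = 25L, b = 25L, c = 25L), r = 1, change_time = 0.02,
      splits = data.frame(time = c(0.6, 1.2), from = c("c", "b"),
                          to = c("b", "a")),
      admixture = data.frame(time = 0.05, target = "c", source = "a",
                             prop = 0.5),
      theta = 5)
    sim <- simulate_scenario(sc, n_loci = 25, seed = 100 + i)
    fst <- pairwise_fst(sim$genotypes, sim$partition)$fst
    fst["a", "c"] / fst["b", "c"]
  }, 0)
  expect_gt(mean(ratios > 0.5 & ratios < 2), 0.7)
})

test_that("the summary vector has the documented layout and invariances", {
  sc <- five_cluster_scenario(n_per_pop = 6L)
  sim <- simulate_scenario(sc, n_loci = 6, seed = 6)
  st <- summary_statistics(sim$genotypes, sim$partition)
  expect_length(st, 5 * 4 + 2 * choose(5, 2))   # 40 for 5 populations
  expect_true(all(is.finite(st)))
  ## invariant to individual order
  perm <- sample(n_ind(sim$genotypes))
  st2 <- summary_statistics(gm_subset(sim$genotypes, perm),
                            align_partition(gm_subset(sim$genotypes, perm),
                                            sim$partition))
  expect_equal(st, st2, tolerance = 1e-9)
  ## two identical populations: pairwise differences near zero
  g <- random_gm(400, 10, alleles = 6L, seed = 7)
  p <- partition(rep(c("x", "y"), 200), ids = g$ids)
  stxy <- summary_statistics(g, p)
  expect_lt(abs(stxy[["fst_x_y"]]), 0.01)
})

test_that("duplicating every individual leaves frequency-level statistics unchanged", {
  g <- random_gm(30, 5, alleles = 5L, seed = 8)
  p <- partition(rep(c("x", "y"), 15), ids = g$ids)
  gd <- genotype_matrix(rbind(g$a1, g$a1), rbind(g$a2, g$a2),
                        ids = c(g$ids, paste0("d", g$ids)))
  pd <- partition(rep(as.character(p), 2), ids = gd$ids)
  s1 <- summary_statistics(g, p); s2 <- summary_statistics(gd, pd)
  ## exactly invariant components (no sample-size correction)
  pick <- grep("mean_k|m_index", names(s1))
  expect_equal(s1[pick], s2[pick], tolerance = 1e-12)
  ## corrected components move only by their small-sample factors
  expect_equal(s1[grep("mean_h", names(s1))],
               s2[grep("mean_h", names(s2))], tolerance = 0.02)
})

test_that("accepting every draw without adjustment returns the prior", {
  sc <- demographic_scenario(c(a = 8L, b = 8L), r = 1, change_time = 0.05,
                             splits = data.frame(time = 0.5, from = "b",
                                                 to = "a"), theta = 5)
  sim <- simulate_scenario(sc, n_loci = 8, seed = 9)
  obs <- summary_statistics(sim$genotypes, sim$partition)
  fit <- abc_fit(obs, sc, n_sims = 150, accept_rate = 1, adjust = "none",
                 n_loci = 8, seed = 10)
  expect_equal(sort(fit$adjusted[, "log10_r_a"]),
               sort(fit$prior[, "log10_r_a"]))
  expect_lt(unname(suppressWarnings(
    ks.test(fit$adjusted[, "log10_r_a"], "punif", -2, 2)$statistic)), 0.12)
  ## classification report structure
  rep <- posterior_r_report(fit)
  expect_true(all(rep$uninformative[grep("log10_r", rep$parameter)]))
})

test_that("posterior classification uses the mode sign with a dead zone", {
  fake <- structure(list(
    prior = matrix(runif(2000, -2, 2), ncol = 2,
                   dimnames = list(NULL, c("log10_r_a", "log10_r_b"))),
    adjusted = cbind(log10_r_a = rnorm(300, 0, 0.05),
                     log10_r_b = rnorm(300, -1.2, 0.1)),
    param_names = c("log10_r_a", "log10_r_b")), class = "abc_result")
  rep <- posterior_r_report(fake)
  expect_equal(rep$classification, c("stable", "bottleneck"))
  expect_false(any(rep$uninformative))
})
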