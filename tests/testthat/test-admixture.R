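test_that("K = 1 returns the degenerate all-ones membership", {
  g <- random_gm(10, 3, seed = 2)
  fit <- fit_admixture(g, K = 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 10))
  expect_true(is.finite(fit$mean_lnl))
})

test_that("the sampler is bitwise reproducible under a seed", {
  g <- random_gm(15, 4, seed = 3)
  f1 <- fit_admixture(g, 2, burn_in = 50, iterations = 200, thinning = 5,
                      seed = 99)
  f2 <- fit_admixture(g, 2, burn_in = 50, iterations = 200, thinning = 5,
                      seed = 99)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$lnl_trace, f2$lnl_trace)
})

test_that("two fixed-difference clusters are recovered almost perfectly", {
  set.seed(4)
  Q <- matrix(0, 60, 2); Q[1:30, 1] <- 1; Q[31:60, 2] <- 1
  spec <- generator_spec(K = 2, loci = rep(6L, 10), drift = 0.5,
                         admixture = Q, seed = 10)
  sim <- generate_genotypes(spec, sample_cluster_frequencies(spec))
  fit <- fit_admixture(sim$genotypes, 2, burn_in = 300, iterations = 1500,
                       thinning = 5, seed = 1)
  pm <- ssrdem:::best_permutation(Q, fit$Q)
  Qa <- fit$Q[, pm]
  agree <- Qa[cbind(1:60, max.col(Q))]
  expect_gte(mean(agree >= 0.95), 0.95)
})

test_that("an individual simulated half-and-half gets intermediate membership", {
  set.seed(5)
  Q <- matrix(0, 201, 2); Q[1:100, 1] <- 1; Q[101:200, 2] <- 1
  Q[201, ] <- c(0.5, 0.5)
  spec <- generator_spec(K = 2, loci = rep(8L, 20), drift = 0.4,
                         admixture = Q, seed = 11)
  sim <- generate_genotypes(spec, sample_cluster_frequencies(spec))
  fit <- fit_admixture(sim$genotypes, 2, burn_in = 300, iterations = 1500,
                       thinning = 5, seed = 2)
  expect_true(all(fit$Q[201, ] > 0.3 & fit$Q[201, ] < 0.7))
})

test_that("the correlated-frequency model runs and returns valid output", {
  g <- random_gm(20, 4, alleles = 4L, seed = 6)
  fit <- fit_admixture(g, 2, burn_in = 100, iterations = 400, thinning = 4,
                       model = "correlated", seed = 3)
  expect_equal(unname(rowSums(fit$Q)), rep(1, 20), tolerance = 1e-9)
  expect_true(all(vapply(fit$P, function(m) max(abs(rowSums(m) - 1)), 0) < 1e-9))
})

test_that("delta-K follows its closed form", {
  ## zero curvature
  expect_equal(unname(evanno_delta_k(c(-100, -90, -80), c(1, 1, 1))), 0)
  ## |(-100) - 2(-80) + (-78)| / 2 = 9
  expect_equal(unname(evanno_delta_k(c(-100, -80, -78), c(1, 2, 1))[1]), 9)
  ## invariant to affine rescaling when the spread rescales identically
  L <- c(-200, -150, -130, -125); s <- c(2, 3, 1, 2)
  expect_equal(evanno_delta_k(3 * L + 7, 3 * s, 2:5),
               evanno_delta_k(L, s, 2:5))
  expect_warning(evanno_delta_k(c(-3, -2, -1), c(1, 0, 1)), "zero")
  expect_error(evanno_delta_k(c(-1, -2), c(1, 1)), "at least 3")
})

test_that("run alignment resolves label switching and scores agreement", {
  set.seed(7)
  Q1 <- matrix(runif(40), 20, 2); Q1 <- Q1 / rowSums(Q1)
  expect_equal(align_runs(list(Q1, Q1))$H, 1)
  ## column permutation only
  al <- align_runs(list(Q1, Q1[, 2:1]), seed = 1)
  expect_equal(al$H, 1, tolerance = 1e-12)
  expect_equal(al$consensus, Q1, ignore_attr = TRUE)
  ## K = 3 permutation resolved too
  Q3 <- matrix(runif(60), 20, 3); Q3 <- Q3 / rowSums(Q3)
  expect_equal(align_runs(list(Q3, Q3[, c(3, 1, 2)]), seed = 1)$H, 1,
               tolerance = 1e-12)
  expect_error(align_runs(list(Q1, Q3)), "identical dimensions")
})

test_that("alignment similarity matches the exhaustive-permutation value", {
  Q1 <- rbind(c(1, 0), c(1, 0))
  Q2 <- rbind(c(1, 0), c(0, 1))
  al <- align_runs(list(Q1, Q2))
  ## best alignment leaves ||Q1 - Q2||_F = sqrt(2); S = 1 - sqrt(2)/2
  byhand <- 1 - sqrt(2) / sqrt(2 * 2)
  exhaustive <- max(vapply(list(1:2, 2:1), function(pm)
    1 - norm(Q1 - Q2[, pm], "F") / sqrt(2 * 2), 0))
  expect_equal(al$H, byhand, tolerance = 1e-12)
  expect_equal(al$H, exhaustive, tolerance = 1e-12)
})

test_that("threshold assignment is inclusive at the boundary", {
  qbar <- rbind(c(0.85, 0.15), c(0.80, 0.20), c(0.5, 0.5))
  rownames(qbar) <- paste0("i", 1:3)
  asg <- assign_clusters(qbar, 0.8)
  expect_equal(unname(asg$labels), c("cluster1", "cluster1", "admixed"))
  expect_equal(asg$assigned_fraction, 2 / 3)
  p <- partition(c("A", "A", "B"), ids = rownames(qbar))
  tal <- assign_clusters(qbar, 0.8, p)$tallies
  expect_equal(unname(tal["A", "cluster1"]), 2)
  expect_equal(unname(tal["B", "admixed"]), 1)
})

test_that("H', delta-K, and assignments are invariant to cluster relabeling", {
  set.seed(9)
  runs <- lapply(1:3, function(i) {
    Q <- matrix(runif(30), 10, 3); Q / rowSums(Q)
  })
  H0 <- align_runs(runs, seed = 2)$H
  perm <- c(2, 3, 1)
  H1 <- align_runs(lapply(runs, function(Q) Q[, perm]), seed = 2)$H
  expect_equal(H0, H1, tolerance = 1e-9)
  qbar <- runs[[1]]
  rownames(qbar) <- paste0("i", 1:10)
  l0 <- assign_clusters(qbar, 0.5)$labels
  l1 <- assign_clusters(qbar[, perm], 0.5)$labels
  relab <- function(lab, pm) ifelse(lab == "admixed", lab,
                                    paste0("cluster", match(as.integer(sub("cluster", "", lab)), pm)))
  expect_equal(unname(relab(l0, perm)), unname(l1))
})
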