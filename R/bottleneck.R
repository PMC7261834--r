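## Heterozygosity-excess bottleneck test: equilibrium gene diversity
## conditional on the observed allele count under IAM / SMM / TPM, one-tailed
## Wilcoxon aggregation, and the allele-frequency mode-shift test.

#' Two-phase mutation model parameters
#'
#' @param p_single Proportion of single-step mutations.
#' @param variance_multi Variance of the multi-step (geometric) component;
#'   the geometric parameter is chosen so the step-size variance equals
#'   this value.
#' @return A list of class `tpm_params`.
#' @export
tpm_params <- function(p_single = 0.95, variance_multi = 12) {
  stopifnot(p_single >= 0, p_single <= 1, variance_multi > 0)
  ## geometric on {1,2,...}: var = (1-g)/g^2 = variance_multi
  gpar <- (-1 + sqrt(1 + 4 * variance_multi)) / (2 * variance_multi)
  structure(list(p_single = p_single, variance_multi = variance_multi,
                 geom_prob = gpar), class = "tpm_params")
}

## One coalescent draw of n gene copies with mutation parameter theta
## (= 2 * n_e * mu on this time scale): returns allele states of the copies.
sim_coalescent_alleles <- function(n, theta, model, tpm) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  blen <- numeric(n_nodes)
  birth <- numeric(n_nodes)
  active <- seq_len(n)
  t <- 0
  nxt <- n
  for (j in n:2) {
    t <- t + rexp(1, j * (j - 1) / 2)
    pick <- sample.int(j, 2L)
    nxt <- nxt + 1L
    birth[nxt] <- t
    for (ch in active[pick]) {
      parent[ch] <- nxt
      blen[ch] <- t - birth[ch]
    }
    active <- c(active[-pick], nxt)
  }
  nmut <- rpois(n_nodes - 1L, theta / 2 * blen[-n_nodes])
  state <- numeric(n_nodes)
  if (model == "iam") {
    state[n_nodes] <- 0
    new_id <- 0
    for (v in (n_nodes - 1L):1L) {   # decreasing birth order: parents first
      state[v] <- if (nmut[v] > 0L) { new_id <- new_id + 1; new_id }
                  else state[parent[v]]
    }
  } else {
    tot <- sum(nmut)
    if (tot > 0L) {
      if (model == "smm") sizes <- rep(1L, tot)
      else sizes <- ifelse(runif(tot) < tpm$p_single, 1L,
                           rgeom(tot, tpm$geom_prob) + 1L)
      steps <- sizes * sign(runif(tot) - 0.5)
      ends <- cumsum(nmut)
      net <- numeric(n_nodes - 1L)
      has <- which(nmut > 0L)
      for (v in has)
        net[v] <- sum(steps[(ends[v] - nmut[v] + 1L):ends[v]])
    } else net <- numeric(n_nodes - 1L)
    state[n_nodes] <- 0
    for (v in (n_nodes - 1L):1L)
      state[v] <- state[parent[v]] + net[v]
  }
  state[seq_len(n)]
}

## Mean realized allele count at (n, theta) under a model, by simulation.
mean_allele_count <- function(n, theta, model, tpm, nrep = 60L) {
  mean(vapply(seq_len(nrep), function(i)
    length(unique(sim_coalescent_alleles(n, theta, model, tpm))), 0))
}

## Bisection on log-theta so that the expected allele count is ~ k.
tune_theta <- function(n, k, model, tpm) {
  if (model == "iam") {
    ## Ewens: E[k] = sum theta/(theta + i), i = 0..n-1 - solve directly
    f <- function(th) sum(th / (th + 0:(n - 1))) - k
    lo <- 1e-4; hi <- 1e4
    return(stats::uniroot(f, c(lo, hi))$root)
  }
  lo <- log(1e-3); hi <- log(2e3)
  for (it in 1:14) {
    mid <- (lo + hi) / 2
    mk <- mean_allele_count(n, exp(mid), model, tpm)
    if (mk < k) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Equilibrium gene diversity conditional on the observed allele count
#'
#' Simulates the coalescent of `n` gene copies with mutations under the
#' chosen mutation model, with the mutation rate tuned (bisection on the
#' expected allele count) and draws retained only when the realized allele
#' count equals `k` (rejection), giving the mutation-drift-equilibrium
#' distribution of gene diversity conditional on observing `k` alleles in
#' `n` copies.  Each retained draw scores the unbiased gene diversity
#' \eqn{H = \frac{n}{n-1}(1 - \sum p^2)}.
#'
#' @param n Gene copies sampled (2 per diploid individual).
#' @param k Observed allele count, `1 <= k <= n`.
#' @param model `"iam"`, `"smm"`, or `"tpm"`.
#' @param tpm [tpm_params()] (used for `model = "tpm"`).
#' @param n_iter Accepted draws to collect (>= 100).
#' @param seed Optional RNG seed.
#' @param theta Optional mutation parameter; by default tuned by bisection
#'   so the expected allele count matches `k`.  Under the IAM the allele
#'   configuration given `k` does not depend on theta (Ewens); under
#'   SMM/TPM it does, which is why [heterozygosity_excess_test()] passes a
#'   single dataset-level theta rather than re-tuning per locus.
#' @return A list: `mean`, `sd`, `draws` (length `n_iter`), `theta`,
#'   `acceptance`.
#' @export
simulate_heq <- function(n, k, model = c("iam", "smm", "tpm"),
                         tpm = tpm_params(), n_iter = 1000L, seed = NULL,
                         theta = NULL) {
  model <- match.arg(model)
  stopifnot(k >= 1L, k <= n, n_iter >= 100L)
  if (!is.null(seed)) set.seed(seed)
  if (k == 1L)
    return(list(mean = 0, sd = 0, draws = rep(0, n_iter), theta = 0,
                acceptance = 1))
  if (k == n) warning("k = n: every copy distinct; H_eq near its maximum")
  if (is.null(theta)) theta <- tune_theta(n, k, model, tpm)
  draws <- numeric(n_iter)
  got <- 0L; tried <- 0L
  max_try <- max(250L * n_iter, 25000L)
  while (got < n_iter) {
    tried <- tried + 1L
    if (tried > max_try && got / tried < 0.01)
      stop("rejection acceptance below 1%; widen the tuning bounds or ",
           "check (n, k) = (", n, ", ", k, ")")
    st <- sim_coalescent_alleles(n, theta, model, tpm)
    cnt <- table(st)
    if (length(cnt) != k) next
    p <- as.numeric(cnt) / n
    got <- got + 1L
    draws[got] <- n / (n - 1) * (1 - sum(p^2))
  }
  list(mean = mean(draws), sd = sd(draws), draws = draws,
       theta = theta, acceptance = got / tried)
}

#' Heterozygosity-excess bottleneck test
#'
#' For every polymorphic locus in the chosen group, compares the unbiased
#' expected heterozygosity \eqn{H_e} with the equilibrium distribution
#' \eqn{H_{eq}} simulated by [simulate_heq()] at that locus's gene-copy
#' and allele counts (all loci conditioned at one dataset-level mutation
#' parameter, tuned to the mean observed allele count), and aggregates the
#' per-locus signal with a one-tailed Wilcoxon signed-rank test toward
#' heterozygosity excess (the signature of a recent bottleneck).  The
#' primary `wilcoxon_p` is computed on the per-locus excess probabilities
#' centered at 1/2 -- a probability-integral transform that is uniform
#' under the mutation-drift-equilibrium null, giving a calibrated test;
#' `wilcoxon_p_classic` applies the same Wilcoxon to the raw differences
#' \eqn{H_e - \bar H_{eq}} (the classical form, conservative because the
#' conditional distribution of \eqn{H} given the allele count is skewed).
#' The exact Wilcoxon null is used up to 25 loci when ranks are untied,
#' the normal approximation with continuity correction otherwise.
#'
#' @param g A [genotype_matrix()].
#' @param p Optional [partition()]; with `group`, restricts the test to
#'   one group.
#' @param group Group label within `p` (omit to test the whole matrix).
#' @param model `"iam"`, `"smm"`, or `"tpm"`.
#' @param tpm [tpm_params()].
#' @param n_iter Equilibrium draws per locus.
#' @param seed Optional RNG seed.
#' @param heq_cache Optional environment memoizing [simulate_heq()] calls
#'   by `(model, n, k)`; pass the same environment across calls to reuse
#'   equilibrium distributions.
#' @return A list of class `bottleneck_report`: `per_locus` (data frame
#'   with n copies, k, `he`, `heq_mean`, `heq_sd`, standardized deviation
#'   `dh`, per-locus excess probability `p_excess`), `wilcoxon_p` and
#'   `wilcoxon_p_classic` (one-tailed, excess), `theta` (dataset-level
#'   tuned mutation parameter), `n_excess`/`n_deficit`, `model`.
#'   Monomorphic loci are excluded; fewer than 4 usable loci is an error.
#' @export
heterozygosity_excess_test <- function(g, p = NULL, group = NULL,
                                       model = c("iam", "smm", "tpm"),
                                       tpm = tpm_params(), n_iter = 1000L,
                                       seed = NULL, heq_cache = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(group)) {
    if (is.null(p)) stop("group given without a partition")
    p <- align_partition(g, p)
    rows <- which(as.character(p) == group)
    if (!length(rows)) stop("unknown group: ", group)
    if (length(rows) < 10L)
      warning("fewer than 10 individuals in group ", group)
    g <- gm_subset(g, rows)
  }
  if (is.null(heq_cache)) heq_cache <- new.env(parent = emptyenv())
  nk <- lapply(seq_len(n_loci(g)), function(l) {
    lc <- locus_codes(g, l)
    cnt <- locus_allele_counts(lc)
    n <- sum(cnt); k <- sum(cnt > 0)
    if (k < 2L || n < 4L) return(NULL)
    pfr <- cnt / n
    list(locus = g$loci[l], n = n, k = k,
         he = n / (n - 1) * (1 - sum(pfr^2)))
  })
  nk <- Filter(Negate(is.null), nk)
  if (length(nk) < 4L)
    stop("fewer than 4 polymorphic loci: Wilcoxon test not computed")
  ## one dataset-level theta per model, matched to the mean allele count at
  ## the median copy number, then snapped to a coarse log grid so
  ## equilibrium distributions can be reused across datasets
  kbar <- mean(vapply(nk, `[[`, 0, "k"))
  nmed <- stats::median(vapply(nk, `[[`, 0, "n"))
  key_t <- paste("theta", model, nmed, round(kbar, 1), sep = ":")
  if (is.null(heq_cache[[key_t]]))
    heq_cache[[key_t]] <- exp(round(log(tune_theta(nmed, kbar, model, tpm)),
                                    1))
  theta_hat <- heq_cache[[key_t]]
  ## probe pool of realized allele counts at theta_hat: loci whose k is in
  ## the far tail at the common rate fall back to per-locus tuning
  rows <- lapply(nk, function(x) {
    kp_key <- paste("kpool", model, x$n, theta_hat, sep = ":")
    if (is.null(heq_cache[[kp_key]]))
      heq_cache[[kp_key]] <- vapply(seq_len(500L), function(i)
        length(unique(sim_coalescent_alleles(x$n, theta_hat, model, tpm))),
        0L)
    use_common <- mean(heq_cache[[kp_key]] == x$k) >= 0.02
    key <- paste(model, x$n, x$k,
                 if (use_common) theta_hat else "tuned", sep = ":")
    if (is.null(heq_cache[[key]]))
      heq_cache[[key]] <- simulate_heq(x$n, x$k, model, tpm, n_iter,
                                       theta = if (use_common) theta_hat)
    hq <- heq_cache[[key]]
    data.frame(locus = x$locus, n_copies = x$n, k = x$k, he = x$he,
               heq_mean = hq$mean, heq_sd = hq$sd,
               dh = if (hq$sd > 0) (x$he - hq$mean) / hq$sd else NA_real_,
               p_excess = mean(hq$draws < x$he) +
                 0.5 * mean(hq$draws == x$he))
  })
  tab <- do.call(rbind, rows)
  d <- tab$he - tab$heq_mean
  u <- tab$p_excess - 0.5
  structure(list(per_locus = tab,
                 wilcoxon_p = .safe_wilcox_greater(u),
                 wilcoxon_p_classic = .safe_wilcox_greater(d),
                 theta = theta_hat,
                 n_excess = sum(u > 0), n_deficit = sum(u < 0),
                 model = model),
            class = "bottleneck_report")
}

## One-sided (greater) Wilcoxon signed-rank p; exact null up to 25 untied
## values, normal approximation with continuity correction otherwise.
## With no positive value the excess alternative has no support: p = 1.
.safe_wilcox_greater <- function(x) {
  if (!any(x > 0)) return(1)
  ok <- length(x) <= 25L && !any(x == 0) && !anyDuplicated(abs(x))
  suppressWarnings(wilcox.test(x, alternative = "greater",
                               exact = ok, correct = TRUE)$p.value)
}

#' @export
print.bottleneck_report <- function(x, ...) {
  cat(sprintf("bottleneck_report (%s): %d loci, %d excess / %d deficit, one-tailed Wilcoxon p = %.4g\n",
              toupper(x$model), nrow(x$per_locus), x$n_excess, x$n_deficit,
              x$wilcoxon_p))
  invisible(x)
}

#' Allele-frequency mode-shift test
#'
#' Pools all alleles over loci within the chosen group, bins their
#' within-group frequencies into ten classes of width 0.1, and flags the
#' distribution as `"shifted"` when the modal class is not the lowest
#' (0-0.1) class.  A stable population at mutation-drift equilibrium shows
#' an L-shaped distribution dominated by rare alleles; a recent bottleneck
#' shifts the mode into intermediate classes.
#'
#' @inheritParams heterozygosity_excess_test
#' @return A list: `histogram` (proportions per frequency class, summing
#'   to 1), `shape` (`"L-shaped"` or `"shifted"`), `n_alleles`.
#' @export
mode_shift <- function(g, p = NULL, group = NULL) {
  if (!is.null(group)) {
    if (is.null(p)) stop("group given without a partition")
    p <- align_partition(g, p)
    g <- gm_subset(g, which(as.character(p) == group))
  }
  freqs <- unlist(lapply(seq_len(n_loci(g)), function(l) {
    cnt <- locus_allele_counts(locus_codes(g, l))
    tot <- sum(cnt)
    if (tot == 0) return(numeric(0))
    (cnt / tot)[cnt > 0]
  }))
  if (!length(freqs)) stop("no scored alleles")
  cls <- cut(freqs, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE)
  h <- as.numeric(table(cls)) / length(freqs)
  names(h) <- levels(cls)
  list(histogram = h,
       shape = if (which.max(h) == 1L) "L-shaped" else "shifted",
       n_alleles = length(freqs))
}
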