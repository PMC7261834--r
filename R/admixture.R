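#' Bayesian admixture clustering of a genotype panel
#'
#' Gibbs sampler for the admixture model: each individual carries a
#' membership vector Q over `K` clusters; each allele copy originates from
#' one cluster and is drawn from that cluster's locus allele frequencies P.
#' The sampler alternates (i) the latent origin of every allele copy given
#' Q and P, (ii) P given the origins (Dirichlet posterior; under the
#' correlated-frequency model, an F-model prior around sampled ancestral
#' frequencies with one drift parameter per cluster), (iii) Q given the
#' origins (Dirichlet(alpha + counts)), and (iv) the concentration alpha by
#' a Metropolis step under a uniform(0, 10) prior.  Missing calls
#' contribute nothing.  Reported Q and P are posterior means over
#' post-burn-in thinned samples.
#'
#' Chain lengths are the caller's choice; published analyses of panels of
#' this kind typically use a burn-in of 100,000 followed by 1,000,000
#' iterations, while the defaults here are desk-scale.
#'
#' @param g A [genotype_matrix()].
#' @param K Number of clusters (`K = 1` returns the degenerate all-ones Q
#'   and the log-likelihood of the frequency-only model).
#' @param burn_in,iterations,thinning MCMC control; `iterations` counts
#'   post-burn-in sweeps.
#' @param model `"independent"` (default) or `"correlated"` cluster allele
#'   frequencies.
#' @param seed Optional RNG seed (bitwise-reproducible trace).
#' @return An object of class `admixture_result`: list with `K`, `Q`
#'   (individuals x K, rows sum to 1), `P` (per-locus cluster allele
#'   frequency matrices with allele codes as column names), `alpha`,
#'   `lnl_trace`, `mean_lnl`, `var_lnl`, `mcmc`, `model`, `seed`.
#' @export
fit_admixture <- function(g, K, burn_in = 2000L, iterations = 10000L,
                          thinning = 10L,
                          model = c("independent", "correlated"),
                          seed = NULL) {
  model <- match.arg(model)
  stopifnot(K >= 1L, iterations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lcs <- lapply(seq_len(n_loci(g)), function(l) locus_codes(g, l))
  empty <- vapply(lcs, function(lc) length(lc$codes) == 0L, TRUE)
  if (any(empty)) {
    warning("dropping ", sum(empty), " entirely missing locus/loci")
    lcs <- lcs[!empty]
  }
  n <- n_ind(g); L <- length(lcs)
  A1 <- vapply(lcs, function(lc) ifelse(is.na(lc$idx1), -1L, lc$idx1 - 1L),
               integer(n))
  A2 <- vapply(lcs, function(lc) ifelse(is.na(lc$idx2), -1L, lc$idx2 - 1L),
               integer(n))
  A1 <- matrix(A1, nrow = n); A2 <- matrix(A2, nrow = n)
  nall <- vapply(lcs, function(lc) length(lc$codes), 0L)
  if (K == 1L) {
    Q <- matrix(1, n, 1)
    lnl <- 0
    P <- vector("list", L)
    for (l in seq_len(L)) {
      cnt <- locus_allele_counts(lcs[[l]])
      pfr <- cnt / sum(cnt)
      P[[l]] <- matrix(pfr, nrow = 1,
                       dimnames = list(NULL, lcs[[l]]$codes))
      obs <- c(A1[, l], A2[, l]); obs <- obs[obs >= 0L] + 1L
      lnl <- lnl + sum(log(pfr[obs]))
    }
    res <- list(K = 1L, Q = Q, P = P, alpha = NA_real_, lnl_trace = lnl,
                mean_lnl = lnl, var_lnl = 0,
                mcmc = c(burn_in = burn_in, iterations = iterations,
                         thinning = thinning),
                model = model, seed = seed)
    class(res) <- "admixture_result"
    return(res)
  }
  fit <- .gibbs_admixture(A1, A2, nall, K, as.integer(burn_in),
                          as.integer(iterations), as.integer(thinning),
                          model == "correlated", 1.0, 1.0, 0.25, 10.0)
  rownames(fit$Q) <- g$ids
  for (l in seq_len(L)) colnames(fit$P[[l]]) <- lcs[[l]]$codes
  res <- list(K = as.integer(K), Q = fit$Q, P = fit$P, alpha = fit$alpha,
              lnl_trace = fit$lnl_trace,
              mean_lnl = mean(fit$lnl_trace), var_lnl = var(fit$lnl_trace),
              mcmc = c(burn_in = burn_in, iterations = iterations,
                       thinning = thinning),
              model = model, seed = seed)
  class(res) <- "admixture_result"
  res
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture_result: K = %d, %d individuals, mean lnL = %.1f, alpha = %.3f\n",
              x$K, nrow(x$Q), x$mean_lnl, x$alpha))
  invisible(x)
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (first in seq_len(k)) {
    rest <- matrix(setdiff(seq_len(k), first)[sub], ncol = k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  out
}

## Best column permutation of Q2 to match Q1: maximizes sum(Q1 * Q2[, perm]).
## Exhaustive for K <= 7, greedy otherwise.
best_permutation <- function(Q1, Q2) {
  K <- ncol(Q1)
  S <- crossprod(Q1, Q2)   # S[j, k] = sum Q1[,j] * Q2[,k]
  if (K <= 7L) {
    perms <- all_permutations(K)
    sc <- apply(perms, 1L, function(pm) sum(S[cbind(seq_len(K), pm)]))
    perms[which.max(sc), ]
  } else {
    perm <- integer(K)
    taken <- rep(FALSE, K)
    for (j in order(-apply(S, 1L, max))) {
      k <- which.max(ifelse(taken, -Inf, S[j, ]))
      perm[j] <- k; taken[k] <- TRUE
    }
    perm
  }
}

#' Align replicate admixture runs and score their agreement
#'
#' Resolves label switching across replicate runs of [fit_admixture()] at
#' the same `K`: each run is aligned, by its best column permutation, to
#' the element-wise mean of the previously aligned runs (greedy growth;
#' repeated over `n_orders` random run orders, keeping the ordering with
#' the highest mean similarity).  The pairwise similarity of two aligned
#' runs is \eqn{S(Q, Q') = 1 - \|Q - Q'\|_F / \sqrt{2n}}, and `H'` is the
#' mean over run pairs.
#'
#' @param runs List of Q matrices (or `admixture_result`s) with identical
#'   dimensions.
#' @param n_orders Random input orders tried (1 keeps the given order).
#' @param seed Optional RNG seed.
#' @return A list: `aligned` (list of permuted Q matrices), `consensus`
#'   (element-wise mean, rows re-normalized), `H` (the H' coefficient),
#'   `permutations`.
#' @export
align_runs <- function(runs, n_orders = 100L, seed = NULL) {
  runs <- lapply(runs, function(r) if (inherits(r, "admixture_result")) r$Q else r)
  dims <- vapply(runs, dim, integer(2L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all runs must have identical dimensions")
  R <- length(runs)
  n <- dims[1, 1]
  if (R == 1L)
    return(list(aligned = runs, consensus = runs[[1L]], H = 1,
                permutations = list(seq_len(dims[2, 1]))))
  if (!is.null(seed)) set.seed(seed)
  score_order <- function(ord) {
    aligned <- vector("list", R)
    perms <- vector("list", R)
    ref <- runs[[ord[1L]]]
    aligned[[ord[1L]]] <- ref
    perms[[ord[1L]]] <- seq_len(ncol(ref))
    acc <- ref
    cnt <- 1L
    for (r in ord[-1L]) {
      pm <- best_permutation(acc / cnt, runs[[r]])
      aligned[[r]] <- runs[[r]][, pm, drop = FALSE]
      perms[[r]] <- pm
      acc <- acc + aligned[[r]]
      cnt <- cnt + 1L
    }
    sims <- combn(R, 2L, function(ij)
      1 - norm(aligned[[ij[1L]]] - aligned[[ij[2L]]], "F") / sqrt(2 * n))
    list(aligned = aligned, perms = perms, H = mean(sims))
  }
  best <- score_order(seq_len(R))
  if (n_orders > 1L) for (o in seq_len(n_orders - 1L)) {
    cand <- score_order(sample.int(R))
    if (cand$H > best$H) best <- cand
  }
  consensus <- Reduce(`+`, best$aligned) / R
  consensus <- consensus / rowSums(consensus)
  rownames(consensus) <- rownames(runs[[1L]])
  list(aligned = best$aligned, consensus = consensus, H = best$H,
       permutations = best$perms)
}

#' Evanno's delta-K diagnostic
#'
#' \eqn{\Delta K = |L(K-1) - 2L(K) + L(K+1)| / s(K)}: the absolute second
#' difference of the mean log-likelihood across consecutive `K`, divided
#' by the between-run standard deviation at `K`.  Undefined at the
#' endpoints of the K range; infinite (with a warning) where `s(K) = 0`.
#'
#' @param mean_lnl Named or plain numeric vector of mean log-likelihoods
#'   over runs, at consecutive K values.
#' @param sd_lnl Between-run standard deviations, same length.
#' @param k_values The K values (default `seq_along(mean_lnl)`).
#' @return Named numeric vector of delta-K at the interior K values.
#' @export
evanno_delta_k <- function(mean_lnl, sd_lnl, k_values = seq_along(mean_lnl)) {
  m <- length(mean_lnl)
  if (m < 3L) stop("delta-K needs at least 3 consecutive K values")
  if (any(diff(k_values) != 1))
    stop("K values must be consecutive")
  idx <- 2:(m - 1L)
  num <- abs(mean_lnl[idx - 1L] - 2 * mean_lnl[idx] + mean_lnl[idx + 1L])
  s <- sd_lnl[idx]
  if (any(s == 0)) warning("zero between-run sd: delta-K infinite")
  setNames(num / s, k_values[idx])
}

#' Replicate-run ensemble over a range of K
#'
#' Runs [fit_admixture()] `n_runs` times per K, and summarizes the
#' ensemble: mean and sd of the run mean log-likelihoods, Evanno's
#' delta-K, and the between-run similarity H' from [align_runs()].
#'
#' @inheritParams fit_admixture
#' @param k_values Integer vector of consecutive K values.
#' @param n_runs Replicate runs per K.
#' @param n_orders Random input orders for alignment.
#' @param seed Seed; run `r` at K uses `seed + 1000*K + r`.
#' @return A list: `runs` (list over K of lists of `admixture_result`),
#'   `summary` (data frame K, mean_lnl, sd_lnl, delta_k, H),
#'   `consensus` (list over K of consensus Q matrices).
#' @export
admixture_ensemble <- function(g, k_values, n_runs = 3L, burn_in = 1000L,
                               iterations = 4000L, thinning = 10L,
                               model = "independent", n_orders = 20L,
                               seed = 1L) {
  k_values <- as.integer(k_values)
  runs <- consensus <- vector("list", length(k_values))
  names(runs) <- names(consensus) <- k_values
  Hs <- Ls <- Ss <- rep(NA_real_, length(k_values))
  for (ki in seq_along(k_values)) {
    K <- k_values[ki]
    rr <- lapply(seq_len(n_runs), function(r)
      fit_admixture(g, K, burn_in, iterations, thinning, model,
                    seed = seed + 1000L * K + r))
    runs[[ki]] <- rr
    ml <- vapply(rr, `[[`, 0, "mean_lnl")
    Ls[ki] <- mean(ml); Ss[ki] <- sd(ml)
    if (K == 1L) {
      Hs[ki] <- 1
      consensus[[ki]] <- rr[[1L]]$Q
    } else {
      al <- align_runs(rr, n_orders = n_orders, seed = seed + K)
      Hs[ki] <- al$H
      consensus[[ki]] <- al$consensus
    }
  }
  dk <- rep(NA_real_, length(k_values))
  if (length(k_values) >= 3L)
    dk[2:(length(k_values) - 1L)] <-
      evanno_delta_k(Ls, Ss, k_values)
  list(runs = runs,
       summary = data.frame(K = k_values, mean_lnl = Ls, sd_lnl = Ss,
                            delta_k = dk, H = Hs),
       consensus = consensus)
}

#' Threshold-based cluster assignment from a consensus Q
#'
#' Assigns each individual to its argmax cluster when the maximum
#' membership reaches the threshold `q_star` (inclusive; ties to the
#' lowest cluster index), and to `"admixed"` otherwise.
#'
#' @param qbar Consensus membership matrix (rows sum to 1).
#' @param q_star Assignment threshold (default 0.8).
#' @param p Optional [partition()] for per-group tallies.
#' @return A list: `labels` (character vector `cluster<k>` or
#'   `"admixed"`), `assigned_fraction`, and `tallies` (group x label
#'   table, when `p` given).
#' @export
assign_clusters <- function(qbar, q_star = 0.8, p = NULL) {
  stopifnot(all(abs(rowSums(qbar) - 1) < 1e-6))
  k <- max.col(qbar, ties.method = "first")
  mx <- qbar[cbind(seq_len(nrow(qbar)), k)]
  lab <- ifelse(mx >= q_star, paste0("cluster", k), "admixed")
  names(lab) <- rownames(qbar)
  out <- list(labels = lab, assigned_fraction = mean(mx >= q_star),
              q_star = q_star)
  if (!is.null(p)) {
    ids <- rownames(qbar)
    if (is.null(ids) || anyNA(match(ids, names(p))))
      stop("per-group tallies need a partition covering the Q rows")
    out$tallies <- table(group = as.character(p[ids]), label = lab)
  }
  out
}
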