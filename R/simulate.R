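## Forward simulation of admixed SSR genotype panels under the F-model
## (latent clusters with drift-correlated allele frequencies).

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) { x[which.max(alpha)] <- 1 }
  x / sum(x)
}

## Vectorized categorical sampling: one draw per row of a row-stochastic
## matrix P; returns 1-based column indices.
sample_rows_categorical <- function(P) {
  cs <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
  pmin(rowSums(cs < runif(nrow(P))) + 1L, ncol(P))
}

#' Specification for the admixed-panel genotype generator
#'
#' Describes a panel of diploid individuals drawn from `K` latent clusters
#' whose allele frequencies are correlated with a shared ancestral pool
#' through per-cluster drift parameters `F` (the F-model: cluster
#' frequencies are Dirichlet with parameters
#' \eqn{p_{anc} (1-F_k)/F_k}, so `F` is interpretable on the
#' \eqn{F_{ST}} scale).
#'
#' @param K Number of latent clusters.
#' @param loci Either an integer vector of allele counts per locus
#'   (ancestral frequencies then drawn Dirichlet(1) over codes
#'   `100 + 2*(0:(m-1))`), or a list of named numeric vectors of ancestral
#'   allele frequencies (names = integer allele codes).
#' @param drift Per-cluster drift parameter, each in (0, 1) (recycled).
#' @param admixture Individuals x K matrix of mixing proportions, rows
#'   summing to 1.
#' @param missing_rate Probability a call is masked missing, per call.
#' @param null_allele_rate Probability that a locus carries a null allele
#'   (the highest-coded allele of that locus is then unamplifiable).
#' @param seed Integer seed for all generator randomness.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(K, loci, drift, admixture,
                           missing_rate = 0, null_allele_rate = 0,
                           seed = 1L) {
  admixture <- as.matrix(admixture)
  if (ncol(admixture) != K) stop("admixture must have K columns")
  if (any(abs(rowSums(admixture) - 1) > 1e-9))
    stop("admixture rows must sum to 1")
  drift <- rep_len(drift, K)
  if (any(drift <= 0 | drift >= 1)) stop("drift parameters must be in (0,1)")
  if (missing_rate < 0 || missing_rate >= 1 ||
      null_allele_rate < 0 || null_allele_rate >= 1)
    stop("rates must be in [0,1)")
  if (is.numeric(loci) && is.null(dim(loci))) {
    loci <- lapply(loci, function(m) {
      stats::setNames(rep(NA_real_, m), 100L + 2L * (seq_len(m) - 1L))
    })
  }
  structure(list(K = K, loci = loci, drift = drift, admixture = admixture,
                 n = nrow(admixture), missing_rate = missing_rate,
                 null_allele_rate = null_allele_rate, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Draw cluster allele frequencies under the F-model
#'
#' For cluster `k` and locus `l`, frequencies are Dirichlet with parameter
#' vector \eqn{p_{anc} (1-F_k)/F_k}.  Ancestral frequencies left
#' unspecified in the spec are drawn Dirichlet(1) first.  Ancestral alleles
#' with zero frequency are dropped with a warning.
#'
#' @param spec A [generator_spec()].
#' @return A list per locus: `codes` (integer allele codes), `ancestral`
#'   (frequency vector), `freq` (alleles x K cluster frequency matrix).
#'   Reproducible under `spec$seed`.
#' @export
sample_cluster_frequencies <- function(spec) {
  set.seed(spec$seed)
  lapply(seq_along(spec$loci), function(l) {
    anc <- spec$loci[[l]]
    codes <- as.integer(names(anc))
    if (all(is.na(anc))) anc <- rdirichlet1(rep(1, length(anc)))
    if (any(anc == 0)) {
      warning("dropping zero-frequency ancestral allele(s) at locus ", l)
      keep <- anc > 0
      anc <- anc[keep] / sum(anc[keep]); codes <- codes[keep]
    }
    freq <- vapply(seq_len(spec$K), function(k)
      rdirichlet1(anc * (1 - spec$drift[k]) / spec$drift[k]),
      numeric(length(anc)))
    list(codes = codes, ancestral = unname(anc),
         freq = matrix(freq, ncol = spec$K))
  })
}

#' Generate a diploid genotype panel from cluster frequencies
#'
#' Each allele copy is drawn by sampling its cluster of origin from the
#' individual's admixture row, then an allele from that cluster's locus
#' frequencies, so genotypes within a pure cluster are Hardy-Weinberg in
#' expectation.  Missing-data masking is applied per call; at loci with a
#' null allele, null homozygotes become missing and null heterozygotes
#' appear homozygous for the visible allele.
#'
#' @param spec A [generator_spec()].
#' @param freqs Output of [sample_cluster_frequencies()] for `spec`.
#' @return A list: `genotypes` ([genotype_matrix()]), `partition` (true
#'   max-ancestry labels `cluster1..K`, ties to the lowest index),
#'   `Q` (the true admixture design), and `null_loci` (indices of loci
#'   carrying a null allele).
#' @export
generate_genotypes <- function(spec, freqs) {
  set.seed(spec$seed + 1L)
  n <- spec$n; L <- length(freqs)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  Q <- spec$admixture
  null_loci <- which(runif(L) < spec$null_allele_rate)
  for (l in seq_len(L)) {
    fr <- freqs[[l]]
    for (copy in 1:2) {
      z <- sample_rows_categorical(Q)
      pa <- t(fr$freq)[z, , drop = FALSE]     # n x alleles
      al <- fr$codes[sample_rows_categorical(pa)]
      if (copy == 1L) a1[, l] <- al else a2[, l] <- al
    }
    if (l %in% null_loci) {
      null_code <- max(fr$codes)
      both <- a1[, l] == null_code & a2[, l] == null_code
      one1 <- a1[, l] == null_code & !both
      one2 <- a2[, l] == null_code & !both
      a1[both, l] <- NA_integer_; a2[both, l] <- NA_integer_
      a1[one1, l] <- a2[one1, l]
      a2[one2, l] <- a1[one2, l]
    }
  }
  if (spec$missing_rate > 0) {
    mask <- matrix(runif(n * L) < spec$missing_rate, n, L)
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
  }
  g <- genotype_matrix(a1, a2)
  lab <- paste0("cluster", max.col(Q, ties.method = "first"))
  list(genotypes = g,
       partition = partition(lab, ids = g$ids,
                             levels = paste0("cluster", seq_len(spec$K))),
       Q = Q, null_loci = null_loci)
}

#' Worldwide SSR germplasm panel preset
#'
#' Emulates the structure of a worldwide apricot germplasm panel: 890
#' accessions in 7 geographic groups, 25 SSR loci with 18-32 ancestral
#' alleles each, 5 latent clusters whose drift parameters put the realized
#' global multi-cluster \eqn{F_{ST}} near 0.17, and about 30% admixed
#' individuals (maximum membership below 0.8).  Geographic groups map onto
#' clusters as: Eastern Asia to cluster 1, Central Asia to cluster 2
#' (least drifted, hence most diverse), Irano-Caucasian plus part of North
#' Africa to cluster 3, Continental Europe to cluster 4 (most drifted),
#' Mediterranean Europe plus the remainder of North Africa to cluster 5;
#' the America group is mostly admixed between clusters 2 and 5.
#'
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return A list: `genotypes`, `groups` (geographic [partition()]),
#'   `clusters` (true max-ancestry cluster partition), `Q` (true admixture
#'   design), and `spec`.
#' @export
worldwide_preset <- function(seed = 1L) {
  set.seed(seed)
  sizes <- c("Eastern Asia" = 67, "Central Asia" = 142,
             "Irano-Caucasian" = 86, "Continental Europe" = 86,
             "Mediterranean Europe" = 250, "North Africa" = 214,
             "America" = 45)
  drift <- c(0.31, 0.10, 0.21, 0.49, 0.21)
  ## per group: list of (weight, pure cluster) and admixed recipes
  comp <- list(
    "Eastern Asia"         = list(pure = c("1" = 0.85), adm = list(c(1, 2), c(1, 5))),
    "Central Asia"         = list(pure = c("2" = 0.75), adm = list(c(2, 1), c(2, 3))),
    "Irano-Caucasian"      = list(pure = c("3" = 0.70), adm = list(c(3, 5), c(3, 2))),
    "Continental Europe"   = list(pure = c("4" = 0.85), adm = list(c(4, 5))),
    "Mediterranean Europe" = list(pure = c("5" = 0.62), adm = list(c(5, 3), c(5, 1))),
    "North Africa"         = list(pure = c("3" = 0.52, "5" = 0.20), adm = list(c(3, 5))),
    "America"              = list(pure = c("2" = 0.05, "5" = 0.33), adm = list(c(5, 2)),
                                  wrange = c(0.60, 0.75)))
  n <- sum(sizes)
  Q <- matrix(0, n, 5)
  grp <- character(n)
  i <- 0L
  for (gname in names(sizes)) {
    ng <- sizes[[gname]]
    cp <- comp[[gname]]
    n_pure <- round(ng * cp$pure)
    n_adm <- ng - sum(n_pure)
    for (k in names(n_pure)) {
      kk <- as.integer(k)
      for (j in seq_len(n_pure[[k]])) {
        i <- i + 1L; Q[i, kk] <- 1; grp[i] <- gname
      }
    }
    wr <- if (is.null(cp$wrange)) c(0.25, 0.75) else cp$wrange
    for (j in seq_len(n_adm)) {
      i <- i + 1L
      pair <- cp$adm[[1L + (j - 1L) %% length(cp$adm)]]
      w <- runif(1, wr[1L], wr[2L])
      Q[i, pair[1L]] <- w; Q[i, pair[2L]] <- 1 - w
      grp[i] <- gname
    }
  }
  m_alleles <- sample(18:32, 25, replace = TRUE)
  spec <- generator_spec(K = 5, loci = m_alleles, drift = drift,
                         admixture = Q, missing_rate = 0.02,
                         null_allele_rate = 0, seed = seed)
  freqs <- sample_cluster_frequencies(spec)
  sim <- generate_genotypes(spec, freqs)
  groups <- partition(grp, ids = sim$genotypes$ids, levels = names(sizes))
  list(genotypes = sim$genotypes, groups = groups,
       clusters = sim$partition, Q = sim$Q, spec = spec)
}
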