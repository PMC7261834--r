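# Shared fixtures: all built in code at test time.

## Genotype matrix from a compact spec: list of "a/b" strings per
## individual (NA for missing), loci in columns.
gm_from_calls <- function(calls, ids = NULL, loci = NULL) {
  n <- length(calls); L <- length(calls[[1L]])
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) for (j in seq_len(L)) {
    cl <- calls[[i]][j]
    if (is.na(cl)) next
    ab <- as.integer(strsplit(cl, "/")[[1L]])
    a1[i, j] <- ab[1L]; a2[i, j] <- ab[2L]
  }
  genotype_matrix(a1, a2, ids = ids, loci = loci)
}

## Random diploid panel drawn from per-locus uniform allele frequencies.
random_gm <- function(n, L, alleles = 5L, missing_rate = 0, seed = 1L) {
  set.seed(seed)
  a1 <- matrix(sample.int(alleles, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample.int(alleles, n * L, replace = TRUE), n, L)
  if (missing_rate > 0) {
    mask <- matrix(runif(n * L) < missing_rate, n, L)
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
  }
  genotype_matrix(a1, a2)
}

## Two well-separated clusters: fixed for disjoint alleles at every locus.
fixed_difference_gm <- function(n_per = 10L, L = 5L) {
  a <- matrix(1L, 2L * n_per, L)
  a[(n_per + 1L):(2L * n_per), ] <- 2L
  g <- genotype_matrix(a, a)
  p <- partition(rep(c("g1", "g2"), each = n_per), ids = g$ids)
  list(g = g, p = p)
}

## Panmictic HWE sample at given allele frequencies (one locus).
hwe_locus_gm <- function(n, freqs, seed = 1L) {
  set.seed(seed)
  m <- length(freqs)
  a1 <- matrix(sample.int(m, n, replace = TRUE, prob = freqs), n, 1)
  a2 <- matrix(sample.int(m, n, replace = TRUE, prob = freqs), n, 1)
  genotype_matrix(a1, a2)
}

## Single-population constant-size scenario (no events).
one_pop_scenario <- function(n = 50L, r = 1, change_time = 0.1, theta = 5,
                             gsm = tpm_params(p_single = 1)) {
  demographic_scenario(c(pop1 = as.integer(n)), r = r,
                       change_time = change_time,
                       splits = data.frame(time = numeric(0),
                                           from = character(0),
                                           to = character(0)),
                       theta = theta, gsm = gsm)
}
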