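## Per-locus and per-group diversity statistics for codominant markers.

## Weir & Cockerham within-population variance components (b, c) for one
## locus in one sample.  Returns per-allele b and c; F_IS = 1 - sum(c)/sum(b+c).
wc_within_components <- function(lc, rows = NULL) {
  i1 <- lc$idx1; i2 <- lc$idx2
  if (!is.null(rows)) { i1 <- i1[rows]; i2 <- i2[rows] }
  keep <- !is.na(i1)
  i1 <- i1[keep]; i2 <- i2[keep]
  n <- length(i1)
  if (n < 2L) return(NULL)
  m <- length(lc$codes)
  cnt <- tabulate(c(i1, i2), nbins = m)
  p <- cnt / (2 * n)
  het <- i1 != i2
  ## h_a: frequency of individuals heterozygous *for* allele a
  h <- (tabulate(i1[het], nbins = m) + tabulate(i2[het], nbins = m)) / n
  b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  list(b = b, c = h / 2, n = n, p = p, het = mean(het))
}

fis_from_components <- function(bc) {
  tb <- sum(vapply(bc, function(x) sum(x$b), 0))
  tc <- sum(vapply(bc, function(x) sum(x$c), 0))
  if (tb + tc <= 0) return(NA_real_)
  1 - tc / (tb + tc)
}

## One-sided permutation p-value for heterozygote deficit: permute gene
## copies among individuals within the sample, locus by locus.
fis_permutation_p <- function(g, rows = NULL, n_perm = 1000L) {
  lcs <- lapply(seq_len(n_loci(g)), function(l) locus_codes(g, l))
  obs_bc <- Filter(Negate(is.null),
                   lapply(lcs, wc_within_components, rows = rows))
  obs <- fis_from_components(obs_bc)
  if (is.na(obs) || n_perm < 1L) return(c(fis = obs, p = NA_real_))
  ge <- 0L
  for (b in seq_len(n_perm)) {
    bc <- vector("list", length(lcs))
    for (l in seq_along(lcs)) {
      lc <- lcs[[l]]
      i1 <- lc$idx1; i2 <- lc$idx2
      if (!is.null(rows)) { i1 <- i1[rows]; i2 <- i2[rows] }
      keep <- !is.na(i1)
      copies <- sample(c(i1[keep], i2[keep]))
      n <- length(copies) %/% 2L
      if (n < 2L) next
      perm <- list(codes = lc$codes, idx1 = copies[seq_len(n)],
                   idx2 = copies[n + seq_len(n)])
      bc[[l]] <- wc_within_components(perm)
    }
    bc <- Filter(Negate(is.null), bc)
    if (length(bc) && !is.na(f <- fis_from_components(bc)) && f >= obs)
      ge <- ge + 1L
  }
  c(fis = obs, p = (ge + 1) / (n_perm + 1))
}

#' Per-locus diversity summary
#'
#' Computes, for every locus, the columns of a classical SSR diversity
#' table: observed allele count (`NA_` as `n_alleles`), effective allele
#' count \eqn{N_E = 1/\sum p^2}, rarefied allelic richness, major-allele
#' frequency, Shannon information index \eqn{I = -\sum p \ln p}, observed
#' heterozygosity, unbiased expected heterozygosity
#' \eqn{H_E = \frac{2n}{2n-1}(1-\sum p^2)}, and the Weir-Cockerham
#' inbreeding coefficient \eqn{F_{IS}} with a one-sided permutation p-value
#' (heterozygote-deficit alternative).  Allele frequencies use non-missing
#' calls only.
#'
#' @param g A [genotype_matrix()].
#' @param rarefaction_g Rarefaction size in gene copies for allelic
#'   richness; `"auto"` (default) uses the smallest non-missing copy count
#'   over loci.
#' @param n_perm Permutations for the \eqn{F_{IS}} test per locus
#'   (0 disables; p-values then `NA`).
#' @param seed Optional RNG seed for the permutations.
#' @return A data frame with one row per locus, plus attribute
#'   `"multilocus"`: unweighted means over loci, with `fis` pooled over
#'   variance components (and `fis_mean`, the mean of per-locus ratios).
#'   Entirely missing loci are dropped with a warning.  Monomorphic loci
#'   report `fis = NA`.
#' @export
locus_summary <- function(g, rarefaction_g = "auto", n_perm = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(g)
  lcs <- lapply(seq_len(L), function(l) locus_codes(g, l))
  nn <- vapply(lcs, function(lc) sum(!is.na(lc$idx1)), 0L)
  if (any(nn == 0L)) {
    warning("dropping ", sum(nn == 0L), " entirely missing locus/loci")
    keep <- nn > 0L
    lcs <- lcs[keep]; loci <- g$loci[keep]; nn <- nn[keep]
  } else loci <- g$loci
  if (identical(rarefaction_g, "auto")) rarefaction_g <- min(2L * nn)
  rows <- lapply(seq_along(lcs), function(l) {
    lc <- lcs[[l]]
    cnt <- locus_allele_counts(lc)
    n <- nn[l]
    p <- cnt / sum(cnt)
    ne <- 1 / sum(p^2)
    he <- 2 * n / (2 * n - 1) * (1 - sum(p^2))
    het <- lc$idx1 != lc$idx2
    ho <- mean(het[!is.na(het)])
    bc <- wc_within_components(lc)
    fis <- if (length(lc$codes) < 2L || is.null(bc)) NA_real_ else
      fis_from_components(list(bc))
    data.frame(locus = loci[l], n = n,
               n_alleles = length(lc$codes),
               n_effective = ne,
               allelic_richness = rarefy_counts(cnt, rarefaction_g),
               major_allele_freq = max(p),
               shannon = -sum(p[p > 0] * log(p[p > 0])),
               ho = ho, he = he, fis = fis, fis_p = NA_real_)
  })
  res <- do.call(rbind, rows)
  if (n_perm > 0L) {
    for (l in seq_along(lcs)) {
      gl <- gm_subset(g, loci = match(loci[l], g$loci))
      pr <- fis_permutation_p(gl, n_perm = n_perm)
      res$fis_p[l] <- pr["p"]
    }
  }
  bc_all <- Filter(Negate(is.null), lapply(lcs, wc_within_components))
  multi <- data.frame(n_alleles = mean(res$n_alleles),
                      n_effective = mean(res$n_effective),
                      allelic_richness = mean(res$allelic_richness),
                      shannon = mean(res$shannon),
                      ho = mean(res$ho), he = mean(res$he),
                      fis = fis_from_components(bc_all),
                      fis_mean = mean(res$fis, na.rm = TRUE))
  attr(res, "multilocus") <- multi
  attr(res, "rarefaction_g") <- rarefaction_g
  res
}

## Hypergeometric rarefaction of an allele count vector to s gene copies.
rarefy_counts <- function(cnt, s) {
  tot <- sum(cnt)
  if (s < 1) stop("rarefaction size must be >= 1")
  s <- min(s, tot)
  sum(1 - exp(lchoose(tot - cnt, s) - lchoose(tot, s)))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of
#' `rarefaction_g` gene copies (hypergeometric rarefaction):
#' \eqn{A_R = \sum_i [1 - \binom{2n-n_i}{g}/\binom{2n}{g}]}.  Computed per
#' locus, within each group when a partition is supplied.
#'
#' @inheritParams locus_summary
#' @param p Optional [partition()]; when given, richness is computed per
#'   group x locus and `"auto"` rarefies to the smallest non-missing copy
#'   count over group x locus cells.
#' @return Without `p`: a named vector over loci.  With `p`: a matrix
#'   (groups x loci) with attribute `"rarefaction_g"`; group means are in
#'   attribute `"group_means"`.
#' @export
allelic_richness <- function(g, p = NULL, rarefaction_g = "auto") {
  if (!identical(rarefaction_g, "auto") && rarefaction_g < 2)
    stop("rarefaction size must be >= 2 gene copies")
  lcs <- lapply(seq_len(n_loci(g)), function(l) locus_codes(g, l))
  if (is.null(p)) {
    cnts <- lapply(lcs, locus_allele_counts)
    if (identical(rarefaction_g, "auto"))
      rarefaction_g <- min(vapply(cnts, sum, 0))
    ar <- vapply(cnts, rarefy_counts, 0, s = rarefaction_g)
    names(ar) <- g$loci
    attr(ar, "rarefaction_g") <- rarefaction_g
    return(ar)
  }
  p <- align_partition(g, p)
  grp_rows <- split(seq_along(p), p)
  cnts <- lapply(grp_rows, function(rows)
    lapply(lcs, locus_allele_counts, rows = rows))
  copy_counts <- unlist(lapply(cnts, vapply, sum, 0))
  if (identical(rarefaction_g, "auto"))
    rarefaction_g <- min(copy_counts[copy_counts > 0])
  ar <- matrix(0, length(grp_rows), n_loci(g),
               dimnames = list(names(grp_rows), g$loci))
  for (gi in seq_along(grp_rows))
    ar[gi, ] <- vapply(cnts[[gi]], rarefy_counts, 0, s = rarefaction_g)
  attr(ar, "rarefaction_g") <- rarefaction_g
  attr(ar, "group_means") <- rowMeans(ar)
  ar
}

#' Per-group diversity summary
#'
#' Group-wise counterpart of [locus_summary()]: per group, the sample size,
#' mean allele and effective allele numbers, private alleles (observed in
#' that group only), unique alleles (observed in a single individual of the
#' whole panel, attributed to its group), rarefied allelic richness,
#' heterozygosities, and multilocus Weir-Cockerham \eqn{F_{IS}} with a
#' permutation p-value.
#'
#' @inheritParams allelic_richness
#' @param n_perm Permutations for the per-group \eqn{F_{IS}} test
#'   (0 disables).
#' @param seed Optional RNG seed.
#' @return Data frame with one row per group.  Groups of fewer than 2
#'   individuals are dropped with a warning.  Loci entirely missing within
#'   a group are excluded from that group's averages.
#' @export
group_summary <- function(g, p, rarefaction_g = "auto", n_perm = 0L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- align_partition(g, p)
  sizes <- table(p)
  if (any(sizes < 2L)) {
    warning("dropping group(s) with < 2 individuals: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
    keep <- as.character(p) %in% names(sizes)[sizes >= 2L]
    g <- gm_subset(g, which(keep))
    p <- align_partition(g, p)
  }
  lcs <- lapply(seq_len(n_loci(g)), function(l) locus_codes(g, l))
  grp_rows <- split(seq_along(p), p)
  ## group x locus allele counts
  cnts <- lapply(grp_rows, function(rows)
    lapply(lcs, locus_allele_counts, rows = rows))
  ar <- allelic_richness(g, p, rarefaction_g)
  ## private alleles: per locus, alleles with presence in exactly one group
  n_groups <- length(grp_rows)
  priv <- setNames(numeric(n_groups), names(grp_rows))
  for (l in seq_len(n_loci(g))) {
    pres <- vapply(cnts, function(cl) cl[[l]] > 0,
                   logical(length(lcs[[l]]$codes)))
    pres <- matrix(pres, ncol = n_groups)
    one <- rowSums(pres) == 1L
    if (any(one))
      priv <- priv + colSums(pres[one, , drop = FALSE])
  }
  ## unique alleles: seen in exactly one individual of the whole matrix
  uniq <- setNames(numeric(n_groups), names(grp_rows))
  for (l in seq_len(n_loci(g))) {
    lc <- lcs[[l]]
    m <- length(lc$codes)
    carrier <- matrix(FALSE, n_ind(g), m)
    ok <- !is.na(lc$idx1)
    carrier[cbind(which(ok), lc$idx1[ok])] <- TRUE
    carrier[cbind(which(ok), lc$idx2[ok])] <- TRUE
    ncarry <- colSums(carrier)
    for (a in which(ncarry == 1L)) {
      ind <- which(carrier[, a])
      uniq[as.integer(p[ind])] <- uniq[as.integer(p[ind])] + 1
    }
  }
  rows <- lapply(seq_along(grp_rows), function(gi) {
    rws <- grp_rows[[gi]]
    per_locus <- lapply(seq_along(lcs), function(l) {
      cnt <- cnts[[gi]][[l]]
      tot <- sum(cnt)
      if (tot == 0L) return(NULL)
      n <- tot / 2
      pfr <- cnt / tot
      i1 <- lcs[[l]]$idx1[rws]; i2 <- lcs[[l]]$idx2[rws]
      het <- i1 != i2
      c(na = sum(cnt > 0), ne = 1 / sum(pfr^2),
        ho = mean(het[!is.na(het)]),
        he = if (n > 0.5) tot / (tot - 1) * (1 - sum(pfr^2)) else NA_real_)
    })
    per_locus <- do.call(rbind, Filter(Negate(is.null), per_locus))
    fp <- fis_permutation_p(gm_subset(g, rws), n_perm = n_perm)
    data.frame(group = names(grp_rows)[gi], n = length(rws),
               n_alleles = mean(per_locus[, "na"]),
               n_effective = mean(per_locus[, "ne"]),
               private = priv[gi], unique = uniq[gi],
               allelic_richness = attr(ar, "group_means")[gi],
               ho = mean(per_locus[, "ho"]), he = mean(per_locus[, "he"]),
               fis = fp["fis"],
               fis_p = if (n_perm > 0L) fp["p"] else NA_real_)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "rarefaction_g") <- attr(ar, "rarefaction_g")
  res
}

#' Null-allele frequency estimate from a heterozygote deficit
#'
#' Closed-form estimator (Brookfield's first estimator)
#' \eqn{r = (H_E - H_O)/(1 + H_E)}, floored at zero: the null-allele
#' frequency that would produce the observed heterozygote deficit when
#' null homozygotes are read as missing.
#'
#' @param h_o,h_e Observed and expected heterozygosity in \[0, 1\]
#'   (vectorized).
#' @return Estimated null-allele frequency (0 when `h_o >= h_e`).
#' @export
null_allele_rate <- function(h_o, h_e) {
  stopifnot(all(h_o >= 0 & h_o <= 1, na.rm = TRUE),
            all(h_e >= 0 & h_e <= 1, na.rm = TRUE))
  pmax(0, (h_e - h_o) / (1 + h_e))
}
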