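## Between-group differentiation: Weir-Cockerham theta, Nei distances,
## AMOVA, simple-matching dissimilarity, NJ trees, PCoA.

## Weir & Cockerham (1984) variance components a, b, c summed over alleles
## and loci for the groups in `p`.  Returns the theta estimate.
wc_theta <- function(g, p) {
  p <- align_partition(g, p)
  grp_rows <- split(seq_along(p), p)
  ta <- tb <- tc <- 0
  for (l in seq_len(n_loci(g))) {
    lc <- locus_codes(g, l)
    m <- length(lc$codes)
    if (m < 1L) next
    ni <- pm <- hm <- NULL
    for (rows in grp_rows) {
      i1 <- lc$idx1[rows]; i2 <- lc$idx2[rows]
      keep <- !is.na(i1)
      i1 <- i1[keep]; i2 <- i2[keep]
      n <- length(i1)
      if (n == 0L) next
      cnt <- tabulate(c(i1, i2), nbins = m)
      het <- i1 != i2
      h <- (tabulate(i1[het], nbins = m) + tabulate(i2[het], nbins = m)) / n
      ni <- c(ni, n)
      pm <- cbind(pm, cnt / (2 * n))
      hm <- cbind(hm, h)
    }
    r <- length(ni)
    if (r < 2L || m < 2L) next
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- as.vector(pm %*% ni) / (r * nbar)
    s2 <- as.vector(((pm - pbar)^2) %*% ni) / ((r - 1) * nbar)
    hbar <- as.vector(hm %*% ni) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    ta <- ta + sum(a); tb <- tb + sum(b); tc <- tc + sum(cc)
  }
  tot <- ta + tb + tc
  if (tot == 0) return(NA_real_)
  ta / tot
}

#' Pairwise and global F_ST (Weir-Cockerham theta)
#'
#' Multi-allelic Weir-Cockerham \eqn{\theta} with variance components
#' summed over alleles and loci.  Pairwise significance by permuting
#' individuals between the two groups (one-sided: differentiation larger
#' than or equal to the observed value).
#'
#' @param g A [genotype_matrix()].
#' @param p A [partition()] with at least 2 groups of at least 2
#'   individuals.
#' @param n_perm Permutations per pair for p-values (0 disables).
#' @param seed Optional RNG seed.
#' @return A list: `fst` (symmetric matrix, `NA` where every locus is
#'   monomorphic across the pair), `p_values` (matrix or `NULL`), and
#'   `global` (multi-group theta over all groups).
#' @export
pairwise_fst <- function(g, p, n_perm = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- align_partition(g, p)
  levs <- levels(p)
  if (length(levs) < 2L) stop("need at least 2 groups")
  k <- length(levs)
  fst <- matrix(0, k, k, dimnames = list(levs, levs))
  pv <- if (n_perm > 0L) matrix(NA_real_, k, k, dimnames = list(levs, levs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    rows <- which(as.character(p) %in% levs[c(i, j)])
    gp <- gm_subset(g, rows)
    pp <- align_partition(gp, p)
    th <- wc_theta(gp, pp)
    fst[i, j] <- fst[j, i] <- th
    if (n_perm > 0L && !is.na(th)) {
      lab <- as.character(pp)
      ge <- 0L
      for (b in seq_len(n_perm)) {
        thp <- wc_theta(gp, partition(sample(lab), ids = gp$ids))
        if (!is.na(thp) && thp >= th) ge <- ge + 1L
      }
      pv[i, j] <- pv[j, i] <- (ge + 1) / (n_perm + 1)
    }
  }
  attr(fst, "kind") <- "fst"
  list(fst = fst, p_values = pv, global = wc_theta(g, p))
}

## Per-group allele frequency list: per locus, matrix alleles x groups.
group_frequencies <- function(g, p) {
  p <- align_partition(g, p)
  grp_rows <- split(seq_along(p), p)
  lapply(seq_len(n_loci(g)), function(l) {
    lc <- locus_codes(g, l)
    fr <- vapply(grp_rows, function(rows) {
      cnt <- locus_allele_counts(lc, rows)
      tot <- sum(cnt)
      list(p = if (tot > 0) cnt / tot else rep(0, length(cnt)), copies = tot)
    }, vector("list", 2L))
    list(codes = lc$codes,
         p = do.call(cbind, fr["p", ]),
         copies = unlist(fr["copies", ]))
  })
}

#' Nei genetic distance between groups
#'
#' Nei's standard genetic distance \eqn{D = -\ln(J_{xy}/\sqrt{J_x J_y})}
#' with the gene-identity terms \eqn{J} averaged over loci (1972 standard
#' form), or the 1978 sample-size-unbiased variant where
#' \eqn{J_x = (2n_x \sum x_i^2 - 1)/(2n_x - 1)}.
#'
#' @inheritParams pairwise_fst
#' @param variant `"standard_1972"` (default) or `"unbiased_1978"`.
#' @return Symmetric distance matrix; `Inf` (with a warning) for pairs
#'   sharing no allele at any locus.
#' @export
nei_distance <- function(g, p, variant = c("standard_1972", "unbiased_1978")) {
  variant <- match.arg(variant)
  p <- align_partition(g, p)
  gf <- group_frequencies(g, p)
  levs <- levels(p)
  k <- length(levs)
  D <- matrix(0, k, k, dimnames = list(levs, levs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    jx <- jy <- jxy <- numeric(length(gf))
    for (l in seq_along(gf)) {
      x <- gf[[l]]$p[, i]; y <- gf[[l]]$p[, j]
      cx <- gf[[l]]$copies[i]; cy <- gf[[l]]$copies[j]
      jx[l] <- sum(x^2); jy[l] <- sum(y^2); jxy[l] <- sum(x * y)
      if (variant == "unbiased_1978") {
        if (cx > 1) jx[l] <- (cx * jx[l] - 1) / (cx - 1)
        if (cy > 1) jy[l] <- (cy * jy[l] - 1) / (cy - 1)
      }
    }
    I <- mean(jxy) / sqrt(mean(jx) * mean(jy))
    if (I <= 0) {
      warning("no shared alleles between ", levs[i], " and ", levs[j],
              ": distance is Inf")
      D[i, j] <- D[j, i] <- Inf
    } else D[i, j] <- D[j, i] <- -log(min(I, 1))
  }
  attr(D, "kind") <- "nei"
  attr(D, "variant") <- variant
  D
}

## Squared Euclidean distance between gene copies on one-hot allele
## vectors, summed over loci scored in both copies' individuals.  Copies
## 2i-1 and 2i belong to individual i.
gene_copy_sqdist <- function(g) {
  n <- n_ind(g)
  nc <- 2L * n
  D2 <- matrix(0, nc, nc)
  for (l in seq_len(n_loci(g))) {
    lc <- locus_codes(g, l)
    ok <- which(!is.na(lc$idx1))
    if (length(ok) < 2L) next
    idx <- as.vector(rbind(lc$idx1[ok], lc$idx2[ok]))  # copy order
    rows <- as.vector(rbind(2L * ok - 1L, 2L * ok))
    D2[rows, rows] <- D2[rows, rows] + 2 * outer(idx, idx, "!=")
  }
  D2
}

amova_from_sqdist <- function(D2, lab) {
  n <- length(lab)
  groups <- split(seq_len(n), lab)
  groups <- groups[lengths(groups) > 0L]
  r <- length(groups)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- sum(vapply(groups, function(rows)
    sum(D2[rows, rows][upper.tri(D2[rows, rows, drop = FALSE])]) / length(rows),
    0))
  ss_among <- ss_total - ss_within
  df_a <- r - 1L; df_w <- n - r
  ms_a <- ss_among / df_a; ms_w <- ss_within / df_w
  sizes <- lengths(groups)
  n0 <- (n - sum(sizes^2) / n) / (r - 1L)
  sig_w <- ms_w
  sig_a <- max(0, (ms_a - ms_w) / n0)
  phi <- if (sig_a + sig_w > 0) sig_a / (sig_a + sig_w) else NA_real_
  list(ss = c(among = ss_among, within = ss_within, total = ss_total),
       df = c(among = df_a, within = df_w, total = n - 1L),
       sigma = c(among = sig_a, within = sig_w),
       phi = phi)
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Distance-based AMOVA partitioning molecular variance among and within
#' groups, with gene copies as the units: squared Euclidean distances
#' between allele copies on one-hot allele vectors, summed over loci
#' (degrees of freedom are therefore on the `2N - 1` scale, the convention
#' of the standard codominant-marker AMOVA implementations, and
#' \eqn{\Phi_{ST}} is on the same scale as \eqn{F_{ST}}).  Negative
#' among-group components are truncated to zero before percentages.
#' \eqn{\Phi_{ST}} significance by permuting whole individuals among
#' groups.
#'
#' @inheritParams pairwise_fst
#' @return A list: `table` (data frame with df, sum of squares, variance
#'   component, percentage per stratum), `phi_st`, and `p_value` (`NA` when
#'   `n_perm = 0`).
#' @export
amova <- function(g, p, n_perm = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- align_partition(g, p)
  if (nlevels(p) < 2L) stop("AMOVA needs at least 2 groups")
  D2 <- gene_copy_sqdist(g)
  ind_lab <- as.character(p)
  expand <- function(lab) rep(lab, each = 2L)
  obs <- amova_from_sqdist(D2, expand(ind_lab))
  pv <- NA_real_
  if (n_perm > 0L) {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      perm <- amova_from_sqdist(D2, expand(sample(ind_lab)))
      if (!is.na(perm$phi) && perm$phi >= obs$phi) ge <- ge + 1L
    }
    pv <- (ge + 1) / (n_perm + 1)
  }
  tot_sig <- sum(obs$sigma)
  tab <- data.frame(
    stratum = c("among groups", "within groups", "total"),
    df = obs$df,
    sum_sq = obs$ss,
    variance = c(obs$sigma, tot_sig),
    percent = 100 * c(obs$sigma, tot_sig) / tot_sig)
  rownames(tab) <- NULL
  list(table = tab, phi_st = obs$phi, p_value = pv)
}

#' Simple-matching dissimilarity between individuals
#'
#' \eqn{d(i,j) = 1 - \frac{1}{L_{ij}} \sum_l m_l/2} where \eqn{m_l} is the
#' number of alleles shared (multiset intersection) between the two diploid
#' calls at locus \eqn{l} and \eqn{L_{ij}} counts loci non-missing in both
#' individuals.
#'
#' @param g A [genotype_matrix()] with at least 2 individuals.
#' @return Symmetric matrix in \[0, 1\]; `NA` (with a warning) for pairs
#'   sharing no scored locus.
#' @export
simple_matching_dissimilarity <- function(g) {
  n <- n_ind(g)
  if (n < 2L) stop("need at least 2 individuals")
  S <- matrix(0, n, n)   # summed shared fraction
  C <- matrix(0L, n, n)  # loci counted
  for (l in seq_len(n_loci(g))) {
    lc <- locus_codes(g, l)
    m <- length(lc$codes)
    ok <- which(!is.na(lc$idx1))
    if (length(ok) < 2L) next
    X <- matrix(0, length(ok), m)
    X[cbind(seq_along(ok), lc$idx1[ok])] <- X[cbind(seq_along(ok), lc$idx1[ok])] + 1
    X[cbind(seq_along(ok), lc$idx2[ok])] <- X[cbind(seq_along(ok), lc$idx2[ok])] + 1
    ## multiset intersection size = (4 - L1 distance)/2
    l1 <- as.matrix(dist(X, method = "manhattan"))
    S[ok, ok] <- S[ok, ok] + (4 - l1) / 4   # m/2 with m = (4 - l1)/2
    C[ok, ok] <- C[ok, ok] + 1L
  }
  d <- 1 - S / C
  diag(d) <- 0
  if (any(C[upper.tri(C)] == 0L))
    warning("individual pair(s) share no scored locus: NA dissimilarity")
  dimnames(d) <- list(g$ids, g$ids)
  attr(d, "kind") <- "simple_matching"
  d
}

#' Neighbor-joining tree with optional bootstrap support
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on any of the package's
#' distance matrices, with bipartition support from `B` bootstrap
#' resamples of loci: `boot_fun(loci_idx)` must return the distance matrix
#' recomputed on the resampled loci.
#'
#' @param d Symmetric finite distance matrix with labels.
#' @param boot_fun Optional function of a locus-index vector returning a
#'   distance matrix on the same labels.
#' @param n_loci_boot Number of loci to resample from (required with
#'   `boot_fun`).
#' @param B Bootstrap replicates.
#' @param seed Optional RNG seed.
#' @return A list: `tree` (an \pkg{ape} `phylo`), `newick`, and `support`
#'   (per internal node, percentage of replicates containing the clade;
#'   `NULL` without bootstrap).
#' @export
nj_tree <- function(d, boot_fun = NULL, n_loci_boot = NULL, B = 100L,
                    seed = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 leaves")
  bad <- which(!is.finite(d) & row(d) != col(d), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite distance between ", rownames(d)[bad[1L, 1L]], " and ",
         colnames(d)[bad[1L, 2L]])
  tree <- ape::nj(as.dist(d))
  support <- NULL
  if (!is.null(boot_fun)) {
    if (is.null(n_loci_boot)) stop("n_loci_boot required for bootstrap")
    if (!is.null(seed)) set.seed(seed)
    reps <- vector("list", B)
    for (b in seq_len(B)) {
      idx <- sample.int(n_loci_boot, n_loci_boot, replace = TRUE)
      reps[[b]] <- ape::nj(as.dist(as.matrix(boot_fun(idx))))
    }
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    support <- 100 * counts / B
  }
  list(tree = tree, newick = ape::write.tree(tree), support = support)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers \eqn{-d^2/2} and eigendecomposes; axes are ordered by
#' eigenvalue.  Negative eigenvalues (non-Euclidean input) are retained
#' and reported, not corrected.
#'
#' @param d Symmetric dissimilarity matrix, zero diagonal, no `NA`.
#' @param n_axes Number of coordinate axes to return.
#' @return A list: `coordinates` (n x n_axes, for axes with positive
#'   eigenvalues; zero columns beyond), `eigenvalues` (all), and
#'   `variance_explained` (share of the positive eigenvalue total).
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("NA entries in distance matrix")
  n <- nrow(d)
  B <- -0.5 * d^2
  B <- sweep(B, 1L, rowMeans(B))
  B <- sweep(B, 2L, colMeans(B))
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  n_axes <- min(n_axes, n)
  co <- matrix(0, n, n_axes)
  for (a in seq_len(n_axes))
    if (ev[a] > 1e-12) co[, a] <- e$vectors[, a] * sqrt(ev[a])
  rownames(co) <- rownames(d)
  list(coordinates = co, eigenvalues = ev,
       variance_explained = pmax(ev, 0) / sum(pmax(ev, 0)))
}
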