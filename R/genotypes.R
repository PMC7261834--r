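#' Diploid codominant genotype matrix
#'
#' The central container of the package: diploid allele calls for a set of
#' individuals at a set of codominant loci (microsatellites/SSRs).  Alleles
#' are coded as positive integers (typically fragment sizes or repeat
#' counts); a missing call is `NA` at both allele slots.  Within a call the
#' two alleles are stored in sorted order, so allele order carries no
#' information.
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two allele
#'   codes of each call.  `NA` in both marks a missing call.  Row names are
#'   individual identifiers, column names are locus names; defaults are
#'   generated when absent.
#' @param ids,loci Optional character vectors overriding the dimnames.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `ids`, `loci`, `a1`, `a2` (allele matrices with `a1 <= a2` elementwise).
#' @examples
#' g <- genotype_matrix(matrix(c(145L, 149L), 1, 2),
#'                      matrix(c(149L, 149L), 1, 2))
#' n_ind(g); n_loci(g)
#' @export
genotype_matrix <- function(a1, a2, ids = NULL, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2)))
    stop("allele matrices must have identical dimensions")
  n <- nrow(a1); L <- ncol(a1)
  if (n < 1L || L < 1L) stop("need at least 1 individual and 1 locus")
  if (is.null(ids))  ids  <- rownames(a1)
  if (is.null(ids))  ids  <- paste0("ind", seq_len(n))
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- paste0("locus", seq_len(L))
  ids <- as.character(ids); loci <- as.character(loci)
  if (anyDuplicated(ids))  stop("duplicate individual identifier: ",
                                ids[duplicated(ids)][1L])
  if (anyDuplicated(loci)) stop("duplicate locus name: ",
                                loci[duplicated(loci)][1L])
  half <- is.na(a1) != is.na(a2)
  if (any(half))
    stop("haploid call (one allele missing) at individual ",
         ids[row(a1)[half][1L]])
  ok <- !is.na(a1)
  if (any(a1[ok] <= 0L) || any(a2[ok] <= 0L))
    stop("allele codes must be positive integers")
  swap <- ok & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param g A `genotype_matrix`.
#' @export
n_ind <- function(g) length(g$ids)

#' @rdname genotype_matrix
#' @export
n_loci <- function(g) length(g$loci)

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing calls)\n",
              n_ind(x), n_loci(x), 100 * miss))
  invisible(x)
}

#' @export
`==.genotype_matrix` <- function(e1, e2) {
  identical(e1$ids, e2$ids) && identical(e1$loci, e2$loci) &&
    identical(e1$a1, e2$a1) && identical(e1$a2, e2$a2)
}

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param g A `genotype_matrix`.
#' @param individuals Identifiers or indices of individuals to keep
#'   (default all).
#' @param loci Locus names or indices to keep (default all).
#' @return A `genotype_matrix` restricted to the selection, in the given
#'   order.
#' @export
gm_subset <- function(g, individuals = NULL, loci = NULL) {
  ri <- if (is.null(individuals)) seq_along(g$ids) else {
    if (is.character(individuals)) match(individuals, g$ids) else individuals
  }
  ci <- if (is.null(loci)) seq_along(g$loci) else {
    if (is.character(loci)) match(loci, g$loci) else loci
  }
  if (anyNA(ri)) stop("unknown individual identifier")
  if (anyNA(ci)) stop("unknown locus name")
  ## selections with repeats (e.g. bootstrap resampling of loci) get
  ## uniquified names
  genotype_matrix(g$a1[ri, ci, drop = FALSE], g$a2[ri, ci, drop = FALSE],
                  ids = make.unique(g$ids[ri]),
                  loci = make.unique(g$loci[ci]))
}

#' Partition of individuals into groups
#'
#' A partition assigns each individual to one group (a geographic group, an
#' inferred genetic cluster, a core-collection membership, ...).  Group
#' labels keep their first-appearance order unless `levels` is given.
#'
#' @param labels Character (or factor) vector of group labels, named by
#'   individual identifier (or pass `ids`).
#' @param ids Individual identifiers, if `labels` is unnamed.
#' @param levels Optional explicit label order.
#' @return A named factor of class `c("partition", "factor")`.
#' @export
partition <- function(labels, ids = names(labels), levels = NULL) {
  if (is.null(ids)) stop("partition needs individual identifiers")
  labels <- as.character(labels)
  if (length(labels) != length(ids))
    stop("labels and ids differ in length")
  if (anyDuplicated(ids)) stop("duplicate individual in partition")
  if (anyNA(labels)) stop("NA group label")
  if (is.null(levels)) levels <- unique(labels)
  f <- factor(labels, levels = levels)
  names(f) <- as.character(ids)
  class(f) <- c("partition", "factor")
  f
}

#' Match a partition against a genotype matrix
#'
#' Returns the partition restricted and reordered to the individuals of
#' `g`, dropping empty groups; errors if any individual of `g` is unlabeled.
#'
#' @param g A `genotype_matrix`.
#' @param p A [partition()].
#' @return A `partition` aligned with `g$ids`.
#' @export
align_partition <- function(g, p) {
  i <- match(g$ids, names(p))
  if (anyNA(i))
    stop("individuals missing from partition: ",
         paste(head(g$ids[is.na(i)], 3L), collapse = ", "))
  partition(as.character(p)[i], ids = g$ids,
            levels = intersect(levels(p), as.character(p)[i]))
}

## Per-locus allele bookkeeping used across modules ------------------------

## codes: sorted unique allele codes; idx1/idx2: n-vectors of 1-based indices
## into codes (NA for missing).
locus_codes <- function(g, l) {
  a1 <- g$a1[, l]; a2 <- g$a2[, l]
  codes <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
  list(codes = codes,
       idx1 = match(a1, codes), idx2 = match(a2, codes))
}

## Allele count vector for one locus over a row subset (default all rows).
locus_allele_counts <- function(lc, rows = NULL) {
  i1 <- lc$idx1; i2 <- lc$idx2
  if (!is.null(rows)) { i1 <- i1[rows]; i2 <- i2[rows] }
  tabulate(c(i1[!is.na(i1)], i2[!is.na(i2)]), nbins = length(lc$codes))
}
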