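## Core-collection selection: allele-coverage maximization (advanced M
## strategy) with redundancy pruning.

## Per-individual set of (locus, allele) classes, as integer ids.
allele_class_sets <- function(g) {
  offs <- 0L
  sets <- vector("list", n_ind(g))
  for (i in seq_along(sets)) sets[[i]] <- integer(0)
  for (l in seq_len(n_loci(g))) {
    lc <- locus_codes(g, l)
    m <- length(lc$codes)
    ok <- which(!is.na(lc$idx1))
    for (i in ok)
      sets[[i]] <- c(sets[[i]],
                     offs + unique(c(lc$idx1[i], lc$idx2[i])))
    offs <- offs + m
  }
  list(sets = sets, n_classes = offs)
}

#' Build a core collection by allele-coverage maximization
#'
#' Advanced maximization (M) strategy: iteratively add the individual
#' covering the largest number of not-yet-covered allele classes
#' (locus-allele pairs), until every allele observed in the full matrix is
#' covered; ties are broken by higher within-individual heterozygosity,
#' then by lowest input index.  A post-pass removes any selected
#' individual whose alleles are entirely covered by the rest (redundancy
#' pruning).  Deterministic.
#'
#' @param g A [genotype_matrix()].
#' @return An object of class `core_collection`: `selected` (identifiers,
#'   selection order after pruning), `allele_coverage` (1 under the
#'   default stopping rule), `n_classes`.
#' @export
build_core <- function(g) {
  acs <- allele_class_sets(g)
  sets <- acs$sets
  covered <- logical(acs$n_classes)
  het <- vapply(seq_len(n_ind(g)), function(i) {
    d <- g$a1[i, ] != g$a2[i, ]
    sum(d, na.rm = TRUE)
  }, 0L)
  selected <- integer(0)
  gain <- vapply(sets, length, 0L)
  while (!all(covered)) {
    gain <- vapply(sets, function(s) sum(!covered[s]), 0L)
    gain[selected] <- -1L
    best <- max(gain)
    if (best <= 0L) break   # remaining alleles unreachable (cannot happen)
    cand <- which(gain == best)
    cand <- cand[order(-het[cand], cand)]
    pick <- cand[1L]
    selected <- c(selected, pick)
    covered[sets[[pick]]] <- TRUE
  }
  ## redundancy pruning: drop any member fully covered by the others
  repeat {
    dropped <- FALSE
    for (j in rev(seq_along(selected))) {
      others <- selected[-j]
      cov <- logical(acs$n_classes)
      cov[unlist(sets[others])] <- TRUE
      if (all(cov[sets[[selected[j]]]])) {
        selected <- others
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  structure(list(selected = g$ids[selected],
                 allele_coverage = mean(covered),
                 n_classes = acs$n_classes),
            class = "core_collection")
}

#' @export
print.core_collection <- function(x, ...) {
  cat(sprintf("core_collection: %d accessions, %.1f%% allele coverage\n",
              length(x$selected), 100 * x$allele_coverage))
  invisible(x)
}

#' Coverage and composition report for a core collection
#'
#' @param g The full [genotype_matrix()].
#' @param core A `core_collection` from [build_core()], or a character
#'   vector of identifiers.
#' @param partitions Optional named list of [partition()]s; composition is
#'   tallied against each.
#' @return A list: `coverage` (fraction of the panel's distinct alleles
#'   present in the core), `size`, `size_fraction_pct`
#'   (100 |core| / |panel|), and `composition` (list of per-partition
#'   count tables).
#' @export
coverage_report <- function(g, core, partitions = NULL) {
  ids <- if (inherits(core, "core_collection")) core$selected else core
  idx <- match(ids, g$ids)
  if (anyNA(idx)) stop("unknown identifier in core: ", ids[is.na(idx)][1L])
  acs <- allele_class_sets(g)
  cov <- logical(acs$n_classes)
  cov[unlist(acs$sets[idx])] <- TRUE
  comp <- NULL
  if (!is.null(partitions))
    comp <- lapply(partitions, function(p) table(as.character(p[ids])))
  list(coverage = mean(cov), size = length(ids),
       size_fraction_pct = 100 * length(ids) / n_ind(g),
       composition = comp)
}
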