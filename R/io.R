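#' Read a genotype table (CSV, GenePop, or STRUCTURE dialect)
#'
#' Parses the three plain-text formats in common use for codominant marker
#' panels into a [genotype_matrix()], together with a [partition()] when the
#' dialect encodes one (GenePop "Pop" blocks; the STRUCTURE group column;
#' the optional `group` column of the CSV dialect).
#'
#' Dialects:
#' \describe{
#'   \item{csv}{Header `id,group,locus1,...` (the `group` column optional);
#'     calls written `a/b`; missing as empty, `NA`, or `0`.}
#'   \item{genepop}{Title line, one locus name per line (or comma-separated
#'     on one line), then `Pop` blocks of `id , 001002 003004` rows with 2-
#'     or 3-digit fixed-width alleles; `00`/`000` marks a missing allele.}
#'   \item{structure}{One row per individual, two columns per locus:
#'     `id group a1 a2 a1 a2 ...`; missing allele coded `-9`.}
#' }
#'
#' @param source Path to a file, or a character vector of lines.
#' @param dialect One of `"csv"`, `"genepop"`, `"structure"`.
#' @return A list with elements `genotypes` (a `genotype_matrix`) and
#'   `partition` (a `partition`, or `NULL` when the dialect carries none).
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(source, dialect = c("csv", "genepop", "structure")) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    readLines(source, warn = FALSE) else unlist(strsplit(source, "\n"))
  lines <- sub("[ \t\r]+$", "", lines)
  switch(dialect,
         csv = parse_csv_genotypes(lines),
         genepop = parse_genepop(lines),
         structure = parse_structure(lines))
}

parse_csv_genotypes <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("csv parse error: need header and >=1 row")
  hdr <- strsplit(lines[1L], ",")[[1L]]
  has_group <- length(hdr) >= 2L && tolower(trimws(hdr[2L])) == "group"
  first_locus <- if (has_group) 3L else 2L
  loci <- trimws(hdr[first_locus:length(hdr)])
  n <- length(lines) - 1L
  ids <- character(n); grp <- character(n)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (i in seq_len(n)) {
    f <- trimws(strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]])
    ## trailing empty fields are dropped by strsplit: pad when the comma
    ## count says they were there
    n_commas <- nchar(lines[i + 1L]) -
      nchar(gsub(",", "", lines[i + 1L], fixed = TRUE))
    if (length(f) < length(hdr) && n_commas == length(hdr) - 1L)
      f <- c(f, rep("", length(hdr) - length(f)))
    if (length(f) != length(hdr))
      stop("csv parse error at line ", i + 1L, ": expected ",
           length(hdr), " fields, found ", length(f))
    ids[i] <- f[1L]
    if (has_group) grp[i] <- f[2L]
    for (j in seq_along(loci)) {
      cell <- f[first_locus + j - 1L]
      if (cell %in% c("", "NA", "0", "0/0")) next
      ab <- strsplit(cell, "/", fixed = TRUE)[[1L]]
      if (length(ab) == 1L) ab <- c(ab, ab)
      if (length(ab) != 2L)
        stop("csv parse error at line ", i + 1L, ": call '", cell,
             "' is not diploid")
      a1[i, j] <- as.integer(ab[1L]); a2[i, j] <- as.integer(ab[2L])
    }
  }
  g <- genotype_matrix(a1, a2, ids = ids, loci = loci)
  p <- if (has_group) partition(grp, ids = ids) else NULL
  list(genotypes = g, partition = p)
}

parse_genepop <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("genepop parse error: file too short")
  body <- lines[-1L]                      # drop title
  pop_at <- which(tolower(trimws(body)) == "pop")
  if (!length(pop_at)) stop("genepop parse error: no 'Pop' line")
  loc_lines <- body[seq_len(pop_at[1L] - 1L)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("genepop parse error: no locus names")
  ids <- character(0); grp <- character(0)
  rows1 <- list(); rows2 <- list()
  pop_i <- 0L
  for (k in seq_along(body)) {
    ln <- trimws(body[k])
    if (k < pop_at[1L]) next
    if (tolower(ln) == "pop") { pop_i <- pop_i + 1L; next }
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) != 2L)
      stop("genepop parse error at line ", k + 1L, ": expected 'id , alleles'")
    id <- trimws(parts[1L])
    toks <- strsplit(trimws(parts[2L]), "[ \t]+")[[1L]]
    if (length(toks) != length(loci))
      stop("genepop parse error at line ", k + 1L, ": ", length(toks),
           " genotypes for ", length(loci), " loci")
    w <- nchar(toks[1L])
    if (!all(nchar(toks) == w) || !w %in% c(4L, 6L))
      stop("genepop parse error at line ", k + 1L,
           ": alleles must be fixed-width 2- or 3-digit")
    h <- w %/% 2L
    x1 <- as.integer(substr(toks, 1L, h))
    x2 <- as.integer(substr(toks, h + 1L, w))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    miss_half <- is.na(x1) != is.na(x2)
    if (any(miss_half))
      stop("genepop parse error at line ", k + 1L,
           ": half-missing call at locus ", loci[miss_half][1L])
    ids <- c(ids, id); grp <- c(grp, paste0("pop", pop_i))
    rows1[[length(rows1) + 1L]] <- x1
    rows2[[length(rows2) + 1L]] <- x2
  }
  if (!length(ids)) stop("genepop parse error: no individuals")
  g <- genotype_matrix(do.call(rbind, rows1), do.call(rbind, rows2),
                       ids = ids, loci = loci)
  list(genotypes = g, partition = partition(grp, ids = ids))
}

parse_structure <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(rows)
  if (length(unique(nf)) != 1L)
    stop("structure parse error: ragged rows (line ",
         which(nf != nf[1L])[1L], ")")
  if ((nf[1L] - 2L) %% 2L != 0L || nf[1L] < 4L)
    stop("structure parse error: need id, group, and 2 columns per locus")
  L <- (nf[1L] - 2L) %/% 2L
  ids <- vapply(rows, `[`, "", 1L)
  grp <- vapply(rows, `[`, "", 2L)
  num <- t(vapply(rows, function(r) as.integer(r[-(1:2)]), integer(2L * L)))
  a1 <- num[, 2L * seq_len(L) - 1L, drop = FALSE]
  a2 <- num[, 2L * seq_len(L), drop = FALSE]
  a1[a1 == -9L] <- NA_integer_; a2[a2 == -9L] <- NA_integer_
  if (any(is.na(a1) != is.na(a2)))
    stop("structure parse error: half-missing call")
  g <- genotype_matrix(a1, a2, ids = ids,
                       loci = paste0("locus", seq_len(L)))
  list(genotypes = g, partition = partition(grp, ids = ids))
}

#' Write a genotype table (CSV, GenePop, or STRUCTURE dialect)
#'
#' Deterministic inverse of [read_genotype_table()]: the emitted text parses
#' back to an equal matrix (and partition), with input ordering preserved.
#'
#' @param g A [genotype_matrix()].
#' @param p A [partition()], required for the GenePop dialect (pass an
#'   explicit one-group partition for a single "Pop" block) and optional
#'   for the others.
#' @param dialect One of `"csv"`, `"genepop"`, `"structure"`.
#' @param file Optional path; when `NULL` the lines are returned invisibly.
#' @param title Title line for the GenePop dialect.
#' @return Character vector of output lines (invisibly when `file` given).
#' @export
write_genotype_table <- function(g, p = NULL,
                                 dialect = c("csv", "genepop", "structure"),
                                 file = NULL, title = "ssrdem export") {
  dialect <- match.arg(dialect)
  if (!is.null(p)) p <- align_partition(g, p)
  out <- switch(dialect,
                csv = format_csv_genotypes(g, p),
                genepop = format_genepop(g, p, title),
                structure = format_structure(g, p))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

format_csv_genotypes <- function(g, p) {
  cell <- ifelse(is.na(g$a1), "", paste0(g$a1, "/", g$a2))
  dim(cell) <- dim(g$a1)
  if (is.null(p)) {
    hdr <- paste(c("id", g$loci), collapse = ",")
    body <- apply(cbind(g$ids, cell), 1L, paste, collapse = ",")
  } else {
    hdr <- paste(c("id", "group", g$loci), collapse = ",")
    body <- apply(cbind(g$ids, as.character(p), cell), 1L, paste, collapse = ",")
  }
  c(hdr, body)
}

format_genepop <- function(g, p, title) {
  if (is.null(p))
    stop("genepop output requires a partition; pass a one-group partition ",
         "explicitly for a single Pop block")
  mx <- max(g$a2, na.rm = TRUE)
  if (mx > 999L)
    stop("genepop output requires allele codes <= 999; recode first ",
         "(see recode_alleles)")
  w <- 3L
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = w, flag = "0")
  }
  cell <- matrix(paste0(fmt(g$a1), fmt(g$a2)), nrow = n_ind(g))
  out <- c(title, g$loci)
  for (lev in levels(p)) {
    out <- c(out, "Pop")
    rows <- which(as.character(p) == lev)
    out <- c(out, paste0(g$ids[rows], " , ",
                         apply(cell[rows, , drop = FALSE], 1L, paste,
                               collapse = " ")))
  }
  out
}

format_structure <- function(g, p) {
  grp <- if (is.null(p)) rep("1", n_ind(g)) else as.character(p)
  a1 <- g$a1; a2 <- g$a2
  a1[is.na(a1)] <- -9L; a2[is.na(a2)] <- -9L
  L <- n_loci(g)
  inter <- matrix(NA_integer_, n_ind(g), 2L * L)
  inter[, 2L * seq_len(L) - 1L] <- a1
  inter[, 2L * seq_len(L)] <- a2
  paste(g$ids, grp, apply(inter, 1L, paste, collapse = " "))
}

#' Remap allele codes into a compact positive range
#'
#' Utility for exporting matrices whose codes exceed a dialect's width
#' limit: alleles at each locus are renumbered 1..m in increasing code
#' order, and the mapping is returned.
#'
#' @param g A [genotype_matrix()].
#' @return A list: `genotypes` (recoded matrix) and `map` (per-locus data
#'   frame of old and new codes).
#' @export
recode_alleles <- function(g) {
  a1 <- g$a1; a2 <- g$a2
  maps <- vector("list", n_loci(g))
  for (l in seq_len(n_loci(g))) {
    lc <- locus_codes(g, l)
    a1[, l] <- lc$idx1
    a2[, l] <- lc$idx2
    maps[[l]] <- data.frame(locus = g$loci[l], old = lc$codes,
                            new = seq_along(lc$codes))
  }
  list(genotypes = genotype_matrix(a1, a2, ids = g$ids, loci = g$loci),
       map = do.call(rbind, maps))
}
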