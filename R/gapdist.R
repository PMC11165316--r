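# Gap-only pairwise distances over a multiple sequence alignment.
#
# The distance between two aligned rows counts only the columns where
# exactly one of the two is gapped, divided by the number of columns where
# at least one of the two has a residue (the effective pairwise length).
# Amino-acid substitutions contribute nothing: two sequences that align end
# to end with no gaps have distance zero no matter how many residues differ,
# while a single 5-residue gap over an effective length of 100 gives 0.05.
# Columns gapped in BOTH rows belong to some third sequence's insertion and
# are excluded from numerator and denominator alike, so two rows with an
# identical gap structure are at distance zero.  Terminal gaps count exactly
# like internal gaps: clade members are thereby forced to have very similar
# lengths, not just similar internal exon structure.

#' Gap distance between two aligned rows
#'
#' @param row_a,row_b aligned strings of equal length (`-` = gap).
#' @return `list(distance, pair_len, gap_cols)` where `gap_cols` is the
#'   number of columns gapped in exactly one row, `pair_len` the number of
#'   columns with a residue in at least one row, and
#'   `distance = gap_cols / pair_len`.
#' @export
#' @examples
#' gap_distance_pair("AC-EF", "ACDEF")  # distance 1/5
gap_distance_pair <- function(row_a, row_b) {
  if (nchar(row_a) != nchar(row_b))
    gc_stop("aligned rows differ in length")
  ga <- strsplit(row_a, "", fixed = TRUE)[[1]] == "-"
  gb <- strsplit(row_b, "", fixed = TRUE)[[1]] == "-"
  pair_len <- sum(!(ga & gb))
  if (pair_len == 0) gc_stop("degenerate pair: no column has a residue")
  gap_cols <- sum(xor(ga, gb))
  list(distance = gap_cols / pair_len,
       pair_len = pair_len,
       gap_cols = gap_cols)
}

#' Gap-distance matrix for a multiple alignment
#'
#' Computes all pairwise gap-only distances of an `msa` at once.  With `G`
#' the rows-by-columns gap indicator, the number of shared-gap columns for a
#' pair is `G %*% t(G)`, from which the one-sided gap counts and effective
#' pairwise lengths follow without any per-pair loop.
#'
#' @param x an `msa` object, or a named character vector of aligned rows.
#' @return object of class `gap_dist`: list with `labels` (accessions), `d`
#'   (symmetric matrix of distances in `[0, 1]`, zero diagonal) and
#'   `pair_len` (matrix of effective pairwise lengths).
#' @export
gap_distance_matrix <- function(x) {
  rows <- if (inherits(x, "msa")) x$rows else x
  if (length(rows) < 2) gc_stop("need at least 2 rows for a distance matrix")
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    gc_stop("rows must have unique names")
  G <- gap_matrix(rows) * 1L          # n x L, 1 = gap
  L <- ncol(G)
  shared <- G %*% t(G)                # columns gapped in both
  g <- rowSums(G)
  gap_cols <- outer(g, g, "+") - 2 * shared
  pair_len <- L - shared
  if (any(pair_len[upper.tri(pair_len)] == 0))
    gc_stop("degenerate pair: no column has a residue")
  d <- gap_cols / pair_len
  diag(d) <- 0
  dimnames(d) <- list(names(rows), names(rows))
  dimnames(pair_len) <- dimnames(d)
  structure(list(labels = names(rows), d = d, pair_len = pair_len),
            class = "gap_dist")
}

#' @export
print.gap_dist <- function(x, ...) {
  cat("gap-distance matrix over", length(x$labels), "sequences; max",
      format(max(x$d), digits = 4), "\n")
  invisible(x)
}

#' Dump a gap-distance matrix as TSV (labels header + lower triangle)
#' @param gdm a `gap_dist` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gap_dist_tsv <- function(gdm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(gdm$labels, collapse = "\t"), con)
  for (i in seq_along(gdm$labels)) {
    vals <- sprintf("%.8g", gdm$d[i, seq_len(i)])
    writeLines(paste(c(gdm$labels[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}
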