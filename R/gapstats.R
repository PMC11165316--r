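# Gap-statistics diagnostics for pairwise proteome comparisons.
#
# BTOP (BLAST trace-back operations) strings compactly encode an alignment:
# an integer is a run of identities, two residue letters are a mismatch
# (query then subject), `X-` is a residue aligned to a gap in the subject,
# `-X` a gap in the query.  Decoding them yields per-alignment identity and
# gap-event statistics (number of gaps, longest gap) from which per
# proteome-pair distributions are summarised.

#' Decode a BTOP alignment encoding
#'
#' @param btop BTOP string.
#' @return data.frame of events in alignment order with columns `type`
#'   (`match`, `mismatch`, `qgap` = gap in query, `sgap` = gap in subject),
#'   `length` (alignment columns spanned) and `chars` (the literal token
#'   text, empty for matches).  Adjacent same-side gap tokens are merged
#'   into one gap event.
#' @export
#' @examples
#' decode_btop("4-A-A2")   # identity 4, query gap of 2, identity 2
decode_btop <- function(btop) {
  chars <- strsplit(btop, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_digit <- chars %in% as.character(0:9)
  is_res <- chars %in% strsplit(BTOP_RES, "")[[1]]
  type <- character(0); len <- integer(0); txt <- character(0)
  pos <- 1L
  while (pos <= n) {
    if (is_digit[pos]) {
      end <- pos
      while (end < n && is_digit[end + 1L]) end <- end + 1L
      run <- as.integer(paste(chars[pos:end], collapse = ""))
      if (run > 0) {
        type <- c(type, "match"); len <- c(len, run); txt <- c(txt, "")
      }
      pos <- end + 1L
    } else {
      if (pos + 1L > n)
        gc_stop("truncated BTOP token at offset ", pos, " in '", btop, "'")
      c1 <- chars[pos]; c2 <- chars[pos + 1L]
      tok <- paste0(c1, c2)
      if (is_res[pos] && is_res[pos + 1L]) {
        type <- c(type, "mismatch")
      } else if (is_res[pos] && c2 == "-") {
        type <- c(type, "sgap")
      } else if (c1 == "-" && is_res[pos + 1L]) {
        type <- c(type, "qgap")
      } else {
        gc_stop("illegal BTOP character pair '", tok, "' at offset ", pos,
                " in '", btop, "'")
      }
      len <- c(len, 1L); txt <- c(txt, tok)
      pos <- pos + 2L
    }
  }
  ev <- data.frame(type = type, length = len, chars = txt,
                   stringsAsFactors = FALSE)
  merge_gap_events(ev)
}

# merge runs of adjacent same-side single-column gap tokens into one event
merge_gap_events <- function(ev) {
  if (nrow(ev) < 2) return(ev)
  grp <- cumsum(c(TRUE, ev$type[-1] != ev$type[-nrow(ev)] |
                    !(ev$type[-1] %in% c("qgap", "sgap"))))
  out <- do.call(rbind, lapply(split(ev, grp), function(g)
    data.frame(type = g$type[1], length = sum(g$length),
               chars = paste(g$chars, collapse = ""),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Re-encode a decoded event list as a BTOP string
#' @param events data.frame from [decode_btop()].
#' @return BTOP string (canonical form: merged gaps, no zero runs).
#' @export
encode_btop <- function(events) {
  paste(ifelse(events$type == "match", as.character(events$length),
               events$chars), collapse = "")
}

#' Summarise one best-hit alignment from its BTOP encoding
#'
#' @param hit one-row data.frame (or list) with at least `btop`; when
#'   `align_len` is present the BTOP expansion must span exactly that many
#'   columns, and when `percent_identity` is present it is cross-checked
#'   against the BTOP-derived identity (warning if they differ by more than
#'   0.1).
#' @return object of class `aln_summary`: list with `query_acc`,
#'   `subject_acc`, `align_len`, `n_identical`, `percent_identity`
#'   (BTOP-derived), `gap_events` (data.frame side/length), `max_gap`, and
#'   `n_gaps_ge(t)`, the number of gap events of length at least `t`.
#' @export
summarize_alignment <- function(hit) {
  ev <- decode_btop(hit$btop)
  span <- sum(ev$length)
  if (!is.null(hit$align_len) && !is.na(hit$align_len) &&
      span != hit$align_len)
    gc_stop("BTOP expansion spans ", span, " columns but align_len is ",
            hit$align_len)
  n_ident <- sum(ev$length[ev$type == "match"])
  pid <- 100 * n_ident / span
  if (!is.null(hit$percent_identity) && !is.na(hit$percent_identity) &&
      abs(pid - hit$percent_identity) > 0.1)
    gc_warn("printed percent identity ", hit$percent_identity,
            " disagrees with BTOP-derived ", round(pid, 2))
  gaps <- ev[ev$type %in% c("qgap", "sgap"), , drop = FALSE]
  gap_events <- data.frame(
    side = ifelse(gaps$type == "qgap", "query", "subject"),
    length = gaps$length, stringsAsFactors = FALSE)
  structure(list(
    query_acc = if (is.null(hit$query_acc)) NA_character_ else hit$query_acc,
    subject_acc = if (is.null(hit$subject_acc)) NA_character_ else
      hit$subject_acc,
    align_len = span,
    n_identical = n_ident,
    percent_identity = pid,
    gap_events = gap_events,
    max_gap = if (nrow(gap_events)) max(gap_events$length) else 0L,
    n_gaps_ge = function(t) sum(gap_events$length >= t)
  ), class = "aln_summary")
}

#' Summarise a table of hits into one row per alignment
#'
#' @param hits data.frame from [read_m8_btop()].
#' @return data.frame with `query_acc`, `subject_acc`, `align_len`,
#'   `n_identical`, `percent_identity` (BTOP-derived), `n_gaps`, `max_gap`.
#' @export
summarize_hits <- function(hits) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    s <- summarize_alignment(hits[i, ])
    data.frame(query_acc = s$query_acc, subject_acc = s$subject_acc,
               align_len = s$align_len, n_identical = s$n_identical,
               percent_identity = s$percent_identity,
               n_gaps = nrow(s$gap_events), max_gap = s$max_gap,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(query_acc = character(0), subject_acc = character(0),
                      align_len = integer(0), n_identical = integer(0),
                      percent_identity = numeric(0), n_gaps = integer(0),
                      max_gap = integer(0)))
  do.call(rbind, rows)
}

#' Keep the best statistically significant hit per query
#'
#' Filters to queries longer than `min_query_len` residues with E-value
#' strictly below `max_evalue`, then keeps one hit per query: the lowest
#' E-value, ties broken by higher bit score, then by subject accession.
#'
#' @param hits data.frame from [read_m8_btop()] with `query_len` populated.
#' @param min_query_len queries must be strictly longer (default 100).
#' @param max_evalue strict E-value cutoff (default 1e-6).
#' @return summary data.frame (see [summarize_hits()]) of the retained best
#'   hits, one row per query.
#' @export
best_hit_filter <- function(hits, min_query_len = 100, max_evalue = 1e-6) {
  keep <- !is.na(hits$query_len) & hits$query_len > min_query_len &
    hits$e_value < max_evalue
  h <- hits[keep, , drop = FALSE]
  if (nrow(h)) {
    h <- h[order(h$query_acc, h$e_value, -h$bit_score, h$subject_acc), ,
           drop = FALSE]
    h <- h[!duplicated(h$query_acc), , drop = FALSE]
  }
  summarize_hits(h)
}

#' Per identity-bin gap statistics for a proteome pair
#'
#' Bins alignments by percent identity (half-open bins `[lo, hi)`) and for
#' each bin reports the count and the fraction of alignments whose longest
#' gap reaches each threshold.  The overall fraction of alignments more
#' than 90% identical, and the gap fractions within that `>90%` subset, are
#' reported alongside.
#'
#' @param summaries data.frame from [summarize_hits()] /
#'   [best_hit_filter()].
#' @param id_breaks identity bin edges (default width-1 bins covering
#'   `[0, 101)` so that 100%-identical alignments land in the last bin).
#' @param gap_thresholds gap lengths to tabulate (default 5 and 10).
#' @return list of class `pair_stats`: `bins` (data.frame with `lo`, `hi`,
#'   `n` and one `frac_ge_<t>` column per threshold), `n` (alignments),
#'   `frac_gt90` (fraction with identity strictly above 90), and `gt90`
#'   (data.frame threshold/fraction within the >90% subset).  Empty input
#'   yields empty tables.
#' @export
proteome_pair_stats <- function(summaries, id_breaks = 0:101,
                                gap_thresholds = c(5, 10)) {
  frac_cols <- paste0("frac_ge_", gap_thresholds)
  if (!nrow(summaries)) {
    bins <- data.frame(lo = numeric(0), hi = numeric(0), n = integer(0))
    bins[frac_cols] <- rep(list(numeric(0)), length(gap_thresholds))
    return(structure(list(bins = bins, n = 0L, frac_gt90 = NA_real_,
                          gt90 = data.frame(threshold = gap_thresholds,
                                            fraction = NA_real_)),
                     class = "pair_stats"))
  }
  idx <- findInterval(summaries$percent_identity, id_breaks,
                      rightmost.closed = FALSE)
  lo <- id_breaks[-length(id_breaks)]
  hi <- id_breaks[-1]
  bins <- data.frame(lo = lo, hi = hi,
                     n = vapply(seq_along(lo),
                                function(b) sum(idx == b), 0L))
  for (k in seq_along(gap_thresholds)) {
    t <- gap_thresholds[k]
    bins[[frac_cols[k]]] <- vapply(seq_along(lo), function(b) {
      inb <- idx == b
      if (!any(inb)) return(NA_real_)
      mean(summaries$max_gap[inb] >= t)
    }, 0)
  }
  gt90 <- summaries$percent_identity > 90
  structure(list(
    bins = bins,
    n = nrow(summaries),
    frac_gt90 = mean(gt90),
    gt90 = data.frame(
      threshold = gap_thresholds,
      fraction = vapply(gap_thresholds, function(t)
        if (any(gt90)) mean(summaries$max_gap[gt90] >= t) else NA_real_, 0))
  ), class = "pair_stats")
}

#' @export
print.pair_stats <- function(x, ...) {
  cat("proteome-pair gap statistics over", x$n, "alignments;",
      sprintf("%.1f%%", 100 * x$frac_gt90), "are >90% identical\n")
  invisible(x)
}

#' Write proteome-pair gap statistics as CSV
#' @param stats a `pair_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_stats_csv <- function(stats, path) {
  utils::write.csv(stats$bins, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample a gap-length distribution for plotting
#'
#' Mirrors the sampled-distribution displays: a fixed-size random sample of
#' alignments, plus all alignments whose longest gap exceeds `long_gap`,
#' plus the `top_n` longest gaps.
#'
#' @param summaries data.frame from [summarize_hits()].
#' @param n_samples random sample size (default 100).
#' @param long_gap always include alignments with `max_gap` above this
#'   (default 50).
#' @param top_n always include this many longest gaps (default 25).
#' @return subset of `summaries` rows (deduplicated), ordered by descending
#'   `max_gap`.
#' @export
sample_gap_distribution <- function(summaries, n_samples = 100,
                                    long_gap = 50, top_n = 25) {
  if (!nrow(summaries)) return(summaries)
  take <- sample(nrow(summaries), min(n_samples, nrow(summaries)))
  take <- union(take, which(summaries$max_gap > long_gap))
  take <- union(take, order(-summaries$max_gap)[seq_len(min(top_n,
                                                            nrow(summaries)))])
  out <- summaries[take, , drop = FALSE]
  out[order(-out$max_gap, out$query_acc), , drop = FALSE]
}
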