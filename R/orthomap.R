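# Extension of human-anchored orthogroup assignments to further proteomes.
#
# A target-proteome sequence inherits the orthogroup of its best qualifying
# hit against the human proteome, where qualifying means identity of at
# least 50% and alignment coverage of strictly more than 75% of the human
# protein length.  Coverage is measured in human coordinates: the alignment
# length minus the columns gapped on the human side of the alignment
# (decoded from BTOP when available, otherwise taken from the human
# coordinate span).

#' Identity/coverage rule for orthogroup extension
#'
#' @param min_identity minimum fractional identity (default 0.50,
#'   inclusive).
#' @param min_coverage minimum fraction of the human sequence length
#'   covered (default 0.75, exclusive by default).
#' @param identity_inclusive is the identity bound inclusive (`>=`,
#'   default) or strict (`>`)?
#' @param coverage_strict is the coverage bound strict (`>`, default) or
#'   inclusive (`>=`)?
#' @return list of class `mapping_rule`.
#' @export
mapping_rule <- function(min_identity = 0.50, min_coverage = 0.75,
                         identity_inclusive = TRUE, coverage_strict = TRUE) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 identity_inclusive = identity_inclusive,
                 coverage_strict = coverage_strict),
            class = "mapping_rule")
}

# alignment length in the human sequence's coordinates
human_aligned_length <- function(hit, human_side) {
  if (!is.null(hit$btop) && !is.na(hit$btop) && nzchar(hit$btop)) {
    ev <- decode_btop(hit$btop)
    gap_type <- if (human_side == "subject") "sgap" else "qgap"
    sum(ev$length) - sum(ev$length[ev$type == gap_type])
  } else if (human_side == "subject") {
    abs(hit$s_end - hit$s_start) + 1L
  } else {
    abs(hit$q_end - hit$q_start) + 1L
  }
}

#' Extend orthogroup assignments via best qualifying human hits
#'
#' @param hits data.frame from [read_m8_btop()]; by default target-proteome
#'   queries searched against human subjects (`human_side = "subject"`),
#'   with the human sequence length populated (`subject_len` /
#'   `query_len`).
#' @param human_orthogroup_map data.frame from [read_orthogroup_table()]
#'   (or a named character vector accession -> orthogroup).  A human
#'   accession listed under several orthogroups resolves to the
#'   lexicographically smallest, with a warning.
#' @param rule a [mapping_rule()].
#' @param human_side which side of the hit is the human anchor, `"subject"`
#'   (default) or `"query"`.
#' @return data.frame with one row per assigned target accession:
#'   `accession`, `orthogroup_id`, `via` (the human accession),
#'   `identity` (fraction), `coverage` (fraction of human length); ordered
#'   by `accession`, independent of hit order.  Hits whose human accession
#'   is absent from the map are ignored with a warning.
#' @export
extend_orthogroups <- function(hits, human_orthogroup_map,
                               rule = mapping_rule(),
                               human_side = c("subject", "query")) {
  human_side <- match.arg(human_side)
  if (is.data.frame(human_orthogroup_map)) {
    m <- human_orthogroup_map[order(human_orthogroup_map$accession,
                                    human_orthogroup_map$orthogroup_id), ]
    dup <- duplicated(m$accession)
    if (any(dup))
      gc_warn("human accession(s) in several orthogroups; using the ",
              "lexicographically smallest: ",
              paste(unique(m$accession[dup]), collapse = ", "))
    og_of <- stats::setNames(m$orthogroup_id, m$accession)[!dup]
  } else {
    og_of <- human_orthogroup_map
  }
  if (!nrow(hits))
    return(data.frame(accession = character(0), orthogroup_id = character(0),
                      via = character(0), identity = numeric(0),
                      coverage = numeric(0), stringsAsFactors = FALSE))

  human_acc <- if (human_side == "subject") hits$subject_acc else
    hits$query_acc
  target_acc <- if (human_side == "subject") hits$query_acc else
    hits$subject_acc
  human_len <- if (human_side == "subject") hits$subject_len else
    hits$query_len
  if (anyNA(human_len))
    gc_stop("human sequence lengths must be populated for coverage")

  known <- human_acc %in% names(og_of)
  if (any(!known))
    gc_warn("ignoring ", sum(!known), " hit(s) whose human accession is ",
            "not in the orthogroup map")

  identity <- hits$percent_identity / 100
  coverage <- vapply(seq_len(nrow(hits)), function(i)
    human_aligned_length(hits[i, ], human_side), 0) / human_len

  ok_id <- if (rule$identity_inclusive) identity >= rule$min_identity else
    identity > rule$min_identity
  ok_cov <- if (rule$coverage_strict) coverage > rule$min_coverage else
    coverage >= rule$min_coverage
  keep <- known & ok_id & ok_cov
  if (!any(keep))
    return(data.frame(accession = character(0), orthogroup_id = character(0),
                      via = character(0), identity = numeric(0),
                      coverage = numeric(0), stringsAsFactors = FALSE))

  df <- data.frame(accession = target_acc[keep],
                   human_acc = human_acc[keep],
                   identity = identity[keep], coverage = coverage[keep],
                   stringsAsFactors = FALSE)
  # best qualifying hit per target: highest identity, then coverage,
  # then the smallest human accession (independent of input order)
  df <- df[order(df$accession, -df$identity, -df$coverage, df$human_acc), ]
  df <- df[!duplicated(df$accession), ]
  out <- data.frame(accession = df$accession,
                    orthogroup_id = unname(og_of[df$human_acc]),
                    via = df$human_acc,
                    identity = df$identity, coverage = df$coverage,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write an accession-to-orthogroup extension table as TSV
#' @param assignments data.frame from [extend_orthogroups()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_extension_tsv <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
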