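# Ranking of low-cost clades, non-overlapping selection per Gene-Centric
# gene set, and classification into confirmed canonicals vs proposed
# changes.
#
# Clades are ranked by strict lexicographic priority: (i) lower clade cost;
# (ii) more proteomes; (iii) more canonical members; (iv) more reviewed
# human/mouse members; (v) smaller relative length deviation from the
# current canonical lengths; ties broken by the smallest member accession so
# the order is total and reproducible.  Reviewed (Swiss-Prot) canonicals are
# never proposed for automatic change - they are flagged for curators.

#' Relative length deviation of a clade from the canonical lengths
#'
#' Clades whose members have lengths very different from the current
#' canonical lengths of the orthogroup are down-weighted in ranking.  The
#' penalty is `|median(member lengths) - median(canonical lengths)| /
#' median(canonical lengths)`.
#'
#' @param member_lengths integer vector of clade member lengths.
#' @param canonical_lengths integer vector of the orthogroup's current
#'   canonical lengths; if empty the penalty is 0, with a warning.
#' @return non-negative number.
#' @export
#' @examples
#' length_penalty(c(196, 196, 197), c(196, 210, 196))  # 0
#' length_penalty(256, 196)                            # ~0.306
length_penalty <- function(member_lengths, canonical_lengths) {
  if (!length(canonical_lengths)) {
    gc_warn("no canonical lengths available; length penalty set to 0")
    return(0)
  }
  mc <- stats::median(canonical_lengths)
  abs(stats::median(member_lengths) - mc) / mc
}

#' Rank clade candidates
#'
#' @param candidates list of candidates for one orthogroup from
#'   [find_low_cost_clades()].
#' @param canonical_lengths lengths of the orthogroup's current canonical
#'   sequences, used for the length-deviation criterion.
#' @return the candidates ordered best-first, each with `length_deviation`
#'   filled in and a 1-based `rank`.
#' @export
rank_clades <- function(candidates, canonical_lengths) {
  if (!length(candidates)) return(candidates)
  candidates <- lapply(candidates, function(x) {
    x$length_deviation <- suppressWarnings(
      length_penalty(x$members$length, canonical_lengths))
    x
  })
  ord <- order(vapply(candidates, `[[`, 0, "cost"),
               -vapply(candidates, `[[`, 0, "n_proteomes"),
               -vapply(candidates, `[[`, 0, "n_canonical"),
               -vapply(candidates, `[[`, 0, "n_reviewed_hm"),
               vapply(candidates, `[[`, 0, "length_deviation"),
               vapply(candidates, function(x) x$accessions[1], ""))
  candidates <- candidates[ord]
  for (i in seq_along(candidates)) candidates[[i]]$rank <- i
  candidates
}

#' Select non-overlapping clades over Gene-Centric gene sets
#'
#' Greedy: the best-ranked clade is always selected; each further clade is
#' selected only if its members' Gene-Centric groups are disjoint from every
#' already-selected clade, so one orthogroup can confirm one set of genes
#' while proposing changes for a different set.
#'
#' @param ranked output of [rank_clades()].
#' @return list of selected candidates (subset of `ranked`, in rank order).
#' @export
select_clades <- function(ranked) {
  selected <- list()
  used <- character(0)
  for (cand in ranked) {
    groups <- unique(cand$members$gene_group_id)
    if (length(intersect(groups, used))) next
    selected[[length(selected) + 1L]] <- cand
    used <- c(used, groups)
  }
  selected
}

#' Turn selected clades into canonical suggestions
#'
#' For every member of every selected clade: if the member is the current
#' canonical of its Gene-Centric group the suggestion is `confirm`;
#' otherwise a change to the member's base accession is suggested -
#' `propose_change` when the current canonical is unreviewed (TrEMBL, may be
#' changed automatically), `flag_reviewed` when it is reviewed (Swiss-Prot
#' canonicals are never changed automatically).
#'
#' @param selected list from [select_clades()].
#' @param records `seq_records` with the current canonical flags for all
#'   Gene-Centric groups involved.
#' @return data.frame with columns `orthogroup_id`, `proteome_id`,
#'   `gene_group_id`, `old_canonical`, `new_canonical`, `action`,
#'   `clade_cost`, `clade_size`, `rank`.
#' @export
emit_suggestions <- function(selected, records) {
  rows <- list()
  for (cand in selected) {
    mem <- cand$members
    for (i in seq_len(nrow(mem))) {
      gg <- mem$gene_group_id[i]
      if (is.na(gg) || !nzchar(gg)) {
        gc_warn("clade member ", mem$accession[i],
                " has no Gene-Centric group; skipped")
        next
      }
      cur <- records[records$has_gene_group &
                       records$gene_group_id == gg &
                       records$proteome_id == mem$proteome_id[i] &
                       records$is_canonical, , drop = FALSE]
      if (!nrow(cur)) {
        gc_warn("no current canonical found for gene group ", gg)
        next
      }
      old <- cur$accession[1]
      if (mem$accession[i] == old) {
        action <- "confirm"
        new <- old
      } else {
        new <- base_accession(mem$accession[i])
        action <- if (cur$review_status[1] == "reviewed")
          "flag_reviewed" else "propose_change"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup_id = cand$orthogroup_id,
        proteome_id = mem$proteome_id[i],
        gene_group_id = gg,
        old_canonical = old,
        new_canonical = new,
        action = action,
        clade_cost = cand$cost,
        clade_size = nrow(mem),
        rank = cand$rank,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(orthogroup_id = character(0),
                      proteome_id = character(0),
                      gene_group_id = character(0),
                      old_canonical = character(0),
                      new_canonical = character(0),
                      action = character(0),
                      clade_cost = numeric(0), clade_size = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
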