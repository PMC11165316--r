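# Low-cost clade search over a gap-distance tree.
#
# A candidate clade holds at most one sequence per proteome, spans at least
# `min_proteomes` proteomes, and has cost at or below the threshold.  The
# cost of a clade is the MAXIMUM pairwise gap distance among its members:
# cost zero then means literally that every pair aligns without one-sided
# gaps, and a low cost certifies that every pair - not just the average
# pair - aligns near-gaplessly.  The default threshold 0.02 is inclusive.

#' Cost of a clade: maximum pairwise gap distance
#'
#' @param leaf_set character vector of accessions (matrix labels).
#' @param gdm a `gap_dist` object.
#' @return maximum pairwise distance within the set; 0 (with a warning) for
#'   a singleton.
#' @export
clade_cost <- function(leaf_set, gdm) {
  if (length(leaf_set) < 2) {
    gc_warn("singleton clade has cost 0 by convention")
    return(0)
  }
  max(gdm$d[leaf_set, leaf_set])
}

# Resolve duplicate proteomes inside a tree clade: isoforms of one gene
# often co-cluster, so for each proteome with several leaves keep the one
# minimising its summed gap distance to the clade members of the OTHER
# proteomes (so rivals do not influence each other's score).  Ties: prefer
# canonical, then reviewed, then the lexicographically smallest accession.
resolve_duplicate_proteomes <- function(leaves, gdm, records) {
  rec <- records[match(leaves, records$accession), , drop = FALSE]
  keep <- character(0)
  for (p in sort(unique(rec$proteome_id))) {
    own <- leaves[rec$proteome_id == p]
    if (length(own) == 1) { keep <- c(keep, own); next }
    others <- setdiff(leaves, own)
    score <- if (length(others))
      rowSums(gdm$d[own, others, drop = FALSE]) else rep(0, length(own))
    r <- rec[match(own, rec$accession), ]
    ord <- order(score, !r$is_canonical, r$review_status != "reviewed", own)
    keep <- c(keep, own[ord[1]])
  }
  sort(keep)
}

new_clade_candidate <- function(orthogroup_id, leaves, gdm, records,
                                node = NA_integer_,
                                hm_proteomes = c("HUMAN", "MOUSE")) {
  rec <- records[match(leaves, records$accession), , drop = FALSE]
  cost <- if (length(leaves) >= 2) max(gdm$d[leaves, leaves]) else 0
  list(orthogroup_id = orthogroup_id,
       accessions = sort(leaves),
       members = rec,
       cost = cost,
       n_proteomes = length(unique(rec$proteome_id)),
       n_canonical = sum(rec$is_canonical),
       n_reviewed_hm = sum(rec$review_status == "reviewed" &
                             rec$proteome_id %in% hm_proteomes),
       length_deviation = NA_real_,
       source_node = node)
}

#' Find all low-cost multi-proteome clades of a gap-distance tree
#'
#' Every internal node of the tree is examined (exhaustive scan, feasible at
#' orthogroup scale).  Within a node's leaf set, duplicate proteomes are
#' first resolved down to one sequence each; the resolved set qualifies if
#' it spans at least `min_proteomes` proteomes and its cost (maximum
#' pairwise gap distance) is at most `cost_threshold` (inclusive).
#' Candidates from nested nodes that resolve to the same member set are
#' reported once, and a candidate strictly contained in another reported
#' candidate is dropped in favour of the larger one (largest proteome
#' coverage first, then lowest cost).
#'
#' @param tree [ape::phylo] from [nj_tree()].
#' @param gdm the `gap_dist` the tree was built from.
#' @param records `seq_records` covering all tree leaves.
#' @param cost_threshold maximum admissible clade cost (default 0.02,
#'   inclusive).
#' @param min_proteomes minimum distinct proteomes per clade (default 3).
#' @param orthogroup_id carried through to the candidates.
#' @param hm_proteomes proteome codes whose reviewed entries count for the
#'   ranking criterion (default human and mouse).
#' @return list of clade candidates (possibly empty), each a list with
#'   `accessions`, `members`, `cost`, `n_proteomes`, `n_canonical`,
#'   `n_reviewed_hm`, `source_node`.
#' @export
find_low_cost_clades <- function(tree, gdm, records,
                                 cost_threshold = 0.02, min_proteomes = 3,
                                 orthogroup_id = NA_character_,
                                 hm_proteomes = c("HUMAN", "MOUSE")) {
  cands <- list()
  for (cl in tree_clade_sets(tree)) {
    leaves <- resolve_duplicate_proteomes(cl$leaves, gdm, records)
    if (length(leaves) < 2) next
    rec <- records[match(leaves, records$accession), , drop = FALSE]
    if (length(unique(rec$proteome_id)) < min_proteomes) next
    if (max(gdm$d[leaves, leaves]) > cost_threshold) next
    cands[[length(cands) + 1L]] <-
      new_clade_candidate(orthogroup_id, leaves, gdm, records,
                          node = cl$node, hm_proteomes = hm_proteomes)
  }
  dedup_candidates(cands)
}

# Candidate leaf sets of an unrooted tree: every bipartition side, i.e.
# each internal node's descendant set plus the complement of every node's
# (internal or tip) descendant set.  The traversal root is an arbitrary
# artifact of the final NJ agglomeration, so a genuine clade can sit on
# either side of an edge.
tree_clade_sets <- function(tree) {
  all_leaves <- sort(tree$tip.label)
  sets <- clades_of(tree)
  out <- sets
  comp_of <- c(lapply(sets, `[[`, "leaves"), as.list(tree$tip.label))
  for (s in comp_of) {
    comp <- setdiff(all_leaves, s)
    if (length(comp) >= 2)
      out[[length(out) + 1L]] <- list(node = NA_integer_, leaves = comp)
  }
  out
}

# keep largest-coverage (then lowest-cost) candidates; drop exact repeats
# and candidates strictly contained in an already-kept one
dedup_candidates <- function(cands) {
  if (length(cands) < 2) return(cands)
  key <- vapply(cands, function(x) paste(x$accessions, collapse = "|"), "")
  cands <- cands[!duplicated(key)]
  ord <- order(-vapply(cands, `[[`, 0, "n_proteomes"),
               vapply(cands, `[[`, 0, "cost"),
               vapply(cands, function(x) x$accessions[1], ""))
  cands <- cands[ord]
  kept <- list()
  for (cand in cands) {
    nested <- any(vapply(kept, function(k)
      all(cand$accessions %in% k$accessions), TRUE))
    if (!nested) kept[[length(kept) + 1L]] <- cand
  }
  kept
}

#' Dump clade candidates as a TSV audit table
#' @param cands list of candidates from [find_low_cost_clades()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(cands, path) {
  df <- candidates_table(cands)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise clade candidates as a data.frame
#' @param cands list of candidates.
#' @return data.frame with one row per candidate.
#' @export
candidates_table <- function(cands) {
  if (!length(cands))
    return(data.frame(orthogroup_id = character(0), node = integer(0),
                      members = character(0), cost = numeric(0),
                      n_proteomes = integer(0)))
  data.frame(
    orthogroup_id = vapply(cands, `[[`, "", "orthogroup_id"),
    node = vapply(cands, function(x) as.integer(x$source_node), 0L),
    members = vapply(cands, function(x)
      paste(x$accessions, collapse = ","), ""),
    cost = vapply(cands, `[[`, 0, "cost"),
    n_proteomes = vapply(cands, function(x) as.integer(x$n_proteomes), 0L),
    stringsAsFactors = FALSE)
}
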