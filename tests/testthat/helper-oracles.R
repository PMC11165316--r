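# Independent oracles and small fixture builders used across the suite.
# These re-derive expected values by the most literal route available
# (per-column counting, subset enumeration, ape's own NJ) and share no code
# with the implementation paths they check.

AA_POOL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# random alignment rows: n sequences by L columns, gap probability per cell;
# all-gap columns are repaired by planting a residue
random_msa_rows <- function(n, L, gap_p = 0.2) {
  m <- matrix(sample(AA_POOL, n * L, replace = TRUE), n, L)
  m[matrix(runif(n * L) < gap_p, n, L)] <- "-"
  for (j in which(colSums(m != "-") == 0))
    m[sample(n, 1), j] <- sample(AA_POOL, 1)
  rows <- apply(m, 1, paste, collapse = "")
  names(rows) <- sprintf("S%02d", seq_len(n))
  rows
}

# literal per-column gap distance between two aligned strings
oracle_gap_pair <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  gap_cols <- 0L; pair_len <- 0L
  for (k in seq_along(ca)) {
    ga <- ca[k] == "-"; gb <- cb[k] == "-"
    if (ga && gb) next
    pair_len <- pair_len + 1L
    if (ga || gb) gap_cols <- gap_cols + 1L
  }
  gap_cols / pair_len
}

oracle_gap_matrix <- function(rows) {
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- oracle_gap_pair(rows[i], rows[j])
  d
}

# random tree with positive branch lengths and its additive leaf distance
# matrix (path sums via cophenetic)
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.05, 0.5))
  tr$tip.label <- sprintf("L%02d", seq_len(n_leaves))
  list(tree = tr, d = stats::cophenetic(tr)[tr$tip.label, tr$tip.label])
}

# duplicate-proteome resolution, re-derived with plain loops: for each
# proteome keep the leaf with the smallest summed distance to leaves of
# other proteomes, ties canonical > reviewed > accession
oracle_resolve <- function(leaves, d, rec) {
  out <- character(0)
  for (p in sort(unique(rec$proteome_id[match(leaves, rec$accession)]))) {
    own <- leaves[rec$proteome_id[match(leaves, rec$accession)] == p]
    if (length(own) > 1) {
      others <- setdiff(leaves, own)
      sc <- sapply(own, function(a)
        if (length(others)) sum(d[a, others]) else 0)
      r <- rec[match(own, rec$accession), ]
      own <- own[order(sc, !r$is_canonical,
                       r$review_status != "reviewed", own)][1]
    }
    out <- c(out, own)
  }
  sort(out)
}

# brute-force candidate search: enumerate every leaf subset, keep those
# that (a) are the resolved form of some tree clade, (b) hold at most one
# sequence per proteome over >= min_p proteomes, (c) cost <= thr; then
# apply the same largest-coverage / lowest-cost containment dedup
oracle_candidates <- function(tree, d, rec, thr = 0.02, min_p = 3) {
  leaves <- tree$tip.label
  parts <- ape::prop.part(tree)
  node_sets <- lapply(parts, function(idx) sort(attr(parts, "labels")[idx]))
  # unrooted tree: both sides of every bipartition are clades
  side_sets <- c(node_sets,
                 lapply(c(node_sets, as.list(leaves)), function(s)
                   sort(setdiff(leaves, s))))
  side_sets <- side_sets[lengths(side_sets) >= 2]
  resolved <- unique(lapply(side_sets, oracle_resolve, d = d, rec = rec))
  keep <- list()
  n <- length(leaves)
  for (mask in 1:(2^n - 1)) {
    S <- sort(leaves[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
    if (length(S) < 2) next
    prot <- rec$proteome_id[match(S, rec$accession)]
    if (anyDuplicated(prot)) next
    if (length(unique(prot)) < min_p) next
    if (max(d[S, S]) > thr) next
    if (!any(vapply(resolved, identical, TRUE, y = S))) next
    keep[[length(keep) + 1L]] <- S
  }
  if (!length(keep)) return(keep)
  np <- vapply(keep, function(S)
    length(unique(rec$proteome_id[match(S, rec$accession)])), 0L)
  cost <- vapply(keep, function(S) max(d[S, S]), 0)
  first <- vapply(keep, `[`, "", 1)
  keep <- keep[order(-np, cost, first)]
  final <- list()
  for (S in keep)
    if (!any(vapply(final, function(K) all(S %in% K), TRUE)))
      final[[length(final) + 1L]] <- S
  final
}

# canonical string form for comparing candidate sets
candidate_keys <- function(cands) {
  sort(vapply(cands, function(x)
    paste(if (is.list(x) && !is.null(x$accessions)) x$accessions else x,
          collapse = "|"), ""))
}

# a small hand-built record table
make_records <- function(accession, proteome, canonical = TRUE,
                         reviewed = FALSE, gene_group = proteome,
                         residues = NULL) {
  n <- length(accession)
  if (is.null(residues)) residues <- strrep("M", 10 + seq_len(n))
  seq_records(accession, proteome, residues,
              review_status = ifelse(rep_len(reviewed, n),
                                     "reviewed", "unreviewed"),
              is_canonical = rep_len(canonical, n),
              gene_group_id = rep_len(gene_group, n))
}
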