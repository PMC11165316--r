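# Synthetic multi-proteome orthogroups with exon-block isoform structure
# and planted ground truth, plus synthetic m8+BTOP proteome-pair tables.
#
# Each synthetic gene is a series of exon blocks; the "truth" isoform (the
# biologically consistent one, shared by every proteome) is the plain
# concatenation of the core blocks, mutated by amino-acid substitutions
# only, so the truth clade has gap cost exactly zero by construction.  A
# decoy proteome's current canonical instead carries an N-terminal
# extension block whose length is proteome-specific and spaced at least 20
# columns from any other decoy's, so every decoy-containing clade has gap
# cost well above the 0.02 acceptance threshold.  Because blocks define
# alignment columns, the generator emits the true multiple alignment
# directly and nothing downstream depends on an external aligner.

DEFAULT_PROTEOMES <- c("HUMAN", "MOUSE", "RAT", "BOVIN",
                       "CANLF", "MONDO", "PANTR", "GORGO")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration for the synthetic-data generator
#'
#' @param n_proteomes number of proteomes (default 6, drawn from a fixed
#'   mammal-style code list).
#' @param n_orthogroups number of orthogroups to simulate.
#' @param substitution_rate per-residue substitution probability on each
#'   proteome's branch (default 0.05); substitutions never create gaps.
#' @param decoy_fraction fraction of proteomes per orthogroup whose current
#'   canonical is a non-truth (extended) isoform (default 0.3).
#' @param decoy_group_fraction fraction of orthogroups that carry decoys at
#'   all (default 1); the rest are generated with every canonical on the
#'   truth pattern, so the pipeline should confirm them.
#' @param reviewed_decoy_fraction fraction of decoy canonicals that are
#'   reviewed entries (default 0; reviewed canonicals are only flagged,
#'   never auto-changed, so keeping this at 0 makes all planted changes
#'   auto-applicable).
#' @param include_short_isoform also give each proteome a cassette-skip
#'   isoform missing one core block (default `FALSE`).
#' @param indel_free_truth keep the truth pattern free of indels so the
#'   truth clade has cost exactly 0 (default `TRUE`).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_proteomes = 6, n_orthogroups = 50,
                              substitution_rate = 0.05,
                              decoy_fraction = 0.3,
                              decoy_group_fraction = 1,
                              reviewed_decoy_fraction = 0,
                              include_short_isoform = FALSE,
                              indel_free_truth = TRUE,
                              seed) {
  stopifnot(n_proteomes >= 2, n_proteomes <= length(DEFAULT_PROTEOMES),
            substitution_rate >= 0, substitution_rate < 1,
            decoy_fraction >= 0, decoy_fraction <= 1,
            decoy_group_fraction >= 0, decoy_group_fraction <= 1,
            !missing(seed))
  structure(list(n_proteomes = n_proteomes, n_orthogroups = n_orthogroups,
                 substitution_rate = substitution_rate,
                 decoy_fraction = decoy_fraction,
                 decoy_group_fraction = decoy_group_fraction,
                 reviewed_decoy_fraction = reviewed_decoy_fraction,
                 include_short_isoform = include_short_isoform,
                 indel_free_truth = indel_free_truth,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rand_res <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# substitute residues i.i.d. at `rate`, always to a different letter
mutate_residues <- function(x, rate) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA20, a), 1), "")
  paste(chars, collapse = "")
}

#' Generate one synthetic orthogroup with planted truth
#'
#' @param og_index integer index used to build the orthogroup id
#'   (`SYNOG<index>`) and accessions.
#' @param config a `sim_config`.  The caller controls the RNG state (e.g.
#'   via [generate_dataset()] or `set.seed`).
#' @param decoy_proteomes optional character vector naming the proteomes to
#'   make decoys; by default `round(decoy_fraction * n_proteomes)` proteomes
#'   are drawn at random.
#' @return list with `bundle` (an `orthogroup_bundle`), `msa` (the true
#'   multiple alignment as an `msa` object) and `truth` (data.frame with
#'   `orthogroup_id`, `proteome_id`, `gene_group_id`, `current_canonical`,
#'   `true_canonical`, `is_decoy`).
#' @export
generate_orthogroup <- function(og_index, config, decoy_proteomes = NULL) {
  og_id <- sprintf("SYNOG%04d", og_index)
  proteomes <- DEFAULT_PROTEOMES[seq_len(config$n_proteomes)]
  if (is.null(decoy_proteomes)) {
    n_decoy <- round(config$decoy_fraction * config$n_proteomes)
    decoy_proteomes <- if (n_decoy > 0)
      sample(proteomes, n_decoy) else character(0)
  }
  stopifnot(all(decoy_proteomes %in% proteomes))

  nb <- sample(3:6, 1)
  block_len <- sample(25:60, nb, replace = TRUE)
  blocks <- vapply(block_len, rand_res, "")
  core <- paste(blocks, collapse = "")
  core_len <- nchar(core)

  # decoy N-terminal extensions, right-aligned in a shared extension zone;
  # lengths spaced by 20 columns so decoy-decoy gap distances stay > 0.02
  ext_len <- stats::setNames(integer(length(decoy_proteomes)),
                             decoy_proteomes)
  if (length(decoy_proteomes))
    ext_len[] <- 40 + 20 * (seq_along(decoy_proteomes) - 1)
  ext_zone <- if (length(ext_len)) max(ext_len) else 0L

  pad <- function(res, lead_gaps) {
    paste0(strrep("-", lead_gaps), res,
           strrep("-", ext_zone + core_len - lead_gaps - nchar(res)))
  }

  acc_truth <- function(p) sprintf("T%04dX%s", og_index, p)
  acc_decoy <- function(p) sprintf("D%04dX%s", og_index, p)

  recs <- list(); rows <- character(0); row_acc <- character(0)
  truth_rows <- list()
  for (p in proteomes) {
    gg <- sprintf("GG%04d_%s", og_index, p)
    is_decoy <- p %in% decoy_proteomes
    truth_res <- mutate_residues(core, config$substitution_rate)
    if (is_decoy) {
      ext <- rand_res(ext_len[[p]])
      decoy_res <- paste0(ext,
                          mutate_residues(core, config$substitution_rate))
      can_acc <- acc_decoy(p)
      iso_acc <- paste0(acc_truth(p), "-1")
      reviewed_can <- stats::runif(1) < config$reviewed_decoy_fraction
      recs[[length(recs) + 1L]] <- data.frame(
        accession = c(can_acc, iso_acc),
        proteome_id = p,
        entry_name = paste0(sprintf("SG%04d_", og_index), p),
        review_status = c(if (reviewed_can) "reviewed" else "unreviewed",
                          "unreviewed"),
        is_canonical = c(TRUE, FALSE),
        gene_group_id = gg,
        residues = c(decoy_res, truth_res),
        stringsAsFactors = FALSE)
      rows <- c(rows, pad(decoy_res, ext_zone - ext_len[[p]]),
                pad(truth_res, ext_zone))
      row_acc <- c(row_acc, can_acc, iso_acc)
      truth_can <- iso_acc
    } else {
      can_acc <- acc_truth(p)
      reviewed_can <- p %in% c("HUMAN", "MOUSE")
      recs[[length(recs) + 1L]] <- data.frame(
        accession = can_acc,
        proteome_id = p,
        entry_name = paste0(sprintf("SG%04d_", og_index), p),
        review_status = if (reviewed_can) "reviewed" else "unreviewed",
        is_canonical = TRUE,
        gene_group_id = gg,
        residues = truth_res,
        stringsAsFactors = FALSE)
      rows <- c(rows, pad(truth_res, ext_zone))
      row_acc <- c(row_acc, can_acc)
      truth_can <- can_acc
    }
    if (config$include_short_isoform) {
      skip <- (match(p, proteomes) - 1) %% nb + 1
      keep_blocks <- blocks[-skip]
      short_res <- mutate_residues(paste(keep_blocks, collapse = ""),
                                   config$substitution_rate)
      # reinsert the gap at the skipped block's columns
      before <- if (skip > 1) sum(block_len[seq_len(skip - 1)]) else 0
      aligned <- paste0(substr(short_res, 1, before),
                        strrep("-", block_len[skip]),
                        substr(short_res, before + 1, nchar(short_res)))
      iso_acc <- paste0(can_acc, "-2")
      recs[[length(recs) + 1L]] <- data.frame(
        accession = iso_acc, proteome_id = p,
        entry_name = paste0(sprintf("SG%04d_", og_index), p),
        review_status = "unreviewed", is_canonical = FALSE,
        gene_group_id = gg, residues = short_res,
        stringsAsFactors = FALSE)
      rows <- c(rows, pad(aligned, ext_zone))
      row_acc <- c(row_acc, iso_acc)
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      orthogroup_id = og_id, proteome_id = p, gene_group_id = gg,
      current_canonical = can_acc, true_canonical = truth_can,
      is_decoy = is_decoy, stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, recs)
  rec <- seq_records(members$accession, members$proteome_id,
                     members$residues, entry_name = members$entry_name,
                     review_status = members$review_status,
                     is_canonical = members$is_canonical,
                     gene_group_id = members$gene_group_id)
  aln <- stats::setNames(rows, row_acc)
  aln <- strip_allgap_columns(aln, quiet = TRUE)  # no decoys -> empty zone
  list(bundle = orthogroup_bundle(og_id, rec),
       msa = msa(og_id, aln),
       truth = do.call(rbind, truth_rows))
}

#' Generate a full synthetic dataset
#'
#' @param config a `sim_config`; its `seed` initialises the RNG so the same
#'   configuration always yields an identical dataset.
#' @return list of class `syn_dataset` with `bundles` (named list of
#'   `orthogroup_bundle`), `msas` (named list of `msa`), `records` (all
#'   sequence records combined), `truth` (row-bound truth tables),
#'   `orthogroup_table` and `gene_centric` mapping tables, and `config`.
#' @export
generate_dataset <- function(config) {
  set.seed(config$seed)
  n_decoy_ogs <- round(config$decoy_group_fraction * config$n_orthogroups)
  decoy_ogs <- sort(sample(config$n_orthogroups, n_decoy_ogs))
  bundles <- list(); msas <- list(); truths <- list()
  for (i in seq_len(config$n_orthogroups)) {
    g <- generate_orthogroup(
      i, config,
      decoy_proteomes = if (i %in% decoy_ogs) NULL else character(0))
    bundles[[g$bundle$orthogroup_id]] <- g$bundle
    msas[[g$bundle$orthogroup_id]] <- g$msa
    truths[[i]] <- g$truth
  }
  records <- do.call(rbind, lapply(bundles, `[[`, "members"))
  rownames(records) <- NULL
  class(records) <- c("seq_records", "data.frame")
  truth <- do.call(rbind, truths)
  og_tab <- data.frame(orthogroup_id = truth$orthogroup_id,
                       accession = truth$current_canonical,
                       stringsAsFactors = FALSE)
  gc_tab <- data.frame(gene_group_id = records$gene_group_id,
                       accession = records$accession,
                       is_canonical = records$is_canonical,
                       review_status = records$review_status,
                       stringsAsFactors = FALSE)
  structure(list(bundles = bundles, msas = msas, records = records,
                 truth = truth, orthogroup_table = og_tab,
                 gene_centric = gc_tab, config = config),
            class = "syn_dataset")
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Emits one FASTA per proteome, the orthogroup and Gene-Centric TSV
#' tables, one aligned FASTA per orthogroup (under `msa/`), and the truth
#' table as CSV.
#'
#' @param dataset from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "msa"), recursive = TRUE, showWarnings = FALSE)
  for (p in unique(dataset$records$proteome_id)) {
    rec <- dataset$records[dataset$records$proteome_id == p, , drop = FALSE]
    write_proteome_fasta(rec, file.path(dir, paste0(p, ".fasta")))
  }
  utils::write.table(dataset$orthogroup_table,
                     file.path(dir, "orthogroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$gene_centric,
                     file.path(dir, "gene_centric.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (og in names(dataset$msas)) {
    m <- dataset$msas[[og]]
    x <- Biostrings::AAStringSet(m$rows)
    Biostrings::writeXStringSet(
      x, file.path(dir, "msa", paste0(gsub("[^A-Za-z0-9_.-]", "_", og),
                                      ".afa")))
  }
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Generate a synthetic m8+BTOP best-hit table with planted gap fractions
#'
#' Emulates a pairwise proteome comparison: one best hit per query, all
#' with E-values well below 1e-6 and query lengths above 100, with an
#' exact planted fraction of alignments more than 90% identical and, within
#' that subset, an exact planted fraction carrying a gap of at least 5
#' residues.
#'
#' @param n_alignments number of alignments (one query each).
#' @param frac_gt90 fraction of alignments with identity > 90%
#'   (`round(frac * n)` of them, exactly).
#' @param frac_gap_ge5_gt90 fraction of the >90% subset given a gap of
#'   length >= 5 (again exact after rounding).
#' @param frac_gap_ge5_lo same for the <=90% subset (default 0.5).
#' @param max_gap_range range the planted long gap lengths are drawn from
#'   (default 5 to 120).
#' @param seed optional RNG seed.
#' @return hits data.frame in [read_m8_btop()] layout with `query_len` /
#'   `subject_len` populated; the attribute `planted` records the planted
#'   fractions.
#' @export
generate_pair_hits <- function(n_alignments, frac_gt90 = 0.5,
                               frac_gap_ge5_gt90 = 0.2,
                               frac_gap_ge5_lo = 0.5,
                               max_gap_range = c(5, 120),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_alignments
  if (n == 0) {
    f <- tempfile(); writeLines(character(0), f); on.exit(unlink(f))
    h <- read_m8_btop(f)
    attr(h, "planted") <- list(frac_gt90 = NA, frac_gap_ge5_gt90 = NA)
    return(h)
  }
  n_hi <- round(frac_gt90 * n)
  hi <- seq_len(n) <= n_hi          # first n_hi queries are >90% identical
  gap_hi <- seq_len(n_hi) <= round(frac_gap_ge5_gt90 * n_hi)
  n_lo <- n - n_hi
  gap_lo <- seq_len(n_lo) <= round(frac_gap_ge5_lo * n_lo)
  has_big_gap <- c(gap_hi, gap_lo)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pid_target <- if (hi[i]) stats::runif(1, 92, 98) else
      stats::runif(1, 60, 88)
    gap_pool <- max_gap_range[1]:max_gap_range[2]
    gap <- if (has_big_gap[i]) gap_pool[sample.int(length(gap_pool), 1)]
      else sample(0:4, 1)
    # aligned-residue span large enough that identity/alen can reach the
    # target despite the gap (alen = residue span + gap columns)
    span <- max(200, ceiling(gap * pid_target / (100 - pid_target))) +
      sample(50:150, 1)
    alen <- span + gap
    nid <- min(round(pid_target * alen / 100), span - 1)
    nmis <- span - nid
    # identity run | mismatches | identity run | gap | identity run;
    # adjacent integer runs must be merged so they cannot concatenate
    n1 <- nid %/% 3; n3 <- nid %/% 3; n2 <- nid - n1 - n3
    mis <- strrep("AG", nmis)
    gap_str <- if (gap > 0) strrep("-A", gap) else ""
    btop <- if (nmis > 0 && gap > 0) {
      paste0(n1, mis, n2, gap_str, n3)
    } else if (gap > 0) {
      paste0(n1 + n2, gap_str, n3)
    } else if (nmis > 0) {
      paste0(n1, mis, n2 + n3)
    } else {
      as.character(nid)
    }
    qlen <- nid + nmis + sample(0:20, 1)   # query-side gaps only
    rows[[i]] <- data.frame(
      query_acc = sprintf("SQ%05d", i),
      subject_acc = sprintf("SS%05d", i),
      percent_identity = round(100 * nid / alen, 2),
      align_len = alen, mismatches = nmis, gap_opens = as.integer(gap > 0),
      q_start = 1L, q_end = as.integer(nid + nmis),
      s_start = 1L, s_end = as.integer(alen),
      e_value = 10^stats::runif(1, -40, -10),
      bit_score = round(2 * nid + stats::runif(1, 0, 10), 1),
      btop = btop,
      query_len = qlen,
      subject_len = alen + sample(0:20, 1),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "planted") <- list(
    frac_gt90 = n_hi / n,
    frac_gap_ge5_gt90 = if (n_hi) mean(gap_hi) else NA_real_,
    frac_gap_ge5_lo = if (n_lo) mean(gap_lo) else NA_real_)
  out
}
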