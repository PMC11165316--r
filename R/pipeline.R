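# End-to-end driver: gather -> align -> gap-distance -> NJ tree -> clade
# search -> rank/select -> suggestion report, with per-orthogroup failure
# isolation and a run summary in the yield-table categories.

#' Run the canonical-selection pipeline over orthogroup bundles
#'
#' Orthogroups spanning fewer than `min_proteomes` proteomes are skipped;
#' the rest are aligned (or their supplied alignment validated), their
#' gap-distance matrix and Neighbor-Joining tree built, low-cost clades
#' found, ranked and greedily selected over disjoint Gene-Centric gene
#' sets, and suggestions emitted.  A failure in one orthogroup is logged
#' and counted; the run continues.
#'
#' @param bundles named list of `orthogroup_bundle` (e.g. from
#'   [build_orthogroup_bundles()] or [generate_dataset()]).
#' @param msas optional named list of `msa` objects (or paths to aligned
#'   FASTA files) keyed by orthogroup id; orthogroups without one are
#'   aligned with `aligner`.
#' @param aligner aligner for orthogroups lacking a pre-computed alignment:
#'   a function or command template as in [align_orthogroup()], or `NULL`
#'   (such orthogroups then fail and are counted).
#' @param cost_threshold maximum clade cost (default 0.02, inclusive).
#' @param min_proteomes minimum proteomes per orthogroup and per clade
#'   (default 3).
#' @param hm_proteomes proteomes whose reviewed entries count in ranking
#'   criterion (iv) (default human and mouse).
#' @param out_dir when non-`NULL`: write `suggestions.csv`,
#'   `run_summary.json` and `candidates.tsv` there (and `trees/*.nwk` when
#'   `write_trees`); reruns on identical input are byte-identical.
#' @param write_trees also write one newick tree per analysed orthogroup.
#' @return list of class `gapclade_run` with `suggestions` (data.frame),
#'   `summary` (list, see Details), `candidates` (list per orthogroup) and
#'   `failed` (named character vector of error messages).
#'
#' @details The summary counts partition the orthogroups:
#' `skipped + no_low_cost + confirmed_groups + proposed_groups +
#' both_groups + failed = total_groups`.  A group is `confirmed` when every
#' selected clade only confirms current canonicals, `proposed` when every
#' selected clade proposes at least one change, and `both` when different
#' clades of the group do one and the other.  `clade_canonicals` counts
#' canonical sequences inside selected clades, `confirmed_canonicals` the
#' `confirm` suggestions, and `proposed_changes` the suggestions that
#' propose a different isoform (including those only flagged because the
#' current canonical is reviewed, tallied separately as `flagged_reviewed`).
#' @export
run_pipeline <- function(bundles, msas = NULL, aligner = NULL,
                         cost_threshold = 0.02, min_proteomes = 3,
                         hm_proteomes = c("HUMAN", "MOUSE"),
                         out_dir = NULL, write_trees = FALSE) {
  flt <- filter_orthogroups(bundles, min_proteomes)
  suggestions <- list()
  all_cands <- list()
  failed <- character(0)
  trees <- list()
  n_no_clade <- 0L
  group_class <- character(0)

  for (og in names(flt$kept)) {
    bundle <- flt$kept[[og]]
    res <- tryCatch({
      m <- msas[[og]]
      if (is.character(m)) m <- load_prealigned(m, bundle)
      if (is.null(m)) {
        if (is.null(aligner))
          gc_stop("no alignment available for ", og, " and no aligner set")
        m <- align_orthogroup(bundle, aligner)
      }
      gdm <- gap_distance_matrix(m)
      tree <- nj_tree(gdm)
      cands <- find_low_cost_clades(tree, gdm, bundle$members,
                                    cost_threshold = cost_threshold,
                                    min_proteomes = min_proteomes,
                                    orthogroup_id = og,
                                    hm_proteomes = hm_proteomes)
      canon_len <- bundle$members$length[bundle$members$is_canonical]
      ranked <- rank_clades(cands, canon_len)
      sel <- select_clades(ranked)
      sugg <- emit_suggestions(sel, bundle$members)
      list(tree = tree, cands = ranked, sugg = sugg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[og] <- conditionMessage(res)
      message("orthogroup ", og, " failed: ", conditionMessage(res))
      next
    }
    trees[[og]] <- res$tree
    all_cands[[og]] <- res$cands
    if (!nrow(res$sugg)) {
      n_no_clade <- n_no_clade + 1L
      next
    }
    suggestions[[og]] <- res$sugg
    per_clade <- tapply(res$sugg$action != "confirm", res$sugg$rank, any)
    group_class[og] <- if (all(per_clade)) "proposed"
      else if (!any(per_clade)) "confirmed" else "both"
  }

  sugg <- if (length(suggestions)) do.call(rbind, suggestions) else
    emit_suggestions(list(), NULL)
  rownames(sugg) <- NULL

  total_canon <- sum(vapply(bundles, function(b)
    sum(b$members$is_canonical), 0))
  summary <- list(
    total_groups = length(bundles),
    skipped = length(flt$skipped),
    failed = length(failed),
    no_low_cost = n_no_clade,
    confirmed_groups = sum(group_class == "confirmed"),
    proposed_groups = sum(group_class == "proposed"),
    both_groups = sum(group_class == "both"),
    total_canonicals = total_canon,
    clade_canonicals = sum(sugg$action == "confirm"),
    confirmed_canonicals = sum(sugg$action == "confirm"),
    proposed_changes = sum(sugg$action != "confirm"),
    flagged_reviewed = sum(sugg$action == "flag_reviewed"))

  out <- structure(list(suggestions = sugg, summary = summary,
                        candidates = all_cands, failed = failed,
                        trees = trees),
                   class = "gapclade_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_suggestion_report(sugg, file.path(out_dir, "suggestions.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_candidates_tsv(unlist(all_cands, recursive = FALSE),
                         file.path(out_dir, "candidates.tsv"))
    if (write_trees) {
      dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
      for (og in names(trees))
        write_newick(trees[[og]],
                     file.path(out_dir, "trees",
                               paste0(gsub("[^A-Za-z0-9_.-]", "_", og),
                                      ".nwk")))
    }
  }
  out
}

#' @export
print.gapclade_run <- function(x, ...) {
  s <- x$summary
  cat("gapclade run:", s$total_groups, "orthogroups |", s$skipped,
      "skipped,", s$no_low_cost, "without low-cost clades,", s$failed,
      "failed\n")
  cat("  groups:", s$confirmed_groups, "confirmed,", s$proposed_groups,
      "with proposed changes,", s$both_groups, "both\n")
  cat("  canonicals:", s$confirmed_canonicals, "confirmed,",
      s$proposed_changes, "changes proposed (", s$flagged_reviewed,
      "flagged reviewed )\n")
  invisible(x)
}

#' Run the pipeline from files on disk
#'
#' Reads proteome FASTA files, the Gene-Centric and orthogroup tables,
#' builds the bundles, and calls [run_pipeline()]; pre-computed alignments
#' are looked up in `prealigned_dir` as `<orthogroup>.afa` (with characters
#' outside `[A-Za-z0-9_.-]` replaced by `_`).
#'
#' @param fasta_paths character vector of proteome FASTA files.
#' @param orthogroup_tsv,gene_centric_tsv mapping-table paths.
#' @param prealigned_dir optional directory of aligned FASTA files.
#' @param ... passed to [run_pipeline()].
#' @return see [run_pipeline()].
#' @export
run_pipeline_files <- function(fasta_paths, orthogroup_tsv, gene_centric_tsv,
                               prealigned_dir = NULL, ...) {
  gc_tab <- read_gene_centric_table(gene_centric_tsv)
  og_tab <- read_orthogroup_table(orthogroup_tsv)
  records <- do.call(rbind, lapply(fasta_paths, read_proteome_fasta,
                                   gene_centric = gc_tab))
  class(records) <- c("seq_records", "data.frame")
  bundles <- build_orthogroup_bundles(records, og_tab)
  msas <- NULL
  if (!is.null(prealigned_dir)) {
    paths <- file.path(prealigned_dir,
                       paste0(gsub("[^A-Za-z0-9_.-]", "_", names(bundles)),
                              ".afa"))
    msas <- stats::setNames(as.list(paths), names(bundles))
    msas <- msas[file.exists(paths)]
  }
  run_pipeline(bundles, msas = msas, ...)
}
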