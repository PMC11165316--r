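# Orthogroup bundles and the multiple-sequence-alignment stage.
#
# The aligner itself is pluggable: production use shells out to an external
# program (muscle with "-maxiters 2 -diags" by default), tests use a
# deterministic stub function, and synthetic bundles carry their true
# alignment so the suite never depends on aligner behaviour.

#' Bundle the sequences gathered for one orthogroup
#'
#' @param orthogroup_id orthogroup identifier (kept verbatim, e.g.
#'   `PTHR11818:SF19`).
#' @param members a `seq_records` table; every member must carry a
#'   Gene-Centric group.
#' @return an object of class `orthogroup_bundle` with elements
#'   `orthogroup_id`, `members` and `proteome_count`.
#' @export
orthogroup_bundle <- function(orthogroup_id, members) {
  if (!all(members$has_gene_group))
    gc_stop("orthogroup ", orthogroup_id, ": member(s) without Gene-Centric ",
            "group: ",
            paste(members$accession[!members$has_gene_group], collapse = ", "))
  structure(
    list(orthogroup_id = orthogroup_id,
         members = members,
         proteome_count = length(unique(members$proteome_id))),
    class = "orthogroup_bundle")
}

#' @export
print.orthogroup_bundle <- function(x, ...) {
  cat("orthogroup", x$orthogroup_id, "-", nrow(x$members), "sequences from",
      x$proteome_count, "proteomes\n")
  invisible(x)
}

#' Gather orthogroup bundles from records and an orthogroup table
#'
#' The orthogroup table assigns canonical accessions to orthogroups; each
#' canonical's Gene-Centric group is then expanded to all of its isoform
#' accessions, across all proteomes in `records`.  Records with a
#' Gene-Centric group that reaches no orthogroup stay in `records` but are
#' never aligned.
#'
#' @param records `seq_records` for all proteomes.
#' @param orthogroup_table data.frame from [read_orthogroup_table()].
#' @return named list of `orthogroup_bundle` objects (orthogroups whose
#'   accessions match no record are dropped).
#' @export
build_orthogroup_bundles <- function(records, orthogroup_table) {
  ogs <- split(orthogroup_table$accession, orthogroup_table$orthogroup_id)
  out <- list()
  for (og in names(ogs)) {
    seed <- records[records$accession %in% ogs[[og]], , drop = FALSE]
    groups <- unique(seed$gene_group_id[seed$has_gene_group])
    if (!length(groups)) next
    members <- records[records$has_gene_group &
                         records$gene_group_id %in% groups, , drop = FALSE]
    if (!nrow(members)) next
    members <- members[order(members$proteome_id, members$accession), ,
                       drop = FALSE]
    rownames(members) <- NULL
    out[[og]] <- orthogroup_bundle(og, members)
  }
  out[order(names(out))]
}

#' Construct/validate a multiple alignment
#'
#' @param orthogroup_id orthogroup identifier.
#' @param rows named character vector of aligned strings (names are
#'   accessions), all of equal length; `-` is the gap character.  Columns
#'   that are gapped in every row are not allowed (see
#'   [strip_allgap_columns()]).
#' @return object of class `msa`: list(orthogroup_id, rows, n_cols).
#' @export
msa <- function(orthogroup_id, rows) {
  if (length(rows) < 1) gc_stop("alignment must have at least one row")
  w <- unique(nchar(rows))
  if (length(w) != 1)
    gc_stop("aligned rows have differing widths: ",
            paste(w, collapse = ", "))
  gm <- gap_matrix(rows)
  if (any(colSums(!gm) == 0))
    gc_stop("alignment contains all-gap column(s); strip them first")
  structure(list(orthogroup_id = orthogroup_id, rows = rows, n_cols = w),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa for", x$orthogroup_id, "-", length(x$rows), "rows x",
      x$n_cols, "columns\n")
  invisible(x)
}

# logical matrix: rows = sequences, TRUE where gapped
gap_matrix <- function(rows) {
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  m == "-"
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Remove columns gapped in every row
#'
#' All-gap columns can appear after subsetting an alignment; they carry no
#' signal and would inflate distance denominators.
#'
#' @param rows named character vector of aligned strings.
#' @param quiet suppress the message reporting how many columns were removed.
#' @return the rows with all-gap columns removed.
#' @export
strip_allgap_columns <- function(rows, quiet = FALSE) {
  chars <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  keep <- colSums(chars != "-") > 0
  if (all(keep)) return(rows)
  if (!quiet)
    message("stripped ", sum(!keep), " all-gap column(s)")
  out <- apply(chars[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(rows)
  out
}

#' Align an orthogroup bundle
#'
#' @param bundle an `orthogroup_bundle` with at least two members.
#' @param aligner either a function `(records) -> named character vector` of
#'   aligned rows (used by tests and for pre-computed alignments), or a
#'   command template string containing `{fasta}` and `{afa}` placeholders,
#'   e.g. the default `"muscle -maxiters 2 -diags -in {fasta} -out {afa}"`.
#' @return an `msa` object with rows in bundle order.
#' @export
align_orthogroup <- function(bundle,
                             aligner = "muscle -maxiters 2 -diags -in {fasta} -out {afa}") {
  mem <- bundle$members
  if (nrow(mem) < 2)
    gc_stop("orthogroup ", bundle$orthogroup_id,
            ": need at least 2 sequences to align")
  if (anyDuplicated(mem$accession))
    gc_stop("orthogroup ", bundle$orthogroup_id, ": duplicate accessions")
  if (is.function(aligner)) {
    rows <- aligner(mem)
  } else {
    rows <- run_external_aligner(mem, aligner)
  }
  rows <- rows[mem$accession]   # bundle order, error if any missing
  if (anyNA(rows) || anyNA(names(rows)))
    gc_stop("aligner output is missing sequence(s) for orthogroup ",
            bundle$orthogroup_id)
  bad <- ungap(rows) != mem$residues
  if (any(bad))
    gc_stop("aligner altered residues of: ",
            paste(mem$accession[bad], collapse = ", "))
  msa(bundle$orthogroup_id, strip_allgap_columns(rows, quiet = TRUE))
}

run_external_aligner <- function(members, template) {
  fa <- tempfile(fileext = ".fa")
  afa <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fa, afa)), add = TRUE)
  x <- Biostrings::AAStringSet(members$residues)
  names(x) <- members$accession
  Biostrings::writeXStringSet(x, fa)
  cmd <- gsub("{fasta}", fa, gsub("{afa}", afa, template, fixed = TRUE),
              fixed = TRUE)
  res <- suppressWarnings(system(cmd, intern = TRUE, ignore.stderr = FALSE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    gc_stop("aligner failed (exit ", status, "): ", cmd, "\n",
            paste(res, collapse = "\n"))
  if (!file.exists(afa)) gc_stop("aligner produced no output: ", cmd)
  out <- as.character(Biostrings::readAAStringSet(afa))
  names(out) <- vapply(names(out), function(h) {
    p <- parse_fasta_header(paste0(">", h))
    if (is.null(p)) h else p$accession
  }, "")
  out
}

#' Load and validate a pre-computed alignment
#'
#' @param path aligned FASTA whose ungapped rows must reproduce the bundle's
#'   residues exactly (headers may use the UniProt dialect or bare
#'   accessions).
#' @param bundle the `orthogroup_bundle` the alignment belongs to.
#' @return an `msa` object, with all-gap columns stripped (reported by a
#'   message).
#' @export
load_prealigned <- function(path, bundle) {
  raw <- as.character(Biostrings::readAAStringSet(path))
  names(raw) <- vapply(names(raw), function(h) {
    p <- parse_fasta_header(paste0(">", h))
    if (is.null(p)) gc_stop("malformed header in ", path, ": ", h)
    p$accession
  }, "")
  mem <- bundle$members
  rows <- raw[mem$accession]
  if (anyNA(rows))
    gc_stop("alignment ", path, " is missing: ",
            paste(setdiff(mem$accession, names(raw)), collapse = ", "))
  names(rows) <- mem$accession
  bad <- toupper(ungap(rows)) != mem$residues
  if (any(bad))
    gc_stop("ungapped alignment row differs from input sequence for: ",
            paste(mem$accession[bad], collapse = ", "))
  msa(bundle$orthogroup_id, strip_allgap_columns(toupper(rows)))
}

#' Filter orthogroup bundles by proteome coverage
#'
#' Orthogroups seen in fewer than `min_proteomes` distinct proteomes are set
#' aside (they cannot support a multi-proteome clade) and counted for the
#' run report.
#'
#' @param bundles list of `orthogroup_bundle`.
#' @param min_proteomes minimum number of distinct proteomes (default 3).
#' @return `list(kept = ..., skipped = ...)`; the two lists partition the
#'   input.
#' @export
filter_orthogroups <- function(bundles, min_proteomes = 3) {
  stopifnot(min_proteomes >= 1)
  counts <- vapply(bundles, `[[`, 0, "proteome_count")
  list(kept = bundles[counts >= min_proteomes],
       skipped = bundles[counts < min_proteomes])
}
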