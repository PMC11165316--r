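# Readers and writers for every external format the pipeline touches:
# UniProt-dialect proteome FASTA, mapping TSVs, aligned FASTA, newick trees,
# m8+BTOP search tables and the suggestion report CSV.

VALID_DBS <- c("sp", "tr", "sp_iso", "tr_iso")

#' Construct a sequence-record table
#'
#' The package represents protein sequences as a plain `data.frame` with one
#' row per entry and columns `accession`, `proteome_id`, `entry_name`,
#' `review_status` (`"reviewed"` or `"unreviewed"`), `is_canonical`,
#' `gene_group_id` (`NA` when unmapped), `has_gene_group`, `residues` and
#' `length`.
#'
#' @param accession,proteome_id,entry_name,review_status,is_canonical,gene_group_id,residues
#'   vectors of equal length (recycling is not performed).
#' @return a `data.frame` of class `seq_records`.
#' @export
seq_records <- function(accession, proteome_id, residues,
                        entry_name = NA_character_,
                        review_status = "unreviewed",
                        is_canonical = FALSE,
                        gene_group_id = NA_character_) {
  n <- length(accession)
  rec <- data.frame(
    accession = as.character(accession),
    proteome_id = as.character(proteome_id),
    entry_name = rep_len(as.character(entry_name), n),
    review_status = rep_len(as.character(review_status), n),
    is_canonical = rep_len(as.logical(is_canonical), n),
    gene_group_id = rep_len(as.character(gene_group_id), n),
    residues = as.character(residues),
    stringsAsFactors = FALSE
  )
  rec$has_gene_group <- !is.na(rec$gene_group_id) & nzchar(rec$gene_group_id)
  rec$length <- nchar(rec$residues)
  validate_seq_records(rec)
  class(rec) <- c("seq_records", "data.frame")
  rec
}

validate_seq_records <- function(rec) {
  if (any(rec$length < 1)) gc_stop("zero-length sequence: ",
                                   rec$accession[rec$length < 1][1])
  check_residues(rec$residues, rec$accession)
  stopifnot(all(rec$review_status %in% c("reviewed", "unreviewed")))
  key <- paste(rec$accession, rec$proteome_id)
  if (anyDuplicated(key))
    gc_stop("duplicate accession within a proteome: ",
            key[duplicated(key)][1])
  invisible(rec)
}

#' Read a Gene-Centric mapping table
#'
#' Tab-separated with header columns `gene_group_id`, `accession`,
#' `is_canonical` (logical or 0/1) and `review_status`.  A Gene-Centric group
#' collects all accessions (canonical plus isoforms) belonging to one gene.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with the four columns, one row per accession.
#' @export
read_gene_centric_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_group_id", "accession", "is_canonical", "review_status")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    gc_stop("gene-centric table ", path, " lacks column(s): ",
            paste(miss, collapse = ", "))
  tab$is_canonical <- as.logical(tab$is_canonical)
  tab[need]
}

#' Read an orthogroup-to-canonical-accession table
#'
#' Tab-separated with columns `orthogroup_id` and `accession`; orthogroup IDs
#' in the Panther family/subfamily style (`PTHR11818:SF19`) are kept verbatim.
#' Duplicate identical rows are dropped silently; an accession listed under
#' two orthogroups is kept under both, with a warning.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `orthogroup_id`, `accession`.
#' @export
read_orthogroup_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("orthogroup_id", "accession")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    gc_stop("orthogroup table ", path, " lacks column(s): ",
            paste(miss, collapse = ", "))
  tab <- unique(tab[need])
  multi <- unique(tab$accession[duplicated(tab$accession)])
  if (length(multi))
    gc_warn("accession(s) assigned to multiple orthogroups: ",
            paste(utils::head(multi, 5), collapse = ", "))
  tab
}

# split a ">..." header into (db, accession, entry_name); db NA for bare headers
parse_fasta_header <- function(header) {
  h <- sub("^>", "", header)
  h <- sub("\\s.*$", "", h)   # drop description after first whitespace
  parts <- strsplit(h, "|", fixed = TRUE)[[1]]
  if (length(parts) == 1)
    return(list(db = NA_character_, accession = parts[1],
                entry_name = NA_character_))
  if (length(parts) != 3 || !(parts[1] %in% VALID_DBS) || !nzchar(parts[2]))
    return(NULL)
  list(db = parts[1], accession = parts[2], entry_name = parts[3])
}

#' Read a proteome FASTA file in the UniProt reference-proteome dialect
#'
#' Headers are either `>db|ACC|ENTRY_NAME` with `db` one of `sp`, `tr`,
#' `sp_iso`, `tr_iso`, or a bare `>ACC`.  Review status is `reviewed` iff the
#' db tag starts with `sp`.  Canonical status and the Gene-Centric group come
#' from the mapping table, which is the source of truth; when the table
#' contradicts the header convention (an `-n` isoform accession marked
#' canonical, or vice versa) the table wins and the conflict is reported via
#' `message()`.  Records without a Gene-Centric mapping are returned with
#' `has_gene_group = FALSE`, not dropped.
#'
#' @param path FASTA file path.
#' @param gene_centric optional table from [read_gene_centric_table()].
#' @param proteome_id proteome code for the file.  When `NULL` it is derived
#'   per record from the entry name (the part after the last underscore,
#'   e.g. `CRBA4_HUMAN` -> `HUMAN`); bare headers then raise an error.
#' @return a `seq_records` table.
#' @export
read_proteome_fasta <- function(path, gene_centric = NULL, proteome_id = NULL) {
  lines <- readLines(path)
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx)) {
    if (any(nzchar(trimws(lines))))
      gc_stop("no FASTA headers found in ", path)
    return(seq_records(character(), character(), character())[0, ])
  }
  parsed <- vector("list", length(hdr_idx))
  for (k in seq_along(hdr_idx)) {
    p <- parse_fasta_header(lines[hdr_idx[k]])
    if (is.null(p))
      gc_stop("malformed FASTA header at line ", hdr_idx[k], " of ", path)
    parsed[[k]] <- p
  }
  seqs <- as.character(Biostrings::readAAStringSet(path))
  if (length(seqs) != length(hdr_idx))
    gc_stop("FASTA parse mismatch in ", path)
  acc <- vapply(parsed, `[[`, "", "accession")
  db <- vapply(parsed, `[[`, "", "db")
  entry <- vapply(parsed, `[[`, "", "entry_name")
  if (anyDuplicated(acc))
    gc_stop("duplicate accession in ", path, ": ", acc[duplicated(acc)][1])

  if (is.null(proteome_id)) {
    prot <- ifelse(grepl("_", entry), sub("^.*_", "", entry), entry)
    if (anyNA(prot))
      gc_stop("cannot derive proteome for bare header(s) in ", path,
              "; pass proteome_id=")
  } else {
    prot <- rep_len(proteome_id, length(acc))
  }

  review <- ifelse(is.na(db), "unreviewed",
                   ifelse(startsWith(db, "sp"), "reviewed", "unreviewed"))
  canon <- !is_isoform_accession(acc) & (is.na(db) | db %in% c("sp", "tr"))
  gg <- rep(NA_character_, length(acc))

  if (!is.null(gene_centric)) {
    m <- match(acc, gene_centric$accession)
    hit <- !is.na(m)
    gg[hit] <- gene_centric$gene_group_id[m[hit]]
    tab_canon <- gene_centric$is_canonical[m[hit]]
    conflict <- tab_canon != canon[hit]
    if (any(conflict))
      message("canonical flag from mapping table overrides header for: ",
              paste(utils::head(acc[hit][conflict], 5), collapse = ", "))
    canon[hit] <- tab_canon
    tab_rev <- gene_centric$review_status[m[hit]]
    use_rev <- is.na(db[hit]) & !is.na(tab_rev)
    review[hit][use_rev] <- tab_rev[use_rev]
  }

  seq_records(accession = acc, proteome_id = prot, residues = toupper(seqs),
              entry_name = entry, review_status = review,
              is_canonical = canon, gene_group_id = gg)
}

#' Write sequence records as UniProt-dialect FASTA
#'
#' Headers are reconstructed as `db|ACC|ENTRY_NAME` (db from review status and
#' isoform suffix) when an entry name is present, bare `>ACC` otherwise.
#'
#' @param records a `seq_records` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(records, path) {
  db <- ifelse(records$review_status == "reviewed", "sp", "tr")
  db <- ifelse(is_isoform_accession(records$accession) | !records$is_canonical,
               paste0(db, "_iso"), db)
  hdr <- ifelse(is.na(records$entry_name),
                records$accession,
                paste(db, records$accession, records$entry_name, sep = "|"))
  x <- Biostrings::AAStringSet(records$residues)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Read tabular similarity-search output with a BTOP column
#'
#' Expects the 12 standard m8 columns (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, E-value, bit score) plus a final BTOP alignment-encoding
#' column; lines starting with `#` are skipped.  BTOP strings are kept
#' verbatim.
#'
#' @param path path to the tab-separated file.
#' @param query_lengths,subject_lengths optional named integer vectors
#'   (accession -> sequence length) used to populate `query_len` /
#'   `subject_len`; hits without an entry get `NA`.
#' @return `data.frame` of hits in file order with columns `query_acc`,
#'   `subject_acc`, `percent_identity`, `align_len`, `mismatches`,
#'   `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`, `e_value`,
#'   `bit_score`, `btop`, `query_len`, `subject_len`.
#' @export
read_m8_btop <- function(path, query_lengths = NULL, subject_lengths = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  cols <- c("query_acc", "subject_acc", "percent_identity", "align_len",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bit_score", "btop")
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 13), cols))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 13))
      gc_stop("expected 13 tab-separated columns at line ",
              lineno[nf != 13][1], " of ", path, " (got ", nf[nf != 13][1], ")")
    out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
    names(out) <- cols
  }
  num <- c("percent_identity", "e_value", "bit_score")
  int <- c("align_len", "mismatches", "gap_opens",
           "q_start", "q_end", "s_start", "s_end")
  out[num] <- lapply(out[num], as.numeric)
  out[int] <- lapply(out[int], as.integer)
  out$query_len <- if (is.null(query_lengths))
    rep(NA_integer_, nrow(out)) else
      as.integer(query_lengths[out$query_acc])
  out$subject_len <- if (is.null(subject_lengths))
    rep(NA_integer_, nrow(out)) else
      as.integer(subject_lengths[out$subject_acc])
  out
}

#' Write hits in m8+BTOP format
#' @param hits data.frame as returned by [read_m8_btop()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_m8_btop <- function(hits, path) {
  cols <- c("query_acc", "subject_acc", "percent_identity", "align_len",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bit_score", "btop")
  m <- hits[cols]
  m$percent_identity <- formatC(m$percent_identity, format = "f", digits = 2)
  m$e_value <- formatC(m$e_value, format = "g", digits = 3)
  m$bit_score <- formatC(m$bit_score, format = "f", digits = 1)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tree to a newick file
#'
#' Leaf labels are accessions; branch lengths are written with enough digits
#' that re-reading reproduces an isomorphic tree.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a newick tree file
#' @param path newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) ape::read.tree(path)

SUGGESTION_COLS <- c("orthogroup_id", "proteome_id", "gene_group_id",
                     "old_canonical", "new_canonical", "action",
                     "clade_cost", "clade_size", "rank")

#' Write the canonical-suggestion report
#'
#' One CSV row per clade member with `action` one of `confirm`,
#' `propose_change` or `flag_reviewed`, ordered by (orthogroup_id,
#' proteome_id) so repeated runs are byte-identical.
#'
#' @param suggestions data.frame from [emit_suggestions()] /
#'   [run_pipeline()]; an empty data.frame yields a header-only CSV.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_suggestion_report <- function(suggestions, path) {
  if (is.null(suggestions) || !nrow(suggestions)) {
    writeLines(paste(SUGGESTION_COLS, collapse = ","), path)
    return(invisible(path))
  }
  s <- suggestions[order(suggestions$orthogroup_id, suggestions$proteome_id),
                   SUGGESTION_COLS]
  s$clade_cost <- sprintf("%.8g", s$clade_cost)
  utils::write.csv(s, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
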