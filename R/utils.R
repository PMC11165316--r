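#' Strip the isoform suffix from a UniProt-style accession
#'
#' Isoform accessions carry a numeric `-n` suffix (`Q6DTZ8-1`); the base
#' accession identifies the database entry itself.
#'
#' @param accession character vector of accessions.
#' @return character vector with any trailing `-<digits>` removed.
#' @export
#' @examples
#' base_accession(c("P53673", "Q6DTZ8-1"))
base_accession <- function(accession) {
  sub("-[0-9]+$", "", accession)
}

#' Does an accession look like an isoform accession?
#' @param accession character vector.
#' @return logical vector, `TRUE` where the accession has a `-n` suffix.
#' @export
is_isoform_accession <- function(accession) {
  grepl("-[0-9]+$", accession)
}

# stop() with a consistent prefix; keeps call noise out of user-facing errors
gc_stop <- function(...) stop(..., call. = FALSE)

gc_warn <- function(...) warning(..., call. = FALSE)

# validate a vector of residues strings against the accepted alphabet
check_residues <- function(residues, accession = NULL) {
  bad <- !grepl(paste0("^[", paste(AA_LETTERS, collapse = ""), "]+$"), residues)
  if (any(bad)) {
    who <- if (is.null(accession)) which(bad)[1] else accession[bad][1]
    gc_stop("invalid residue characters in sequence: ", who)
  }
  invisible(TRUE)
}
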