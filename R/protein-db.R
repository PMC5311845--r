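#' Construct a protein database table
#'
#' A protein database is a data frame with one row per sequence entry and
#' columns `accession`, `sequence`, `source` and a list column
#' `transcript_ids` linking each protein to the transcripts that encode it.
#' `source` records provenance: a reference proteome entry, a protein
#' translated from a novel transcript (Cuffcompare class code `j`, potentially
#' novel isoform, or `u`, unknown intergenic transcript), or a decoy.
#'
#' @param accession character vector of unique, nonempty accessions.
#' @param sequence character vector of amino-acid sequences (20-letter
#'   alphabet, `X` permitted), same length as `accession`.
#' @param source provenance of each entry, one of `"reference"`,
#'   `"novel_isoform_j"`, `"novel_intergenic_u"`, `"decoy"`. Recycled.
#' @param transcript_ids list of character vectors (possibly empty) of
#'   transcript identifiers per entry, or `NULL` for none.
#' @return a `data.frame` of class `"protein_db"`.
#' @export
protein_db <- function(accession, sequence,
                       source = "reference", transcript_ids = NULL) {
  accession <- as.character(accession)
  sequence <- as.character(sequence)
  n <- length(accession)
  if (length(sequence) != n) stop_msg("accession and sequence lengths differ")
  if (n > 0 && any(!nzchar(accession))) stop_msg("empty accession")
  dup <- accession[duplicated(accession)]
  if (length(dup)) {
    stop_msg("duplicate accession(s): ", paste(unique(dup), collapse = ", "))
  }
  if (n > 0 && any(!nzchar(sequence))) {
    stop_msg("empty sequence for accession(s): ",
             paste(accession[!nzchar(sequence)], collapse = ", "))
  }
  source <- rep_len(as.character(source), n)
  bad <- setdiff(unique(source), db_sources())
  if (length(bad)) stop_msg("unknown source value(s): ", paste(bad, collapse = ", "))
  if (is.null(transcript_ids)) {
    transcript_ids <- rep(list(character()), n)
  }
  if (length(transcript_ids) != n) stop_msg("transcript_ids length mismatch")
  db <- data.frame(accession = accession, sequence = sequence,
                   source = source, stringsAsFactors = FALSE)
  db$transcript_ids <- lapply(transcript_ids, as.character)
  class(db) <- c("protein_db", "data.frame")
  db
}

db_sources <- function() {
  c("reference", "novel_isoform_j", "novel_intergenic_u", "decoy")
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("Protein database: %d entries (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$source)), table(x$source)),
                    collapse = ", ")))
  invisible(x)
}

#' Generate decoy entries for a protein database
#'
#' Produces one decoy per target entry, either by reversing the sequence or by
#' a seeded residue shuffle. Decoy accessions are the target accession with a
#' distinguishing prefix; `source` is set to `"decoy"`. A reversed palindromic
#' sequence is identical to its target; this is permitted and reported via a
#' message.
#'
#' @param db a [protein_db] of target entries (nonempty).
#' @param method `"reverse"` or `"shuffle"`.
#' @param seed integer seed for the shuffle method.
#' @param decoy_prefix accession prefix marking decoys. Default `"decoy_"`.
#' @return a `"protein_db"` of decoy entries, same number of rows as `db`.
#' @export
generate_decoy_entries <- function(db, method = c("reverse", "shuffle"),
                                   seed = 1L, decoy_prefix = "decoy_") {
  if (nrow(db) == 0L) stop_msg("cannot generate decoys from an empty database")
  method <- match.arg(method)
  revseq <- function(s) {
    vapply(strsplit(s, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), character(1))
  }
  seqs <- if (method == "reverse") {
    revseq(db$sequence)
  } else {
    with_seed(seed, vapply(strsplit(db$sequence, "", fixed = TRUE),
                           function(ch) paste(sample(ch), collapse = ""),
                           character(1)))
  }
  same <- seqs == db$sequence
  if (any(same)) {
    message(sum(same), " decoy sequence(s) identical to their target ",
            "(palindrome or trivial shuffle): ",
            paste(utils::head(db$accession[same], 5), collapse = ", "))
  }
  protein_db(paste0(decoy_prefix, db$accession), seqs, source = "decoy",
             transcript_ids = db$transcript_ids)
}
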