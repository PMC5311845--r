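#' Read a protein FASTA file into a protein database
#'
#' One entry per FASTA record; the header token before the first whitespace
#' becomes the accession. Provenance is inferred from configurable accession
#' prefixes (decoys first, then novel classes), defaulting to `"reference"`.
#'
#' Headers written by [write_protein_fasta] carry optional `src=` and `tx=`
#' tokens recording provenance and linked transcript ids; when present these
#' take precedence over prefix inference, so a write/read cycle preserves all
#' fields.
#'
#' @param path path to a FASTA file.
#' @param decoy_prefix accession prefix identifying decoy entries.
#' @param novel_prefixes named character vector mapping accession prefixes to
#'   the novel source classes, e.g.
#'   `c(novel_isoform_j = "novj_", novel_intergenic_u = "novu_")`.
#' @return a [protein_db].
#' @export
read_protein_fasta <- function(path, decoy_prefix = "decoy_",
                               novel_prefixes = c(novel_isoform_j = "novj_",
                                                  novel_intergenic_u = "novu_")) {
  if (!file.exists(path)) stop_msg("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  acc <- sub("\\s.*$", "", hdr)
  seqs <- as.character(aa)
  if (any(!nzchar(seqs))) {
    stop_msg("empty sequence for record(s): ",
             paste(acc[!nzchar(seqs)], collapse = ", "))
  }
  src <- rep("reference", length(acc))
  src[startsWith(acc, decoy_prefix)] <- "decoy"
  for (cls in names(novel_prefixes)) {
    src[startsWith(acc, novel_prefixes[[cls]])] <- cls
  }
  tok <- function(key) {
    m <- regexpr(paste0("\\b", key, "=\\S+"), hdr)
    out <- rep(NA_character_, length(hdr))
    out[m > 0] <- sub(paste0(key, "="), "", regmatches(hdr, m))
    out
  }
  src_tok <- tok("src")
  src[!is.na(src_tok)] <- src_tok[!is.na(src_tok)]
  tx_tok <- tok("tx")
  tx <- rep(list(character()), length(acc))
  tx[!is.na(tx_tok)] <- strsplit(tx_tok[!is.na(tx_tok)], ",", fixed = TRUE)
  protein_db(acc, seqs, source = src, transcript_ids = tx)
}

#' Write a protein database to FASTA
#'
#' Headers are `>accession src=<source> [tx=<t1,t2,...>]` so that
#' [read_protein_fasta] recovers every field.
#'
#' @param db a [protein_db].
#' @param path output path.
#' @param width line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(db, path, width = 60L) {
  aa <- Biostrings::AAStringSet(db$sequence)
  tx <- vapply(db$transcript_ids, paste, character(1), collapse = ",")
  names(aa) <- paste0(db$accession, " src=", db$source,
                      ifelse(nzchar(tx), paste0(" tx=", tx), ""))
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Read novel transcripts from a nucleotide FASTA
#'
#' Novel transcripts are assembled transcripts absent from the reference
#' annotation, labelled by Cuffcompare class codes: `j` for a potentially
#' novel isoform and `u` for an unknown intergenic transcript. Headers carry
#' the class code and optionally the strand, e.g.
#' `>TCONS_00001 class_code=j strand=+`. A missing strand is `"unknown"`.
#'
#' @param path path to a nucleotide FASTA file.
#' @return a data frame of class `"novel_transcripts"` with columns
#'   `transcript_id`, `class_code` (`"j"` or `"u"`), `sequence`
#'   (over `A,C,G,T,N`) and `strand` (`"plus"`, `"minus"`, `"unknown"`).
#' @export
read_novel_transcripts <- function(path) {
  if (!file.exists(path)) stop_msg("file not found: ", path)
  nt <- Biostrings::readDNAStringSet(path)
  hdr <- names(nt)
  id <- sub("\\s.*$", "", hdr)
  if (anyDuplicated(id)) {
    stop_msg("duplicate transcript id(s): ",
             paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    out <- rep(NA_character_, length(hdr))
    out[grepl(paste0(key, "="), hdr)] <- sub(paste0(key, "="), "", m)
    out
  }
  cc <- grab("class_code")
  if (anyNA(cc)) {
    stop_msg("missing class_code in header(s): ",
             paste(id[is.na(cc)], collapse = ", "))
  }
  bad <- setdiff(unique(cc), c("j", "u"))
  if (length(bad)) stop_msg("unsupported class code(s): ", paste(bad, collapse = ", "))
  strand <- grab("strand")
  strand <- ifelse(is.na(strand), "unknown",
                   ifelse(strand == "+", "plus",
                          ifelse(strand == "-", "minus", "unknown")))
  out <- data.frame(transcript_id = id, class_code = cc,
                    sequence = as.character(nt), strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("novel_transcripts", "data.frame")
  out
}

#' Write novel transcripts to a nucleotide FASTA
#'
#' @param novel a `"novel_transcripts"` data frame (see
#'   [read_novel_transcripts]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_novel_transcripts <- function(novel, path) {
  nt <- Biostrings::DNAStringSet(novel$sequence)
  strand_sym <- c(plus = "+", minus = "-", unknown = ".")
  names(nt) <- sprintf("%s class_code=%s strand=%s", novel$transcript_id,
                       novel$class_code, strand_sym[novel$strand])
  Biostrings::writeXStringSet(nt, path)
  invisible(path)
}
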