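#' Read a transcript quantification table
#'
#' Reads a two-column tab-separated table mapping transcript ids to FPKM
#' (Fragments Per Kilobase of transcript per Million mapped reads), the
#' transcript-abundance estimate produced by tools such as Cufflinks. A
#' header row (`transcript_id<TAB>FPKM`, case-insensitive) is optional. An
#' empty file yields an empty (valid) table.
#'
#' @param path path to the TSV file.
#' @return a named numeric vector of class `"quant_table"`: names are
#'   transcript ids, values are FPKM (all `>= 0`).
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) stop_msg("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) &&
      grepl("^transcript_id\t", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (!length(lines)) return(quant_table(character(), numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop_msg("malformed line(s) (need 2 tab-separated fields): line ",
             which(nf < 2L)[1])
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  fpkm <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(fpkm)) {
    stop_msg("non-numeric FPKM for transcript(s): ",
             paste(ids[is.na(fpkm)], collapse = ", "))
  }
  quant_table(ids, fpkm)
}

#' Construct a transcript quantification table
#'
#' @param transcript_id character vector of unique transcript ids.
#' @param fpkm numeric vector of non-negative FPKM values.
#' @return a named numeric vector of class `"quant_table"`.
#' @export
quant_table <- function(transcript_id, fpkm) {
  transcript_id <- as.character(transcript_id)
  fpkm <- as.numeric(fpkm)
  if (length(transcript_id) != length(fpkm)) stop_msg("id/fpkm length mismatch")
  if (anyDuplicated(transcript_id)) {
    stop_msg("duplicate transcript id(s): ",
             paste(unique(transcript_id[duplicated(transcript_id)]),
                   collapse = ", "))
  }
  if (any(fpkm < 0)) {
    stop_msg("negative FPKM for transcript(s): ",
             paste(transcript_id[fpkm < 0], collapse = ", "))
  }
  structure(stats::setNames(fpkm, transcript_id), class = "quant_table")
}

#' Write a transcript quantification table
#'
#' @param quant a [quant_table].
#' @param path output TSV path.
#' @param header write the `transcript_id<TAB>FPKM` header row.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path, header = TRUE) {
  lines <- sprintf("%s\t%.10g", names(quant), as.numeric(quant))
  if (header) lines <- c("transcript_id\tFPKM", lines)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("Quant table: %d transcripts, FPKM range [%g, %g]\n",
              length(x), if (length(x)) min(x) else NA,
              if (length(x)) max(x) else NA))
  invisible(x)
}
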