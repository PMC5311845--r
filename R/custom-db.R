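#' Filter reference proteins by transcript abundance
#'
#' Removes proteins whose transcripts are essentially untranscribed: an entry
#' is retained if and only if the maximum FPKM over its linked transcripts is
#' at or above the threshold (the removal rule is strict less-than). An entry
#' with no transcript ids, or whose transcripts are absent from the
#' quantification table, is treated as FPKM 0 and removed for any positive
#' threshold.
#'
#' @param db a [protein_db].
#' @param quant a [quant_table].
#' @param threshold non-negative FPKM threshold; default 0.1.
#' @return the retained subset of `db`, a `"protein_db"`.
#' @export
filter_by_fpkm <- function(db, quant, threshold = 0.1) {
  if (threshold < 0) stop_msg("threshold must be non-negative")
  if (nrow(db) == 0L) return(db)
  fpkm <- vapply(db$transcript_ids, function(tx) {
    v <- quant[names(quant) %in% tx]
    if (length(v)) max(v) else 0
  }, numeric(1))
  keep <- !(fpkm < threshold)
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_db", "data.frame")
  out
}

# All stop-free translated segments in all requested reading frames of a
# nucleotide sequence. strand "plus": 3 forward frames; "minus": 3 frames of
# the reverse complement; "unknown": all 6.
translate_frames <- function(sequence, strand,
                             genetic_code = Biostrings::GENETIC_CODE) {
  d <- Biostrings::DNAString(sequence)
  strands <- switch(strand,
                    plus = list(d),
                    minus = list(Biostrings::reverseComplement(d)),
                    unknown = list(d, Biostrings::reverseComplement(d)),
                    stop_msg("unknown strand value: ", strand))
  segs <- list()
  frame_idx <- 0L
  for (s in strands) {
    for (off in 0:2) {
      len <- (length(s) - off) %/% 3L * 3L
      if (len >= 3L) {
        aa <- as.character(Biostrings::translate(
          Biostrings::subseq(s, start = off + 1L, width = len),
          genetic.code = genetic_code, if.fuzzy.codon = "solve",
          no.init.codon = TRUE))
        pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
        starts <- c(0L, cumsum(nchar(pieces) + 1L))[seq_along(pieces)] + 1L
        for (k in seq_along(pieces)) {
          if (nzchar(pieces[k])) {
            segs[[length(segs) + 1L]] <- list(peptide = pieces[k],
                                              frame = frame_idx,
                                              start = starts[k])
          }
        }
      }
      frame_idx <- frame_idx + 1L
    }
  }
  segs
}

#' Translate a novel transcript into its longest open peptide
#'
#' Translates all reading frames of a novel transcript (3 forward frames when
#' the strand is known, 6 when unknown), splits each frame at stop codons,
#' and returns the single longest stop-free peptide across all frames; ties
#' are broken by frame index then start position, both ascending. The entry
#' `source` is set from the Cuffcompare class code (`j` -> novel isoform,
#' `u` -> intergenic). Transcripts whose longest peptide is shorter than
#' `min_length` are rejected with a recorded reason, since peptides below the
#' typical minimum tryptic length are rarely identifiable.
#'
#' @param transcript_id transcript identifier (becomes the entry accession,
#'   with `accession_prefix` prepended).
#' @param sequence nucleotide sequence over `A,C,G,T,N`, length `>= 3`.
#' @param class_code `"j"` or `"u"`.
#' @param strand `"plus"`, `"minus"` or `"unknown"`.
#' @param min_length minimum accepted peptide length (amino acids), default 7.
#' @param genetic_code codon table, default the standard code.
#' @param accession_prefix prefix for the protein accession; defaults match
#'   the class code (`"novj_"` / `"novu_"`).
#' @return a one-row [protein_db] with attributes `frame` and `start`
#'   (0-based frame index, 1-based amino-acid start within the frame), or
#'   `NULL` with attribute-free rejection: a `list(rejected = TRUE, reason =
#'   ...)` when no peptide reaches `min_length`.
#' @export
translate_novel_transcript <- function(transcript_id, sequence, class_code,
                                       strand = if (class_code == "j") "plus" else "unknown",
                                       min_length = 7L,
                                       genetic_code = Biostrings::GENETIC_CODE,
                                       accession_prefix = NULL) {
  if (!class_code %in% c("j", "u")) {
    stop_msg("class_code must be 'j' or 'u', got: ", class_code)
  }
  if (nchar(sequence) < 3L) stop_msg("sequence shorter than one codon")
  segs <- translate_frames(sequence, strand, genetic_code)
  if (!length(segs)) {
    return(list(rejected = TRUE, transcript_id = transcript_id,
                reason = "no stop-free segment in any frame"))
  }
  lens <- vapply(segs, function(s) nchar(s$peptide), integer(1))
  frames <- vapply(segs, `[[`, integer(1), "frame")
  starts <- vapply(segs, `[[`, integer(1), "start")
  best <- order(-lens, frames, starts)[1]
  if (lens[best] < min_length) {
    return(list(rejected = TRUE, transcript_id = transcript_id,
                reason = sprintf("longest peptide (%d aa) below minimum %d aa",
                                 lens[best], min_length)))
  }
  src <- if (class_code == "j") "novel_isoform_j" else "novel_intergenic_u"
  if (is.null(accession_prefix)) {
    accession_prefix <- if (class_code == "j") "novj_" else "novu_"
  }
  entry <- protein_db(paste0(accession_prefix, transcript_id),
                      segs[[best]]$peptide, source = src,
                      transcript_ids = list(transcript_id))
  attr(entry, "frame") <- frames[best]
  attr(entry, "start") <- starts[best]
  entry
}

#' Build the customized protein database
#'
#' Assembles the sample-specific search database: reference proteins whose
#' transcripts pass the FPKM threshold, plus proteins translated from novel
#' transcripts (class `j` translated in the 3 forward frames of their
#' annotated strand, class `u` in all 6 frames since intergenic transcripts
#' carry no strand annotation).
#'
#' @param reference a [protein_db] of reference entries.
#' @param novel a `"novel_transcripts"` data frame
#'   (see [read_novel_transcripts]), or `NULL`.
#' @param quant a [quant_table].
#' @param threshold FPKM threshold for [filter_by_fpkm]; default 0.1.
#' @param min_length minimum novel peptide length; default 7.
#' @return a list with elements `db` (the combined `"protein_db"`), `report`
#'   (a `"db_build_report"`: counts in/retained/added/total and the
#'   threshold) and `rejected` (data frame of rejected novel transcripts with
#'   reasons).
#' @export
build_customized_database <- function(reference, novel = NULL, quant,
                                      threshold = 0.1, min_length = 7L) {
  kept <- filter_by_fpkm(reference, quant, threshold)
  novel_entries <- list()
  rejected <- data.frame(transcript_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(novel) && nrow(novel) > 0) {
    for (i in seq_len(nrow(novel))) {
      tr <- translate_novel_transcript(novel$transcript_id[i],
                                       novel$sequence[i],
                                       novel$class_code[i],
                                       strand = novel$strand[i],
                                       min_length = min_length)
      if (is.data.frame(tr)) {
        novel_entries[[length(novel_entries) + 1L]] <- tr
      } else {
        rejected <- rbind(rejected,
                          data.frame(transcript_id = tr$transcript_id,
                                     reason = tr$reason,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (length(novel_entries)) {
    nov <- do.call(rbind, lapply(novel_entries, as.data.frame))
    clash <- intersect(nov$accession, kept$accession)
    if (length(clash)) {
      stop_msg("accession collision between reference and novel entries: ",
               paste(clash, collapse = ", "))
    }
    db <- rbind(as.data.frame(kept), nov)
  } else {
    db <- as.data.frame(kept)
  }
  rownames(db) <- NULL
  class(db) <- c("protein_db", "data.frame")
  report <- structure(list(n_reference_in = nrow(reference),
                           n_reference_retained = nrow(kept),
                           n_novel_added = length(novel_entries),
                           n_total = nrow(db),
                           fpkm_threshold = threshold),
                      class = "db_build_report")
  list(db = db, report = report, rejected = rejected)
}

#' @export
print.db_build_report <- function(x, ...) {
  cat(sprintf(paste0("Customized database build: %d reference in, ",
                     "%d retained (FPKM >= %g), %d novel added, %d total\n"),
              x$n_reference_in, x$n_reference_retained, x$fpkm_threshold,
              x$n_novel_added, x$n_total))
  invisible(x)
}
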