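#' Construct a PSM table
#'
#' A PSM (peptide-spectrum match) table holds one row per candidate match of
#' an MS/MS spectrum to a peptide: identifiers, the peptide (modified
#' sequence notation preserved verbatim), matched protein accessions, the
#' target/decoy label, and a block of numeric base features (e.g. the search
#' engine's scores) treated as an opaque named vector. Optional columns named
#' `PrecursorMz` (Thomson) and `RetentionTime` (seconds) among the features
#' are recognised by the XIC stage.
#'
#' @param spec_id character vector of unique spectrum/PSM identifiers.
#' @param label `"target"` or `"decoy"` per PSM.
#' @param scan_number integer scan numbers.
#' @param peptide character peptide strings.
#' @param proteins list of nonempty character vectors of protein accessions.
#' @param features numeric matrix or data frame of base features, one row per
#'   PSM, with unique column names; no `NA`/`NaN` allowed.
#' @param decoy_prefix accession prefix marking decoy proteins, used to check
#'   label consistency.
#' @return a `data.frame` of class `"psm_table"` with attribute
#'   `"feature_names"`.
#' @export
psm_table <- function(spec_id, label, scan_number, peptide, proteins,
                      features, decoy_prefix = "decoy_") {
  n <- length(spec_id)
  features <- as.matrix(as.data.frame(features, check.names = FALSE))
  if (n > 0 && nrow(features) != n) stop_msg("feature row count mismatch")
  if (anyDuplicated(colnames(features))) stop_msg("duplicate feature names")
  if (n > 0 && any(!is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1, ]
    stop_msg("non-finite feature value at row ", bad[1],
             ", feature '", colnames(features)[bad[2]], "'")
  }
  if (!all(label %in% c("target", "decoy"))) {
    stop_msg("label must be 'target' or 'decoy'")
  }
  if (any(lengths(proteins) == 0L)) {
    stop_msg("PSM(s) with empty protein list: ",
             paste(spec_id[lengths(proteins) == 0L], collapse = ", "))
  }
  all_decoy <- vapply(proteins, function(p) all(startsWith(p, decoy_prefix)),
                      logical(1))
  if (any(label == "target" & all_decoy) || any(label == "decoy" & !all_decoy)) {
    warning("label inconsistent with decoy accession prefix for ",
            sum((label == "target" & all_decoy) | (label == "decoy" & !all_decoy)),
            " PSM(s)", call. = FALSE)
  }
  out <- data.frame(spec_id = as.character(spec_id),
                    label = as.character(label),
                    scan_number = as.integer(scan_number),
                    peptide = as.character(peptide),
                    stringsAsFactors = FALSE)
  out$proteins <- lapply(proteins, as.character)
  fdf <- as.data.frame(features, check.names = FALSE)
  if (n == 0) fdf <- fdf[0, , drop = FALSE]
  out <- cbind(out, fdf)
  attr(out, "feature_names") <- colnames(features)
  class(out) <- c("psm_table", "data.frame")
  out
}

#' Base feature matrix of a PSM table
#' @param psms a [psm_table].
#' @return numeric matrix (PSMs x features).
#' @export
base_features <- function(psms) {
  fn <- attr(psms, "feature_names")
  as.matrix(as.data.frame(psms, check.names = FALSE)[, fn, drop = FALSE])
}

#' Remove feature columns from a PSM table
#'
#' Useful when a PIN file carries precomputed abundance columns (e.g.
#' `FPKM`, `XIC`) that should be lifted out of the base feature block and
#' handled as extras instead.
#'
#' @param psms a [psm_table].
#' @param features names of feature columns to drop (silently ignores
#'   absent names).
#' @return a [psm_table] without those feature columns.
#' @export
drop_features <- function(psms, features) {
  fn <- attr(psms, "feature_names")
  keep <- setdiff(fn, features)
  psm_table(psms$spec_id, psms$label, psms$scan_number, psms$peptide,
            psms$proteins,
            as.matrix(as.data.frame(psms, check.names = FALSE)[, keep,
                                                               drop = FALSE]))
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("PSM table: %d PSMs (%d target, %d decoy), %d base features\n",
              nrow(x), sum(x$label == "target"), sum(x$label == "decoy"),
              length(attr(x, "feature_names"))))
  invisible(x)
}

# Pull a recognised per-PSM quantity (precursor m/z, retention time) out of
# the feature block by case-insensitive name.
psm_feature_column <- function(psms, candidates) {
  fn <- attr(psms, "feature_names")
  hit <- fn[tolower(fn) %in% tolower(candidates)]
  if (!length(hit)) return(NULL)
  as.numeric(as.data.frame(psms, check.names = FALSE)[[hit[1]]])
}

#' Precursor m/z and retention time accessors
#'
#' Looks up the precursor m/z (`PrecursorMz`/`ExpMass`, Th) or retention time
#' (`RetentionTime`/`RT`, seconds) column among the base features.
#'
#' @param psms a [psm_table].
#' @return numeric vector, or `NULL` when no such column exists.
#' @export
precursor_mz <- function(psms) {
  psm_feature_column(psms, c("PrecursorMz", "ExpMass", "mz"))
}

#' @rdname precursor_mz
#' @export
retention_time <- function(psms) {
  psm_feature_column(psms, c("RetentionTime", "RT"))
}

#' Read a Percolator-input (PIN) PSM table
#'
#' PIN is Percolator's tab-delimited input dialect: a header row
#' `SpecId  Label  ScanNr  <feature columns...>  Peptide  Proteins`, with
#' `Label` 1 for target and -1 for decoy, every column between `ScanNr` and
#' `Peptide` a named real feature, and multiple proteins either continued in
#' extra tab-separated cells after `Proteins` or joined by a separator.
#'
#' @param path path to the PIN file.
#' @param proteins_sep separator splitting multiple accessions inside the
#'   `Proteins` cell (default `";"`); tab-continuation cells are always
#'   accepted too.
#' @param decoy_prefix accession prefix marking decoy proteins.
#' @return a [psm_table], preserving the file's PSM order.
#' @export
read_pin_table <- function(path, proteins_sep = ";", decoy_prefix = "decoy_") {
  if (!file.exists(path)) stop_msg("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop_msg("empty PIN file (missing header): ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("SpecId", "Label", "ScanNr", "Peptide", "Proteins")
  missing <- setdiff(need, hdr)
  if (length(missing)) {
    stop_msg("missing mandatory PIN column(s): ", paste(missing, collapse = ", "))
  }
  i_pep <- match("Peptide", hdr)
  i_prot <- match("Proteins", hdr)
  if (i_prot != length(hdr)) stop_msg("Proteins must be the last PIN column")
  i_scan <- match("ScanNr", hdr)
  feat_names <- if (i_pep - 1L >= i_scan + 1L) {
    hdr[seq(i_scan + 1L, i_pep - 1L)]
  } else character()
  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  if (n == 0L) {
    return(psm_table(character(), character(), integer(), character(),
                     list(),
                     matrix(numeric(), 0, length(feat_names),
                            dimnames = list(NULL, feat_names)),
                     decoy_prefix = decoy_prefix))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < length(hdr))) {
    stop_msg("row ", which(nf < length(hdr))[1], " has fewer columns than header")
  }
  get_col <- function(i) vapply(parts, `[[`, character(1), i)
  lab_raw <- get_col(match("Label", hdr))
  if (!all(lab_raw %in% c("1", "-1"))) {
    stop_msg("invalid Label value(s) (must be 1 or -1): row ",
             which(!lab_raw %in% c("1", "-1"))[1])
  }
  feats <- vapply(seq_along(feat_names), function(j) {
    v <- suppressWarnings(as.numeric(get_col(match(feat_names[j], hdr))))
    v
  }, numeric(n))
  feats <- matrix(feats, nrow = n, dimnames = list(NULL, feat_names))
  if (any(!is.finite(feats))) {
    bad <- which(!is.finite(feats), arr.ind = TRUE)[1, ]
    stop_msg("non-numeric or NaN feature at row ", bad[1],
             ", column '", feat_names[bad[2]], "'")
  }
  prots <- lapply(parts, function(p) {
    cells <- p[i_prot:length(p)]  # tab-continuation cells
    unlist(strsplit(cells, proteins_sep, fixed = TRUE), use.names = FALSE)
  })
  psm_table(spec_id = get_col(match("SpecId", hdr)),
            label = ifelse(lab_raw == "1", "target", "decoy"),
            scan_number = as.integer(get_col(match("ScanNr", hdr))),
            peptide = get_col(i_pep),
            proteins = prots,
            features = feats,
            decoy_prefix = decoy_prefix)
}

#' Write a PSM table as a PIN file
#'
#' Columns are written in the deterministic order: base features in their
#' table order, then any extra feature columns in the order given. Multiple
#' proteins are joined by `proteins_sep` in the final cell.
#'
#' @param psms a [psm_table].
#' @param path output path.
#' @param extra_features optional named list/data frame of extra numeric
#'   columns (e.g. FPKM, XIC), each aligned one value per PSM.
#' @param proteins_sep separator used to join multiple accessions.
#' @return `path`, invisibly.
#' @export
write_pin_table <- function(psms, path, extra_features = NULL,
                            proteins_sep = ";") {
  fmat <- base_features(psms)
  if (!is.null(extra_features)) {
    extra_features <- as.data.frame(extra_features, check.names = FALSE)
    if (nrow(psms) > 0 && nrow(extra_features) != nrow(psms)) {
      stop_msg("extra feature column length (", nrow(extra_features),
               ") does not match PSM count (", nrow(psms), ")")
    }
    if (any(colnames(extra_features) %in% colnames(fmat))) {
      stop_msg("extra feature name collides with a base feature")
    }
    fmat <- cbind(fmat, as.matrix(extra_features))
  }
  hdr <- paste(c("SpecId", "Label", "ScanNr", colnames(fmat),
                 "Peptide", "Proteins"), collapse = "\t")
  if (nrow(psms) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  featxt <- apply(fmat, 1, function(r) paste(sprintf("%.10g", r), collapse = "\t"))
  rows <- paste(psms$spec_id,
                ifelse(psms$label == "target", "1", "-1"),
                psms$scan_number, featxt, psms$peptide,
                vapply(psms$proteins, paste, character(1),
                       collapse = proteins_sep),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
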