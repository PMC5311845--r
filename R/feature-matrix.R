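#' Construct a feature matrix for rescoring
#'
#' The aligned PSM x feature table fed to the semi-supervised rescorer: per
#' row one PSM (id, target/decoy label, peptide, matched proteins) and a
#' rectangular block of real-valued features with unique names and no
#' missing values.
#'
#' @param psm_ids character vector of PSM identifiers.
#' @param labels `"target"`/`"decoy"` per PSM.
#' @param values numeric matrix (PSMs x features) with unique column names.
#' @param peptides character vector of peptide strings.
#' @param proteins list of character vectors of protein accessions.
#' @return an object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(psm_ids, labels, values, peptides, proteins) {
  values <- as.matrix(values)
  n <- length(psm_ids)
  if (nrow(values) != n || length(labels) != n || length(peptides) != n ||
      length(proteins) != n) {
    stop_msg("row count mismatch between ids/labels/peptides/proteins/values")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop_msg("feature names must be present and unique")
  }
  if (n > 0 && any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_msg("non-finite value at row ", bad[1], " (", psm_ids[bad[1]],
             "), feature '", colnames(values)[bad[2]], "'")
  }
  if (!all(labels %in% c("target", "decoy"))) {
    stop_msg("labels must be 'target' or 'decoy'")
  }
  structure(list(psm_ids = as.character(psm_ids),
                 labels = as.character(labels),
                 feature_names = colnames(values),
                 values = values,
                 peptides = as.character(peptides),
                 proteins = lapply(proteins, as.character)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d PSMs (%d target, %d decoy) x %d features\n",
              length(x$psm_ids), sum(x$labels == "target"),
              sum(x$labels == "decoy"), length(x$feature_names)))
  cat("  features:", paste(utils::head(x$feature_names, 10), collapse = ", "),
      if (length(x$feature_names) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Row subset preserving alignment of all parallel fields.
subset_feature_matrix <- function(x, idx) {
  feature_matrix(x$psm_ids[idx], x$labels[idx],
                 x$values[idx, , drop = FALSE],
                 x$peptides[idx], x$proteins[idx])
}
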