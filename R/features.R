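#' Assign transcript-abundance (FPKM) features to PSMs
#'
#' Implements the transcript-abundance assignment rule for rescoring. A
#' target PSM receives the largest FPKM over all transcripts of all its
#' matched proteins; a matched protein without a quantified transcript
#' contributes 0 (untranscribed sequences carry zero abundance). A decoy PSM
#' receives a value drawn uniformly with replacement from the pool of values
#' assigned to the target PSMs, so the decoy feature reproduces the target
#' marginal distribution — exactly what a null feature should do under
#' target-decoy FDR estimation.
#'
#' @param psms a [psm_table].
#' @param db a [protein_db] linking protein accessions to transcript ids.
#' @param quant a [quant_table].
#' @param seed integer seed for the decoy draws.
#' @return named numeric vector of FPKM feature values, names = `spec_id`.
#'   Attribute `"rule"` records which rule produced each value
#'   (`"max_fpkm"`, `"untranscribed_zero"`, `"decoy_random"`).
#' @export
assign_fpkm_features <- function(psms, db, quant, seed = 1L) {
  n <- nrow(psms)
  tx_by_acc <- stats::setNames(db$transcript_ids, db$accession)
  is_target <- psms$label == "target"
  vals <- numeric(n)
  rule <- character(n)
  for (i in which(is_target)) {
    tx <- unique(unlist(tx_by_acc[psms$proteins[[i]]], use.names = FALSE))
    v <- quant[names(quant) %in% tx]
    if (length(v)) {
      vals[i] <- max(v)
      rule[i] <- "max_fpkm"
    } else {
      vals[i] <- 0
      rule[i] <- "untranscribed_zero"
    }
  }
  if (any(!is_target)) {
    pool <- vals[is_target]
    if (!length(pool)) {
      stop_msg("cannot assign decoy FPKM features: no target PSMs to form a pool")
    }
    vals[!is_target] <- with_seed(derive_seed(seed, "decoy_fpkm"),
                                  sample(pool, sum(!is_target), replace = TRUE))
    rule[!is_target] <- "decoy_random"
  }
  structure(stats::setNames(vals, psms$spec_id), rule = rule)
}

#' Log-transform a non-negative feature column
#'
#' Elementwise `log2(value + pseudocount)`; abundance features (FPKM, XIC
#' area) span orders of magnitude and are log-transformed before entering
#' the feature matrix.
#'
#' @param values non-negative numeric vector.
#' @param pseudocount positive offset added before the log; default 1, so 0
#'   maps to 0.
#' @param base logarithm base; default 2.
#' @return numeric vector, strictly monotone in `values`.
#' @export
log_transform <- function(values, pseudocount = 1, base = 2) {
  if (pseudocount <= 0) stop_msg("pseudocount must be positive")
  if (any(values < 0, na.rm = TRUE)) stop_msg("negative value in log_transform input")
  log(values + pseudocount, base = base)
}

#' Assemble the feature matrix for a pipeline mode
#'
#' Combines the PSM base features with the selected abundance features
#' (log-transformed), in a deterministic column order: base features in table
#' order, then extras in the order given.
#'
#' @param psms a [psm_table].
#' @param extra named list of extra numeric columns aligned to `psms` (raw,
#'   non-negative scale; e.g. `list(FPKM = ..., XIC = ...)`).
#' @param add character vector naming which extras to append (subset of
#'   `names(extra)`), or a [pipeline_mode] whose flags select them.
#' @param pseudocount,base passed to [log_transform].
#' @return a [feature_matrix].
#' @export
build_feature_matrix <- function(psms, extra = list(), add = names(extra),
                                 pseudocount = 1, base = 2) {
  if (inherits(add, "pipeline_mode")) {
    add <- c(if (add$add_f_mrna) "FPKM", if (add$add_f_peptide) "XIC")
  }
  vals <- base_features(psms)
  for (nm in add) {
    if (!nm %in% names(extra)) stop_msg("extra feature not supplied: ", nm)
    col <- as.numeric(extra[[nm]])
    if (nrow(psms) > 0 && length(col) != nrow(psms)) {
      stop_msg("extra feature '", nm, "' length mismatch")
    }
    if (nm %in% colnames(vals)) stop_msg("feature name collision: ", nm)
    vals <- cbind(vals, log_transform(col, pseudocount, base))
    colnames(vals)[ncol(vals)] <- nm
  }
  feature_matrix(psms$spec_id, psms$label, vals, psms$peptide, psms$proteins)
}
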