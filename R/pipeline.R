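#' Pipeline mode presets
#'
#' The six canonical pipeline configurations, combining database choices
#' (reference only; plus novel-transcript proteins; plus removal of
#' low-RNA-level entries) with the two abundance features:
#'
#' 1. reference database only
#' 2. reference + novel-transcript-derived proteins
#' 3. customized database (reference + novel, low-RNA entries removed)
#' 4. customized database + transcript-abundance feature (F_mRNA)
#' 5. customized database + peptide-abundance feature (F_peptide, MS1 XIC)
#' 6. customized database + both features
#'
#' @param mode_id integer 1-6.
#' @return list of class `"pipeline_mode"` with flags `use_novel_db`,
#'   `filter_low_rna`, `add_f_mrna`, `add_f_peptide`.
#' @export
pipeline_mode <- function(mode_id) {
  if (!mode_id %in% 1:6) stop_msg("mode_id must be in 1..6")
  flags <- list(
    list(FALSE, FALSE, FALSE, FALSE),
    list(TRUE,  FALSE, FALSE, FALSE),
    list(TRUE,  TRUE,  FALSE, FALSE),
    list(TRUE,  TRUE,  TRUE,  FALSE),
    list(TRUE,  TRUE,  FALSE, TRUE),
    list(TRUE,  TRUE,  TRUE,  TRUE))[[mode_id]]
  structure(list(mode_id = as.integer(mode_id),
                 use_novel_db = flags[[1]], filter_low_rna = flags[[2]],
                 add_f_mrna = flags[[3]], add_f_peptide = flags[[4]]),
            class = "pipeline_mode")
}

#' @export
print.pipeline_mode <- function(x, ...) {
  cat(sprintf("Pipeline mode %d: novel_db=%s, low_rna_filter=%s, F_mRNA=%s, F_peptide=%s\n",
              x$mode_id, x$use_novel_db, x$filter_low_rna, x$add_f_mrna,
              x$add_f_peptide))
  invisible(x)
}

#' Run the full rescoring pipeline in one mode
#'
#' Wires the stages together: optional customized-database construction,
#' abundance-feature assignment (FPKM from the quantification table, XIC
#' from the MS1 map), feature-matrix assembly, semi-supervised rescoring,
#' peptide-level rollup, and identification counting at the q-value
#' threshold. Any stage failure aborts with the stage name in the message.
#'
#' @param psms a [psm_table] (the search-engine output to rescore).
#' @param mode a [pipeline_mode] or integer 1-6.
#' @param reference a [protein_db]; required when the mode builds a
#'   database.
#' @param novel a `"novel_transcripts"` data frame; used when
#'   `use_novel_db`.
#' @param quant a [quant_table]; required when `filter_low_rna` or
#'   `add_f_mrna`.
#' @param ms1 an [ms1_map]; required when `add_f_peptide` unless `xic` is
#'   supplied.
#' @param xic optional precomputed per-PSM XIC areas (aligned to `psms`);
#'   skips extraction from `ms1`.
#' @param fpkm optional precomputed per-PSM FPKM values (aligned to
#'   `psms`); skips assignment through the database.
#' @param config a [rescore_config]; its seed drives fold assignment and
#'   decoy FPKM draws.
#' @param fpkm_threshold FPKM threshold for the low-RNA filter.
#' @param q_threshold identification threshold; default 0.01.
#' @param baseline optional baseline report (or count) against which the
#'   relative improvement `(count - baseline) / baseline` is computed.
#' @return list of class `"pipeline_report"`: mode, database build report
#'   (if built), `fit` (the `"psm_rescore"` object), `peptides` (rollup),
#'   `n_psm_ids` and `n_peptide_ids` at `q_threshold`, and
#'   `improvement_pct` when a baseline was given.
#' @export
run_pipeline <- function(psms, mode, reference = NULL, novel = NULL,
                         quant = NULL, ms1 = NULL, xic = NULL, fpkm = NULL,
                         config = rescore_config(), fpkm_threshold = 0.1,
                         q_threshold = 0.01, baseline = NULL) {
  if (!inherits(mode, "pipeline_mode")) mode <- pipeline_mode(mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_msg("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  needs_quant <- mode$filter_low_rna || (mode$add_f_mrna && is.null(fpkm))
  if (needs_quant && is.null(quant)) {
    stop_msg("mode ", mode$mode_id, " requires a quantification table (quant)")
  }
  db <- reference
  db_report <- NULL
  if (!is.null(reference)) {
    built <- stage("build_db", build_customized_database(
      reference,
      novel = if (mode$use_novel_db) novel else NULL,
      quant = quant %||% quant_table(character(), numeric()),
      threshold = if (mode$filter_low_rna) fpkm_threshold else 0))
    db <- built$db
    db_report <- built$report
  }
  extras <- list()
  if (mode$add_f_mrna) {
    if (is.null(fpkm)) {
      if (is.null(db)) {
        stop_msg("mode ", mode$mode_id,
                 " requires a protein database (reference) or precomputed fpkm")
      }
      fpkm <- stage("fpkm_features",
                    assign_fpkm_features(psms, db, quant, seed = config$seed))
    }
    extras$FPKM <- as.numeric(fpkm)
  }
  if (mode$add_f_peptide) {
    if (is.null(xic)) {
      if (is.null(ms1)) {
        stop_msg("mode ", mode$mode_id, " requires an MS1 map (ms1) or ",
                 "precomputed XIC areas (xic)")
      }
      xic <- stage("xic_features", assign_xic_features(psms, ms1))
    }
    extras$XIC <- as.numeric(xic)
  }
  mat <- stage("feature_assembly",
               build_feature_matrix(psms, extra = extras, add = mode))
  fit <- stage("rescoring", rescore_psms(mat, config))
  pep <- stage("peptide_rollup", peptide_level_rollup(fit))
  n_psm <- count_identifications(fit$psms, q_threshold)
  n_pep <- count_identifications(pep, q_threshold)
  improvement <- NULL
  if (!is.null(baseline)) {
    base_n <- if (inherits(baseline, "pipeline_report")) {
      baseline$n_peptide_ids
    } else as.numeric(baseline)
    improvement <- 100 * (n_pep - base_n) / base_n
  }
  structure(list(mode = mode, db_report = db_report, fit = fit,
                 peptides = pep, q_threshold = q_threshold,
                 n_psm_ids = n_psm, n_peptide_ids = n_pep,
                 improvement_pct = improvement),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  print(x$mode)
  if (!is.null(x$db_report)) print(x$db_report)
  cat(sprintf("Identifications at q <= %g: %d PSMs, %d peptides\n",
              x$q_threshold, x$n_psm_ids, x$n_peptide_ids))
  if (!is.null(x$improvement_pct)) {
    cat(sprintf("Improvement over baseline: %.2f%% (peptide level)\n",
                x$improvement_pct))
  }
  invisible(x)
}

#' Write a pipeline run report as JSON
#'
#' Serialises the countable outcome of a run (mode flags, database build
#' counts, identification counts, improvement) for downstream tooling.
#'
#' @param report a `"pipeline_report"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  obj <- list(mode_id = report$mode$mode_id,
              flags = report$mode[c("use_novel_db", "filter_low_rna",
                                    "add_f_mrna", "add_f_peptide")],
              db_report = if (!is.null(report$db_report)) {
                unclass(report$db_report)
              },
              q_threshold = report$q_threshold,
              n_psm_ids = report$n_psm_ids,
              n_peptide_ids = report$n_peptide_ids,
              improvement_pct = report$improvement_pct)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write scored PSM or peptide tables as TSV
#'
#' @param items `$psms` of a `"psm_rescore"` fit or a peptide rollup data
#'   frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scored_table <- function(items, path) {
  if (inherits(items, "psm_rescore")) items <- items$psms
  utils::write.table(items, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
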