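#' Shuffle the assignment of abundance features across PSMs
#'
#' Applies one random row permutation jointly to the selected feature
#' columns, breaking the PSM-to-value link while preserving each column's
#' marginal distribution (and, under the joint shuffle, the correlation
#' between the shuffled columns). All other columns are untouched.
#'
#' @param x a [feature_matrix].
#' @param feature_names names of the columns to shuffle.
#' @param seed integer seed.
#' @param joint shuffle all selected columns with the same permutation
#'   (default) or each with an independent one.
#' @return a [feature_matrix] of the same shape.
#' @export
shuffle_feature_assignment <- function(x, feature_names, seed = 1L,
                                       joint = TRUE) {
  unknown <- setdiff(feature_names, x$feature_names)
  if (length(unknown)) {
    stop_msg("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(x$psm_ids)
  vals <- x$values
  if (joint) {
    perm <- with_seed(derive_seed(seed, "shuffle"), sample.int(n))
    vals[, feature_names] <- vals[perm, feature_names, drop = FALSE]
  } else {
    for (k in seq_along(feature_names)) {
      perm <- with_seed(derive_seed(seed, paste0("shuffle", k)), sample.int(n))
      vals[, feature_names[k]] <- vals[perm, feature_names[k]]
    }
  }
  feature_matrix(x$psm_ids, x$labels, vals, x$peptides, x$proteins)
}

#' Permutation test for the contribution of abundance features
#'
#' Validates that an identification gain attributed to added features (e.g.
#' FPKM and XIC) is genuine: the feature-to-PSM assignment is shuffled
#' `n_permutations` times, the full semi-supervised rescoring (and peptide
#' rollup) is re-run on each shuffled matrix, and the empirical p-value is
#' the fraction of permutations whose identification count is at least the
#' observed (unshuffled) count. Ties count as "as extreme as observed":
#' counting only strictly greater permutations makes the p-value
#' anti-conservative whenever the permutation distribution has atoms, and a
#' rescoring pipeline that ignores an uninformative column produces exactly
#' such atoms — a null feature would then look significant.
#'
#' @param x a [feature_matrix] including the features under test.
#' @param feature_names features whose assignment is shuffled.
#' @param n_permutations number of shuffles (conventional default 100).
#' @param config a [rescore_config]; its seed also drives the shuffles.
#' @param q_threshold acceptance threshold for counting; default 0.01.
#' @param level `"peptide"` (count after [peptide_level_rollup]) or `"psm"`.
#' @param joint passed to [shuffle_feature_assignment].
#' @return an object of class `"permutation_result"`: `observed_count`,
#'   `permuted_counts` (length `n_permutations`), `p_value`,
#'   `shuffled_features`, `seed`.
#' @export
run_permutation_test <- function(x, feature_names, n_permutations = 100L,
                                 config = rescore_config(),
                                 q_threshold = 0.01,
                                 level = c("peptide", "psm"),
                                 joint = TRUE) {
  level <- match.arg(level)
  if (n_permutations < 1L) stop_msg("n_permutations must be >= 1")
  count_of <- function(mat) {
    fit <- rescore_psms(mat, config)
    items <- if (level == "peptide") peptide_level_rollup(fit) else fit$psms
    count_identifications(items, q_threshold)
  }
  observed <- count_of(x)
  permuted <- integer(n_permutations)
  for (i in seq_len(n_permutations)) {
    shuf <- shuffle_feature_assignment(x, feature_names,
                                       seed = derive_seed(config$seed,
                                                          paste0("perm", i)),
                                       joint = joint)
    permuted[i] <- count_of(shuf)
  }
  structure(list(observed_count = observed,
                 permuted_counts = permuted,
                 p_value = sum(permuted >= observed) / n_permutations,
                 shuffled_features = feature_names,
                 seed = config$seed,
                 level = level,
                 q_threshold = q_threshold),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("Permutation test (%d shuffles of %s, %s level, ",
                     "q <= %g):\n  observed %d identifications; permuted ",
                     "median %g (range %d-%d); p = %g\n"),
              length(x$permuted_counts),
              paste(x$shuffled_features, collapse = "+"), x$level,
              x$q_threshold, x$observed_count,
              stats::median(x$permuted_counts), min(x$permuted_counts),
              max(x$permuted_counts), x$p_value))
  invisible(x)
}

#' Histogram of permuted identification counts
#'
#' Plots the permutation null distribution with an arrow marking the
#' observed count.
#'
#' @param x a `"permutation_result"`.
#' @param ... passed to [graphics::hist].
#' @export
plot.permutation_result <- function(x, ...) {
  h <- graphics::hist(x$permuted_counts, breaks = "FD", plot = FALSE)
  xlim <- range(c(h$breaks, x$observed_count))
  graphics::plot(h, xlim = xlim, col = "grey80",
                 xlab = "identifications under shuffled assignment",
                 main = sprintf("Permutation test, p = %g", x$p_value), ...)
  graphics::arrows(x$observed_count, max(h$counts) * 0.5, x$observed_count, 0,
                   length = 0.1, col = "firebrick", lwd = 2)
  graphics::text(x$observed_count, max(h$counts) * 0.55, "observed",
                 col = "firebrick")
  invisible(x)
}
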