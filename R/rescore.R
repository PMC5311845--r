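#' Target-decoy q-value estimation
#'
#' Ranks PSMs by score (descending, decoys before targets at equal score —
#' the conservative tie-break) and computes at each position the simple
#' target-decoy FDR estimate: number of decoys at or above the threshold
#' divided by the number of targets at or above it (pi0 = 1, no +1
#' correction by default). The q-value is the running minimum of this FDR
#' taken from the bottom of the ranking upward, capped at 1.
#'
#' @param scores numeric scores (higher is better).
#' @param labels `"target"`/`"decoy"` aligned with `scores`; at least one
#'   target required.
#' @param plus_one use the `(#decoys + 1)/#targets` corrected estimate.
#' @return numeric q-values aligned with the input (decoy entries receive
#'   the q-value at their ranking position too).
#' @export
estimate_qvalues <- function(scores, labels, plus_one = FALSE) {
  if (length(scores) != length(labels)) stop_msg("scores/labels length mismatch")
  is_t <- labels == "target"
  if (!any(is_t)) stop_msg("no target PSMs: q-values undefined")
  ord <- order(-scores, is_t)  # ties: decoy (FALSE) first
  cum_t <- cumsum(is_t[ord])
  cum_d <- cumsum(!is_t[ord])
  num <- if (plus_one) cum_d + 1 else cum_d
  fdr <- ifelse(cum_t > 0, num / cum_t, Inf)
  fdr <- pmin(fdr, 1)
  q <- rev(cummin(rev(fdr)))
  q[order(ord)]
}

#' Rescoring configuration
#'
#' @param n_folds number of cross-validation folds (default 3: the PSM set
#'   is randomly split into three subsets, with three separate classifiers
#'   each trained on two subsets and applied to the held-out one).
#' @param n_iterations semi-supervised refinement iterations per fold.
#' @param train_fdr q-value threshold defining the positive training set.
#' @param svm_cost_grid candidate soft-margin cost values, selected per
#'   iteration by a nested split of the training data.
#' @param seed integer seed governing fold assignment and nested splits.
#' @param min_psms_per_fold minimum PSMs required per fold.
#' @param plus_one use the +1-corrected FDR estimate throughout.
#' @return a list of class `"rescore_config"`.
#' @export
rescore_config <- function(n_folds = 3L, n_iterations = 10L, train_fdr = 0.01,
                           svm_cost_grid = c(0.1, 1, 10), seed = 1L,
                           min_psms_per_fold = 50L, plus_one = FALSE) {
  if (n_folds < 2L) stop_msg("n_folds must be >= 2")
  if (train_fdr <= 0 || train_fdr >= 1) stop_msg("train_fdr must be in (0,1)")
  structure(list(n_folds = as.integer(n_folds),
                 n_iterations = as.integer(n_iterations),
                 train_fdr = train_fdr,
                 svm_cost_grid = svm_cost_grid,
                 seed = as.integer(seed),
                 min_psms_per_fold = as.integer(min_psms_per_fold),
                 plus_one = plus_one),
            class = "rescore_config")
}

# Count targets at q <= alpha for a candidate score vector.
n_accepted <- function(scores, labels, alpha, plus_one = FALSE) {
  if (!any(labels == "target")) return(0L)
  q <- estimate_qvalues(scores, labels, plus_one)
  sum(labels == "target" & q <= alpha)
}

# Best single-feature direction: the (feature, sign) pair maximizing targets
# at q <= train_fdr. Returns list(j, sign, n_accepted).
initial_direction <- function(x, labels, train_fdr, plus_one = FALSE) {
  best <- list(j = 1L, sign = 1, n = -1L)
  for (j in seq_len(ncol(x))) {
    for (s in c(1, -1)) {
      n <- n_accepted(s * x[, j], labels, train_fdr, plus_one)
      if (n > best$n) best <- list(j = j, sign = s, n = n)
    }
  }
  best
}

# Semi-supervised training on one fold's training split. x is already
# standardized. Returns list(w, b, fallback, init).
train_one_fold <- function(x, labels, config, seed) {
  d <- ncol(x)
  init <- initial_direction(x, labels, config$train_fdr, config$plus_one)
  w_init <- rep(0, d); w_init[init$j] <- init$sign
  scores <- drop(x %*% w_init)
  if (n_accepted(scores, labels, config$train_fdr, config$plus_one) == 0L) {
    warning("fold has no positive PSMs at train_fdr after initialization; ",
            "falling back to best single-feature direction", call. = FALSE)
    return(list(init_w = w_init, init_n = 0L, svm_w = w_init, svm_b = 0,
                svm_n = -1L, svm_iter = 0L, prefer_svm = FALSE,
                fallback = TRUE, init = init))
  }
  is_t <- labels == "target"
  neg_idx <- which(!is_t)
  half <- with_seed(derive_seed(seed, "nested_split"),
                    sample(c(TRUE, FALSE), nrow(x), replace = TRUE))
  # validation metric for a candidate scorer: accepted targets on the
  # held-out half, summed over both half-split directions. Counting is done
  # at a validation FDR of 5 * train_fdr: the count at train_fdr itself is
  # an extreme order statistic (the cutoff is set by ~1 decoy) whose noise
  # would routinely favour the overfitting cost.
  val_fdr <- min(5 * config$train_fdr, 0.5)
  val_count <- function(score_fun) {
    nn <- 0L
    for (h in list(half, !half)) {
      s2 <- score_fun(h)
      if (is.null(s2)) return(-1L)
      nn <- nn + n_accepted(s2, labels[!h], val_fdr, config$plus_one)
    }
    nn
  }
  fit_on <- function(pos, neg, cost, w0, b0) {
    idx <- c(pos, neg)
    y <- c(rep(1, length(pos)), rep(-1, length(neg)))
    # inverse-class-size weights, each class summing to 1: the data term
    # is then O(cost), so the cost grid spans genuine under- to over-fit
    # regardless of how many positives the current iteration accepts
    wts <- c(rep(1 / length(pos), length(pos)),
             rep(1 / length(neg), length(neg)))
    fit_linear_svm(x[idx, , drop = FALSE], y, cost = cost, weights = wts,
                   w0 = w0, b0 = b0)
  }
  # candidate 0 is the initial single-feature direction; the best-validated
  # fitted iterate is the challenger (early stopping by nested validation:
  # semi-supervised refinement at small positive-set sizes can wander, so
  # the iterate that validates best, earliest on ties, represents the SVM)
  init_n <- val_count(function(h) drop(x[!h, , drop = FALSE] %*% w_init))
  svm <- list(w = w_init, b = 0, n = -1L, iter = 0L)
  w <- w_init; b <- 0
  for (it in seq_len(config$n_iterations)) {
    q <- estimate_qvalues(scores, labels, config$plus_one)
    pos_idx <- which(is_t & q <= config$train_fdr)
    if (!length(pos_idx)) break  # keep previous classifier
    cost <- config$svm_cost_grid[1]
    best_cost_n <- -1L
    for (cc in config$svm_cost_grid) {
      nn <- val_count(function(h) {
        p1 <- pos_idx[h[pos_idx]]; n1 <- neg_idx[h[neg_idx]]
        if (!length(p1) || !length(n1)) return(NULL)
        f <- fit_on(p1, n1, cc, w, b)
        drop(x[!h, , drop = FALSE] %*% f$w) + f$b
      })
      if (nn > best_cost_n) { best_cost_n <- nn; cost <- cc }
    }
    f <- fit_on(pos_idx, neg_idx, cost, w, b)
    w <- f$w; b <- f$b
    scores <- drop(x %*% w) + b
    if (best_cost_n > svm$n) svm <- list(w = w, b = b, n = best_cost_n, iter = it)
  }
  # prefer_svm: one-standard-error rule — the fitted classifier must beat
  # the single-feature direction by more than the Poisson noise of the
  # validation count to be preferred. The caller harmonizes the choice
  # across folds so that the pooled ranking never mixes scorer classes.
  list(init_w = w_init, init_n = init_n,
       svm_w = svm$w, svm_b = svm$b, svm_n = svm$n, svm_iter = svm$iter,
       prefer_svm = svm$n > init_n + sqrt(max(init_n, 1)),
       fallback = FALSE, init = init)
}

#' Semi-supervised rescoring of PSMs
#'
#' The central learner: a Percolator-style semi-supervised linear SVM under
#' cross-validation. The PSM set is randomly split into `n_folds` subsets by
#' seeded assignment; for each fold a classifier is trained on the other
#' folds and applied to the held-out fold, so no PSM is ever scored by a
#' classifier that saw it in training. Within each training split, the
#' starting score is the single best-discriminating feature (either sign);
#' each refinement iteration takes as positives the training targets at
#' `q <= train_fdr` under the current scores and as negatives all training
#' decoys, selects the soft-margin cost from `svm_cost_grid` on a nested
#' split, and refits a weighted linear L2-SVM on standardized features.
#' Held-out scores are normalized affinely per fold (decoy median to 0, the
#' score at the `train_fdr` acceptance threshold to 1) before pooling, and
#' final q-values are computed on the pooled set with [estimate_qvalues].
#'
#' @param x a [feature_matrix] containing both targets and decoys.
#' @param config a [rescore_config].
#' @return an object of class `"psm_rescore"`: list with `psms` (data frame
#'   of spec_id, peptide, label, score, q_value, fold), `proteins`,
#'   `models` (per-fold weights, intercepts, standardization parameters,
#'   initial directions), `feature_names`, `config`.
#' @seealso [peptide_level_rollup], [count_identifications]
#' @export
rescore_psms <- function(x, config = rescore_config()) {
  stopifnot(inherits(x, "feature_matrix"))
  n <- length(x$psm_ids)
  if (length(unique(x$labels)) < 2L) {
    stop_msg("feature matrix must contain both target and decoy PSMs")
  }
  K <- config$n_folds
  if (n %/% K < config$min_psms_per_fold) {
    stop_msg("too few PSMs per fold: ", n %/% K, " < ", config$min_psms_per_fold)
  }
  fold <- with_seed(derive_seed(config$seed, "fold_assignment"),
                    sample(rep_len(seq_len(K), n)))
  scores <- numeric(n)
  models <- vector("list", K)
  for (k in seq_len(K)) {
    tr <- fold != k
    mu <- colMeans(x$values[tr, , drop = FALSE])
    sd_ <- apply(x$values[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
    m <- train_one_fold(sweep(sweep(x$values[tr, , drop = FALSE], 2, mu),
                              2, sd_, "/"),
                        x$labels[tr], config,
                        derive_seed(config$seed, paste0("fold", k)))
    m$mu <- mu; m$sd <- sd_
    models[[k]] <- m
  }
  # harmonize the scorer class across folds: pooled q-values are only
  # calibrated when every fold contributes a comparably-behaved score, so
  # the per-fold preference (fitted SVM vs initial single-feature
  # direction, decided by the one-SE rule) is settled by majority vote
  use_svm <- sum(vapply(models, `[[`, logical(1), "prefer_svm")) * 2L > K
  for (k in seq_len(K)) {
    tr <- fold != k
    m <- models[[k]]
    mu <- m$mu; sd_ <- m$sd
    if (use_svm && !m$fallback) {
      m$w <- m$svm_w; m$b <- m$svm_b
    } else {
      m$w <- m$init_w; m$b <- 0
    }
    xs_tr <- sweep(sweep(x$values[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
    # affine per-fold normalization: decoy median -> 0 and the score at the
    # train_fdr acceptance threshold -> 1, estimated on the held-out fold
    # itself; when the held-out fold accepts no targets at train_fdr the
    # threshold is taken from the training split under the same classifier
    # (a stable surrogate), so no fold ever degenerates to an arbitrary
    # scale that would distort the pooled ranking
    xs_te <- sweep(sweep(x$values[!tr, , drop = FALSE], 2, mu), 2, sd_, "/")
    raw <- drop(xs_te %*% m$w) + m$b
    lab_te <- x$labels[!tr]
    med <- stats::median(raw[lab_te == "decoy"])
    if (!is.finite(med)) med <- stats::median(raw)
    q_te <- estimate_qvalues(raw, lab_te, config$plus_one)
    acc <- raw[lab_te == "target" & q_te <= config$train_fdr]
    scale <- if (length(acc)) min(acc) - med else NA_real_
    if (!is.finite(scale) || scale <= 0) {
      raw_tr <- drop(xs_tr %*% m$w) + m$b
      lab_tr <- x$labels[tr]
      med_tr <- stats::median(raw_tr[lab_tr == "decoy"])
      q_tr <- estimate_qvalues(raw_tr, lab_tr, config$plus_one)
      acc_tr <- raw_tr[lab_tr == "target" & q_tr <= config$train_fdr]
      scale <- if (length(acc_tr)) min(acc_tr) - med_tr else NA_real_
      if (!is.finite(scale) || scale <= 0) {
        scale <- stats::sd(raw)
        if (!is.finite(scale) || scale == 0) scale <- 1
      }
    }
    scores[!tr] <- (raw - med) / scale
    m$mu <- mu; m$sd <- sd_; m$norm <- c(center = med, scale = scale)
    models[[k]] <- m
  }
  q <- estimate_qvalues(scores, x$labels, config$plus_one)
  out <- list(psms = data.frame(spec_id = x$psm_ids, peptide = x$peptides,
                                label = x$labels, score = scores, q_value = q,
                                fold = fold, stringsAsFactors = FALSE),
              proteins = x$proteins,
              models = models,
              feature_names = x$feature_names,
              config = config,
              call = match.call())
  class(out) <- "psm_rescore"
  out
}

#' @export
print.psm_rescore <- function(x, ...) {
  cat("Semi-supervised PSM rescoring\n")
  cat(sprintf("  %d PSMs (%d target, %d decoy), %d features, %d folds\n",
              nrow(x$psms), sum(x$psms$label == "target"),
              sum(x$psms$label == "decoy"), length(x$feature_names),
              x$config$n_folds))
  cat(sprintf("  targets at q <= 0.01: %d (PSM level)\n",
              count_identifications(x$psms, 0.01)))
  invisible(x)
}

#' @export
summary.psm_rescore <- function(object, q_thresholds = c(0.01, 0.05), ...) {
  pep <- peptide_level_rollup(object)
  res <- data.frame(q_threshold = q_thresholds,
                    psm_ids = vapply(q_thresholds, function(a)
                      count_identifications(object$psms, a), integer(1)),
                    peptide_ids = vapply(q_thresholds, function(a)
                      count_identifications(pep, a), integer(1)))
  fb <- vapply(object$models, `[[`, logical(1), "fallback")
  out <- list(counts = res, n_folds = object$config$n_folds,
              fallback_folds = which(fb),
              weights = coef(object))
  class(out) <- "summary.psm_rescore"
  out
}

#' @export
print.summary.psm_rescore <- function(x, ...) {
  cat("Identifications (targets at q-value threshold):\n")
  print(x$counts, row.names = FALSE)
  if (length(x$fallback_folds)) {
    cat("Folds that fell back to single-feature scoring:",
        paste(x$fallback_folds, collapse = ", "), "\n")
  }
  cat("\nMean standardized feature weights across folds:\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Feature weights of a rescoring model
#'
#' Per-fold classifiers operate on standardized features, so their weights
#' are comparable across features; `coef` returns the fold-average weight
#' per feature (the feature-importance reading) plus the mean intercept.
#'
#' @param object a `"psm_rescore"` object.
#' @param ... unused.
#' @return named numeric vector of mean standardized weights.
#' @export
coef.psm_rescore <- function(object, ...) {
  W <- t(vapply(object$models, function(m) c(m$w, m$b),
                numeric(length(object$feature_names) + 1L)))
  colnames(W) <- c(object$feature_names, "(Intercept)")
  colMeans(W)
}

#' Score new PSMs with a fitted rescoring model
#'
#' Applies each fold's standardization, classifier and affine normalization
#' to the new feature matrix and averages the fold scores. Useful for
#' scoring PSMs that were not part of training; q-values are not returned
#' (they are only defined within a ranked target-decoy population).
#'
#' @param object a `"psm_rescore"` object.
#' @param newdata a [feature_matrix] with the same features as training.
#' @param ... unused.
#' @return numeric vector of scores, one per row of `newdata`.
#' @export
predict.psm_rescore <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "feature_matrix"))
  if (!identical(newdata$feature_names, object$feature_names)) {
    stop_msg("newdata features do not match the fitted model")
  }
  per_fold <- vapply(object$models, function(m) {
    xs <- sweep(sweep(newdata$values, 2, m$mu), 2, m$sd, "/")
    (drop(xs %*% m$w) + m$b - m$norm["center"]) / m$norm["scale"]
  }, numeric(length(newdata$psm_ids)))
  rowMeans(matrix(per_fold, ncol = length(object$models)))
}

#' Score distribution plot for a rescoring result
#'
#' Overlaid target and decoy score histograms — the standard diagnostic for
#' a target-decoy rescoring run.
#'
#' @param x a `"psm_rescore"` object.
#' @param breaks histogram breaks.
#' @param ... passed to [graphics::hist].
#' @export
plot.psm_rescore <- function(x, breaks = 50, ...) {
  s <- x$psms$score
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  ht <- graphics::hist(s[x$psms$label == "target"], breaks = h$breaks, plot = FALSE)
  hd <- graphics::hist(s[x$psms$label == "decoy"], breaks = h$breaks, plot = FALSE)
  ylim <- c(0, max(ht$counts, hd$counts))
  graphics::plot(ht, col = grDevices::adjustcolor("steelblue", 0.6),
                 ylim = ylim, xlab = "normalized score",
                 main = "Target vs decoy score distribution", ...)
  graphics::plot(hd, col = grDevices::adjustcolor("firebrick", 0.6), add = TRUE)
  graphics::legend("topright", fill = c("steelblue", "firebrick"),
                   legend = c("target", "decoy"), bty = "n")
  invisible(x)
}

#' Roll PSMs up to peptide level
#'
#' Groups scored PSMs by exact peptide string (modified notation preserved;
#' a sequence observed as both target and decoy forms two distinct groups),
#' keeps the best-scoring PSM per peptide, and recomputes q-values on the
#' peptide list.
#'
#' @param psms a `"psm_rescore"` object or its `$psms` data frame (columns
#'   `spec_id`, `peptide`, `label`, `score`).
#' @param plus_one use the +1-corrected FDR estimate.
#' @return data frame with one row per (peptide, label): best `spec_id`,
#'   `score`, recomputed `q_value`.
#' @export
peptide_level_rollup <- function(psms, plus_one = FALSE) {
  if (inherits(psms, "psm_rescore")) {
    plus_one <- psms$config$plus_one
    psms <- psms$psms
  }
  if (!nrow(psms)) {
    return(data.frame(peptide = character(), label = character(),
                      spec_id = character(), score = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(psms$label, psms$peptide, sep = "\r")
  best <- vapply(split(seq_len(nrow(psms)), key),
                 function(i) i[which.max(psms$score[i])], integer(1))
  out <- psms[best, c("peptide", "label", "spec_id", "score")]
  rownames(out) <- NULL
  out$q_value <- estimate_qvalues(out$score, out$label, plus_one)
  out
}

#' Count identifications at a q-value threshold
#'
#' @param items data frame with `label` and `q_value` columns (PSM- or
#'   peptide-level), or a `"psm_rescore"` object (PSM level).
#' @param q_threshold acceptance threshold in (0,1); default 0.01 (1% FDR).
#' @return integer count of target items with `q_value <= q_threshold`.
#' @export
count_identifications <- function(items, q_threshold = 0.01) {
  if (inherits(items, "psm_rescore")) items <- items$psms
  if (q_threshold <= 0 || q_threshold >= 1) {
    stop_msg("q_threshold must be in (0,1)")
  }
  if (!nrow(items)) return(0L)
  sum(items$label == "target" & items$q_value <= q_threshold)
}
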