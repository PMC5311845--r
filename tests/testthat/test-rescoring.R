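sim_matrix <- function(n_t = 400, n_d = 400, auc = 0.9, seed = 1,
                       n_noise = 2) {
  set.seed(seed)
  n <- n_t + n_d
  labels <- c(rep("target", n_t), rep("decoy", n_d))
  correct <- c(runif(n_t) < 0.5, rep(FALSE, n_d))
  shift <- sqrt(2) * qnorm(auc)
  vals <- cbind(score = rnorm(n) + shift * correct,
                matrix(rnorm(n * n_noise), n,
                       dimnames = list(NULL, paste0("z", seq_len(n_noise)))))
  m <- feature_matrix(sprintf("s%d", 1:n), labels, vals,
                      sprintf("P%d", 1:n),
                      ifelse(labels == "decoy", "decoy_p", "p"))
  attr(m, "correct") <- correct
  m
}

test_that("q-value estimation reproduces the worked target-decoy example", {
  scores <- c(10, 8, 6, 4, 7, 3)
  labels <- c(rep("target", 4), rep("decoy", 2))
  q <- estimate_qvalues(scores, labels)
  expect_equal(q[1:4], c(0, 0, 0.25, 0.25))

  # no decoys: every target q is 0
  expect_equal(estimate_qvalues(c(5, 1), c("target", "target")), c(0, 0))

  # every decoy above every target, as many decoys as targets: all q = 1
  q2 <- estimate_qvalues(c(1, 2, 9, 10), c("target", "target", "decoy", "decoy"))
  expect_equal(q2[1:2], c(1, 1))

  expect_error(estimate_qvalues(1:3, rep("decoy", 3)), "target")
})

test_that("q-values agree exactly with the brute-force oracle", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(2:50, 1)
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # coarse rounding: ties
    labels <- sample(c("target", "decoy"), n, replace = TRUE)
    if (!any(labels == "target")) labels[1] <- "target"
    for (p1 in c(FALSE, TRUE)) {
      expect_equal(estimate_qvalues(scores, labels, plus_one = p1),
                   oracle_qvalues(scores, labels, plus_one = p1),
                   info = paste("case", i, "plus_one", p1))
    }
  }
})

test_that("q-values are monotone non-increasing in score among targets", {
  set.seed(8)
  for (i in 1:20) {
    n <- 200
    scores <- rnorm(n)
    labels <- sample(c("target", "decoy"), n, replace = TRUE, prob = c(.6, .4))
    if (!any(labels == "target")) labels[1] <- "target"
    q <- estimate_qvalues(scores, labels)
    t_idx <- labels == "target"
    ord <- order(-scores[t_idx])
    expect_true(all(diff(q[t_idx][ord]) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("rescoring is bit-identical across runs with the same seed", {
  m <- sim_matrix(seed = 5)
  cfg <- rescore_config(seed = 5)
  f1 <- rescore_psms(m, cfg)
  f2 <- rescore_psms(m, cfg)
  expect_identical(f1$psms, f2$psms)
  expect_identical(coef(f1), coef(f2))
})

test_that("every PSM is scored by a classifier not trained on its fold", {
  m <- sim_matrix(seed = 2)
  f <- rescore_psms(m, rescore_config(seed = 2))
  expect_setequal(unique(f$psms$fold), 1:3)
  # recomputing each PSM's score from its own fold's stored model matches
  # the pooled output exactly
  for (k in 1:3) {
    mod <- f$models[[k]]
    idx <- f$psms$fold == k
    xs <- sweep(sweep(m$values[idx, , drop = FALSE], 2, mod$mu), 2, mod$sd, "/")
    raw <- drop(xs %*% mod$w) + mod$b
    expect_equal((raw - mod$norm[["center"]]) / mod$norm[["scale"]],
                 f$psms$score[idx], tolerance = 1e-12)
  }
})

test_that("the learner at least matches a perfectly separating feature", {
  # feature 1 separates a correct-target subpopulation cleanly from decoys
  set.seed(33)
  n_t <- 400; n_d <- 400; n <- n_t + n_d
  labels <- c(rep("target", n_t), rep("decoy", n_d))
  correct <- c(rep(TRUE, 200), rep(FALSE, n_t - 200), rep(FALSE, n_d))
  vals <- cbind(score = rnorm(n, ifelse(correct, 8, 0), 1),
                z = rnorm(n))
  m <- feature_matrix(sprintf("s%d", 1:n), labels, vals, sprintf("P%d", 1:n),
                      ifelse(labels == "decoy", "decoy_p", "p"))
  baseline <- sum(labels == "target" &
                    estimate_qvalues(vals[, "score"], labels) <= 0.01)
  fit <- rescore_psms(m, rescore_config(seed = 33))
  expect_gte(count_identifications(fit$psms, 0.01), baseline)
  expect_gte(baseline, 190)  # the subpopulation really is recovered
})

test_that("a pure-null feature matrix yields essentially no identifications", {
  counts <- vapply(1:8, function(s) {
    set.seed(s)
    n <- 2000
    labels <- rep(c("target", "decoy"), each = n / 2)
    vals <- matrix(rnorm(n * 3), n,
                   dimnames = list(NULL, c("a", "b", "c")))
    m <- feature_matrix(sprintf("s%d", 1:n), labels, vals, sprintf("P%d", 1:n),
                        ifelse(labels == "decoy", "decoy_p", "p"))
    fit <- rescore_psms(m, rescore_config(seed = s))
    count_identifications(fit$psms, 0.01)
  }, integer(1))
  # FDR control on a null set: accepting anything would require 100 targets
  # above the first decoy, which a null ranking essentially never produces
  expect_equal(median(counts), 0)
  expect_lt(mean(counts), 5)
})

test_that("the in-package linear SVM agrees with an independent solver", {
  skip_if_not_installed("e1071")
  set.seed(99)
  n <- 300
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- ifelse(x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.4) > 0, 1, -1)
  ours <- psmrescore:::fit_linear_svm(x, y, cost = 1)
  ref <- e1071::svm(x, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  w_ref <- drop(t(ref$coefs) %*% ref$SV)
  if (ref$labels[1] == -1) w_ref <- -w_ref
  cosine <- sum(ours$w * w_ref) / sqrt(sum(ours$w^2) * sum(w_ref^2))
  expect_gt(cosine, 0.98)
})

test_that("peptide rollup keeps the best PSM per peptide and recomputes q", {
  psms <- data.frame(
    spec_id = c("a", "b", "c", "d", "e"),
    peptide = c("PEPK", "PEPK", "OTHERK", "SHARED", "SHARED"),
    label = c("target", "target", "target", "target", "decoy"),
    score = c(5, 3, 4, 2, 1), stringsAsFactors = FALSE)
  pep <- peptide_level_rollup(psms)
  expect_equal(nrow(pep), 4L)  # PEPK collapsed; SHARED split by label
  expect_equal(pep$spec_id[pep$peptide == "PEPK"], "a")
  expect_equal(pep$score[pep$peptide == "PEPK"], 5)
  expect_setequal(pep$label[pep$peptide == "SHARED"], c("target", "decoy"))
  expect_equal(pep$q_value,
               estimate_qvalues(pep$score, pep$label))

  # all-distinct peptides: identity modulo recomputed q
  distinct <- psms[c(1, 3), ]
  pd <- peptide_level_rollup(distinct)
  expect_setequal(pd$spec_id, distinct$spec_id)
})

test_that("identification counting applies the threshold to targets only", {
  items <- data.frame(label = c("target", "target", "target", "decoy"),
                      q_value = c(0.005, 0.01, 0.02, 0.001))
  expect_equal(count_identifications(items, 0.01), 2L)
  expect_equal(count_identifications(items, 0.02), 3L)
  expect_equal(count_identifications(items[0, ], 0.01), 0L)
  expect_error(count_identifications(items, 0), "q_threshold")
})

test_that("degenerate matrices are rejected with clear errors", {
  m <- sim_matrix(n_t = 100, n_d = 100, seed = 1)
  m$labels <- rep("target", length(m$labels))
  expect_error(rescore_psms(m, rescore_config(seed = 1)), "both target and decoy")
  small <- sim_matrix(n_t = 30, n_d = 30, seed = 1)
  expect_error(rescore_psms(small, rescore_config(seed = 1)), "too few")
})
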