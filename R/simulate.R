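#' Simulation configuration
#'
#' Defines a synthetic study: a toy proteome with transcript quantification,
#' novel transcripts, and a target/decoy PSM population in which abundance
#' features separate correct target PSMs from incorrect ones with tunable
#' effect size. Separation is parameterised by AUC under a Gaussian location
#' model: a feature with AUC `a` shifts correct-target values by
#' `sqrt(2) * qnorm(a)` standard deviations relative to the shared null
#' distribution of incorrect targets and decoys.
#'
#' The base feature block emulates a search-engine feature set: one dominant
#' informative feature (the main match score) at `base_feature_auc` plus
#' `n_base_features - n_informative_base` uninformative auxiliary features.
#'
#' @param n_proteins reference proteome size.
#' @param n_novel number of novel transcripts.
#' @param fpkm_log_mean,fpkm_log_sd log-normal FPKM model (natural-log
#'   scale) for transcript abundance.
#' @param n_target_psms,n_decoy_psms PSM population sizes.
#' @param prop_correct fraction of target PSMs that are correct matches
#'   (decoys are never correct) — the standard mixture assumption behind
#'   target-decoy FDR.
#' @param base_feature_auc,fpkm_feature_auc,xic_feature_auc separation
#'   (correct targets vs incorrect/decoy) of the informative base feature
#'   and of the two abundance features, each in `[0.5, 1)`.
#' @param n_base_features,n_informative_base base feature block shape.
#' @param feature_correlation correlation between the two abundance
#'   features' noise (they are positively correlated in real data); default
#'   0 (independence given correctness).
#' @param peptide_redundancy expected PSMs per distinct peptide (>= 1);
#'   controls how much the peptide-level rollup compresses.
#' @param seed integer seed; every generator is a pure function of the
#'   config including this seed.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_proteins = 200L, n_novel = 20L,
                              fpkm_log_mean = 1, fpkm_log_sd = 1.5,
                              n_target_psms = 1000L, n_decoy_psms = 1000L,
                              prop_correct = 0.5,
                              base_feature_auc = 0.85,
                              fpkm_feature_auc = 0.75,
                              xic_feature_auc = 0.75,
                              n_base_features = 5L,
                              n_informative_base = 1L,
                              feature_correlation = 0,
                              peptide_redundancy = 1.1,
                              seed = 1L) {
  aucs <- c(base_feature_auc, fpkm_feature_auc, xic_feature_auc)
  if (any(aucs < 0.5 | aucs >= 1)) stop_msg("feature AUCs must be in [0.5, 1)")
  if (prop_correct <= 0 || prop_correct >= 1) {
    stop_msg("prop_correct must be in (0,1)")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_novel = as.integer(n_novel),
                 fpkm_log_mean = fpkm_log_mean, fpkm_log_sd = fpkm_log_sd,
                 n_target_psms = as.integer(n_target_psms),
                 n_decoy_psms = as.integer(n_decoy_psms),
                 prop_correct = prop_correct,
                 base_feature_auc = base_feature_auc,
                 fpkm_feature_auc = fpkm_feature_auc,
                 xic_feature_auc = xic_feature_auc,
                 n_base_features = as.integer(n_base_features),
                 n_informative_base = as.integer(n_informative_base),
                 feature_correlation = feature_correlation,
                 peptide_redundancy = peptide_redundancy,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

auc_to_shift <- function(auc) sqrt(2) * stats::qnorm(auc)

# Random tryptic-site-containing protein sequence.
random_protein_seq <- function(len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "P", "Q", "S", "T", "V", "W", "Y")
  s <- sample(c(aa, "K", "R"), len, replace = TRUE,
              prob = c(rep(1, length(aa)), 2, 2))
  paste(s, collapse = "")
}

#' Simulate a toy reference proteome, quant table, and novel transcripts
#'
#' Random protein sequences (containing tryptic cleavage sites), one
#' transcript per protein with log-normal FPKM, and novel transcripts built
#' as an ATG-initiated stop-free open reading frame flanked by random
#' sequence, with class codes sampled from `{j, u}` (class `j` carries a
#' `+` strand annotation; class `u` is unstranded). Deterministic given the
#' config seed.
#'
#' @param config a [simulation_config].
#' @return list with `reference` (a [protein_db]), `quant` (a
#'   [quant_table]) and `novel` (a `"novel_transcripts"` data frame).
#' @export
simulate_reference_resources <- function(config = simulation_config()) {
  with_seed(derive_seed(config$seed, "resources"), {
    np <- config$n_proteins
    acc <- sprintf("prot%04d", seq_len(np))
    tx <- sprintf("tx%04d", seq_len(np))
    seqs <- vapply(pmax(30L, stats::rpois(np, 120)), random_protein_seq,
                   character(1))
    reference <- protein_db(acc, seqs, source = "reference",
                            transcript_ids = as.list(tx))
    fpkm <- stats::rlnorm(np, config$fpkm_log_mean, config$fpkm_log_sd)
    if (config$fpkm_log_sd == 0) fpkm <- rep(exp(config$fpkm_log_mean), np)
    quant <- quant_table(tx, fpkm)
    novel <- NULL
    if (config$n_novel > 0L) {
      bases <- c("A", "C", "G", "T")
      non_stop <- setdiff(names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE != "*"], "ATG")
      mk_seq <- function() {
        orf_len <- sample(10:40, 1)  # codons
        orf <- paste0("ATG", paste(sample(non_stop, orf_len, replace = TRUE),
                                   collapse = ""), "TAA")
        flank <- function(n) paste(sample(bases, n, replace = TRUE),
                                   collapse = "")
        paste0(flank(sample(0:10, 1)), orf, flank(sample(0:10, 1)))
      }
      cc <- sample(c("j", "u"), config$n_novel, replace = TRUE)
      novel <- data.frame(transcript_id = sprintf("TCONS_%05d",
                                                  seq_len(config$n_novel)),
                          class_code = cc,
                          sequence = vapply(seq_len(config$n_novel),
                                            function(i) mk_seq(), character(1)),
                          strand = ifelse(cc == "j", "plus", "unknown"),
                          stringsAsFactors = FALSE)
      class(novel) <- c("novel_transcripts", "data.frame")
    }
    list(reference = reference, quant = quant, novel = novel)
  })
}

#' Simulate a target/decoy PSM population with tunable feature separation
#'
#' Emulates the output of a target-decoy database search: `n_target_psms`
#' target and `n_decoy_psms` decoy PSMs, where a hidden fraction
#' `prop_correct` of targets are correct matches. Correct targets are
#' shifted on the informative features by `sqrt(2) * qnorm(AUC)`; incorrect
#' targets and decoys share the null distribution. Abundance features (FPKM,
#' XIC) are generated on a log2 scale and exponentiated, so they arrive as
#' non-negative raw values whose separation survives the pipeline's log
#' transform exactly (monotone maps preserve AUC). The hidden correctness
#' labels are returned for evaluation only and must never be shown to the
#' rescorer.
#'
#' @param config a [simulation_config].
#' @return list with `psms` (a [psm_table] of base features, including
#'   `PrecursorMz`/`RetentionTime` columns), `extras`
#'   (`list(FPKM = , XIC = )` of raw non-negative values aligned to
#'   `psms`), `matrix` (the base-feature [feature_matrix]) and `correct`
#'   (hidden logical vector, `FALSE` for every decoy).
#' @export
simulate_psm_dataset <- function(config = simulation_config()) {
  with_seed(derive_seed(config$seed, "psms"), {
    nt <- config$n_target_psms; nd <- config$n_decoy_psms
    n <- nt + nd
    label <- c(rep("target", nt), rep("decoy", nd))
    correct <- c(stats::runif(nt) < config$prop_correct, rep(FALSE, nd))
    nb <- config$n_base_features
    shifts <- rep(0, nb)
    shifts[seq_len(min(config$n_informative_base, nb))] <-
      auc_to_shift(config$base_feature_auc)
    base <- matrix(stats::rnorm(n * nb), n, nb)
    base <- base + outer(as.numeric(correct), shifts)
    colnames(base) <- sprintf("score%d", seq_len(nb))
    # abundance features on log2 scale with optional shared noise
    rho <- config$feature_correlation
    z <- stats::rnorm(n)
    mk_extra <- function(auc) {
      g <- 3 + auc_to_shift(auc) * correct +
        sqrt(1 - rho) * stats::rnorm(n) + sqrt(rho) * z
      2^g
    }
    extras <- list(FPKM = mk_extra(config$fpkm_feature_auc),
                   XIC = mk_extra(config$xic_feature_auc))
    # peptides: redundancy collapses some PSMs onto shared peptides
    pool_size <- function(k) max(1L, ceiling(k / config$peptide_redundancy))
    pep <- c(sprintf("PEPT%05d", sample.int(pool_size(nt), nt, replace = TRUE)),
             sprintf("PEPD%05d", sample.int(pool_size(nd), nd, replace = TRUE)))
    prots <- c(lapply(sample.int(max(1L, nt %/% 5L), nt, replace = TRUE),
                      function(i) sprintf("prot%04d", i)),
               lapply(sample.int(max(1L, nd %/% 5L), nd, replace = TRUE),
                      function(i) sprintf("decoy_prot%04d", i)))
    feats <- cbind(base,
                   PrecursorMz = stats::runif(n, 400, 1200),
                   RetentionTime = stats::runif(n, 60, 3540))
    psms <- psm_table(spec_id = sprintf("psm%06d", seq_len(n)),
                      label = label,
                      scan_number = seq_len(n),
                      peptide = pep,
                      proteins = prots,
                      features = feats)
    list(psms = psms, extras = extras,
         matrix = build_feature_matrix(psms),
         correct = correct)
  })
}

#' Simulate an MS1 map with Gaussian elution peaks of known area
#'
#' Each peak contributes a Gaussian elution profile at its m/z, so the true
#' integrated area `amplitude * sigma * sqrt(2*pi)` is known in closed form
#' and recorded for oracle comparisons. Peaks sharing an m/z add. Optional
#' Gaussian intensity noise (truncated at 0).
#'
#' @param peaks data frame with columns `mz`, `rt_apex`, `amplitude`,
#'   `sigma` (seconds).
#' @param rt_range scan time range (seconds).
#' @param sampling_interval scan spacing (seconds).
#' @param noise_sd standard deviation of additive intensity noise.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return an [ms1_map] with attribute `"true_areas"` =
#'   `amplitude * sigma * sqrt(2*pi)` per input peak.
#' @export
simulate_ms1_map <- function(peaks, rt_range = c(0, 600),
                             sampling_interval = 1, noise_sd = 0, seed = 1L) {
  if (sampling_interval <= 0) stop_msg("sampling_interval must be positive")
  if (nrow(peaks) && any(peaks$sigma <= 0)) stop_msg("sigma must be positive")
  rts <- seq(rt_range[1], rt_range[2], by = sampling_interval)
  scan_peaks <- with_seed(derive_seed(seed, "ms1"), lapply(rts, function(t) {
    if (!nrow(peaks)) {
      return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("mz", "intensity"))))
    }
    ints <- peaks$amplitude * exp(-(t - peaks$rt_apex)^2 / (2 * peaks$sigma^2))
    if (noise_sd > 0) ints <- pmax(ints + stats::rnorm(length(ints), 0, noise_sd), 0)
    m <- cbind(mz = peaks$mz, intensity = ints)
    m[order(m[, 1]), , drop = FALSE]
  }))
  out <- ms1_map(rts, scan_peaks)
  attr(out, "true_areas") <- if (nrow(peaks)) {
    peaks$amplitude * peaks$sigma * sqrt(2 * pi)
  } else numeric()
  out
}
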