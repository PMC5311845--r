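---
title: "Abundance-aware rescoring of peptide-spectrum matches: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance-aware rescoring of peptide-spectrum matches: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmrescore)
```

## The problem

Shotgun proteomics identifies peptides by matching MS/MS spectra against a
protein sequence database. Each candidate pairing — a peptide-spectrum match
(PSM) — carries a search-engine score, but the top-ranked match is often
wrong, so identifications are filtered by a false discovery rate (FDR)
estimated with target-decoy competition: the same spectra are also searched
against reversed or shuffled (decoy) sequences, and decoy matches estimate
the rate of false matches among targets.

`psmrescore` implements a proteogenomic identification workflow around this
machinery. Two sources of external evidence are brought to bear:

* **Transcript abundance (FPKM)** from RNA-Seq of the same sample. Proteins
  whose transcripts are expressed are more likely to be present, so the
  transcript abundance of a PSM's protein is informative about the match
  being correct. RNA-Seq also yields *novel transcripts* (Cuffcompare class
  `j`, potentially novel isoforms, and `u`, unknown intergenic transcripts)
  whose translations extend the search space beyond the reference proteome.
* **Peptide abundance (MS1 XIC)**: the area of the precursor's extracted ion
  chromatogram in the MS1 survey scans. A real peptide elutes as a
  chromatographic peak; a spurious match usually does not correspond to a
  well-formed precursor trace.

The package covers four stages: customized database construction, abundance
feature assignment, semi-supervised rescoring with q-value estimation, and a
permutation test validating that any gain is genuinely attributable to the
added features.

## Customized database construction

`build_customized_database()` assembles the sample-specific search space:

* Reference proteins are dropped when the maximum FPKM over their
  transcripts is *strictly below* a threshold (default 0.1 FPKM; an entry at
  exactly the threshold is kept). Proteins with no quantified transcript are
  treated as FPKM 0. The per-protein maximum (rather than a sum or a
  gene-level aggregate) mirrors the max rule used when a PSM maps to several
  proteins; whether the filter should aggregate per gene is genuinely open,
  and per-transcript max is the conservative reading.
* Novel transcripts are translated in all reading frames — three forward
  frames when the strand is annotated, six when it is unknown (class-`u`
  intergenic transcripts carry no strand). Each frame is split at stop
  codons and the single longest stop-free peptide across frames is kept,
  ties broken by frame index and then start position. "Longest translated
  segment" is one of several defensible readings of selecting the longest
  frame product; the chosen frame and offset are recorded per entry so
  alternatives can be compared. Peptides shorter than 7 amino acids (about
  the shortest identifiable tryptic peptide) are rejected with a recorded
  reason.
* Decoys are generated per target by sequence reversal (default) or a
  seeded residue shuffle; either way each decoy is an anagram of its
  target, preserving amino-acid composition.

## Abundance features

`assign_fpkm_features()` implements the transcript-abundance rule: a target
PSM receives the largest FPKM across all transcripts of all its matched
proteins; a matched protein with no quantified transcript contributes zero
(untranscribed sequence). A decoy PSM has no meaningful transcript, so it
receives a value drawn uniformly (with replacement, per PSM) from the pool
of values assigned to target PSMs. Drawing from the target pool makes the
decoy feature distribution match the target marginal exactly, which is what
a feature must do under the null for target-decoy FDR estimation to remain
valid. The draw is per-PSM rather than per-protein — the finer-grained
choice, and the one that keeps the decoy marginal exact.

`assign_xic_features()` computes, per PSM, the area of the precursor's
extracted ion chromatogram: all MS1 intensities within a ppm window (default
10 ppm, the usual Orbitrap precursor tolerance) of the precursor m/z are
summed per scan across a retention-time window (default ±150 s), the apex
is the maximum-intensity local maximum nearest the PSM's retention time,
integration boundaries extend until the trace falls below 1% of the apex or
hits a local minimum, and the area is the trapezoidal integral. Summation
(not maximum) within the tolerance window is robust to centroided isotope
shoulders splitting the trace. Decoy PSMs are processed identically — their
spectra are real, only their sequence assignment is wrong. Empty and
single-point chromatograms integrate to zero. An optional 3-point moving
average (off by default) smooths only the peak-picking, never the
integrated intensities.

Both abundance features span orders of magnitude and enter the feature
matrix as `log2(x + 1)` (`log_transform()`; base and pseudocount
configurable).

## Semi-supervised rescoring

`rescore_psms()` is the package's central model. It follows the
semi-supervised target-decoy learning scheme in which decoys are known
negatives and high-confidence targets serve as provisional positives:

1. PSMs are randomly split into three folds (seeded, by spectrum). Each
   fold is scored by a classifier trained only on the other two folds, so
   no PSM is ever scored by a model that saw it.
2. Within a training split, the starting ranking is the single feature
   (either sign) that maximizes targets accepted at `train_fdr` (default
   1%).
3. Each refinement iteration takes as positives the training targets at
   q ≤ `train_fdr` under the current ranking and as negatives all training
   decoys, then fits a linear soft-margin classifier on standardized
   features.
4. Held-out scores are normalized per fold (decoy median to 0, the score at
   the `train_fdr` acceptance threshold to 1) and pooled; final q-values
   come from `estimate_qvalues()` on the pooled set.

The inner classifier is a primal L2-regularized squared-hinge linear SVM
with per-example class weights, minimized by BFGS with analytic gradients —
the same primal formulation used by Percolator's internal solver, and at
PSM-feature dimensionality each fit costs milliseconds. Class weights are
proportional to inverse class size with each class summing to unit total
weight, so the soft-margin cost grid (`{0.1, 1, 10}`) spans genuine
under- to over-fitting regardless of how few positives an iteration
accepts.

Several choices here deserve explanation, because naive versions measurably
misbehave at realistic acceptance counts (tens to low hundreds of PSMs at
1% FDR):

* **Cost selection.** The cost is chosen per iteration on a symmetric
  half-split of the training data, counting accepted targets at
  5×`train_fdr`. The count at `train_fdr` itself is an extreme order
  statistic — the cutoff is positioned by roughly one decoy — and selecting
  on it routinely favours the overfitting cost.
* **Early stopping.** Semi-supervised refinement with few positives can
  wander rather than converge; the fold's final classifier is the iterate
  that validates best on the held-out halves, with ties and
  noise-level differences resolved in favour of the earlier, simpler
  candidate (a one-standard-error rule against the Poisson noise of the
  validation count). The initial single-feature direction is candidate
  zero: a fitted SVM must beat it decisively to replace it. This makes the
  learner nearly invariant to pure-noise feature columns, which is exactly
  the behaviour the permutation test assumes.
* **Scorer-class harmonization.** The initial-direction-vs-SVM preference
  is settled by majority vote across folds. Pooled q-values are only
  calibrated when all folds contribute comparably-behaved scores; mixing a
  single-feature ranking in one fold with SVM scores in the others was
  measured to distort the merged ranking badly enough to collapse
  acceptance counts.
* **Normalization fallback.** When a held-out fold accepts no targets at
  `train_fdr`, its affine normalization threshold is taken from the
  training split under the same classifier rather than from an arbitrary
  scale; a degenerate fold scale otherwise poisons the pooled ranking.

`estimate_qvalues()` uses the simple target-decoy estimate
(#decoys ≥ t)/(#targets ≥ t) with π0 = 1 and no +1 correction, decoys
ranked before targets at equal scores (the conservative tie-break), and
q-values as the running minimum of FDR from the bottom of the ranking
upward. The +1-corrected variant is available via `plus_one = TRUE`; at
desk-scale acceptance counts it is markedly more conservative (an
acceptance set must reach ~100 targets before any set can pass 1% FDR).

`peptide_level_rollup()` groups by exact peptide string (modified-sequence
notation preserved; a sequence seen as both target and decoy forms two
groups), keeps the best-scoring PSM per peptide, and recomputes q-values on
the peptide list.

The fitted object has `print`, `summary`, `coef` (fold-averaged
standardized weights — the feature-importance reading), `predict` (scores
for new PSMs through the per-fold models) and `plot` (target/decoy score
histograms) methods.

## Permutation validation

`run_permutation_test()` asks whether an identification gain attributed to
the abundance features is real: the feature-to-PSM assignment is shuffled by
one random row permutation (jointly across the selected columns, preserving
their mutual correlation; independent shuffles are available), the *entire*
semi-supervised training is re-run per shuffle, and the empirical p-value is
the fraction of permutations whose identification count is at least the
observed one.

Counting ties as "as extreme as observed" is deliberate. A rescorer that
correctly ignores an uninformative column returns the same count for many
permutations, putting a point mass at the observed value; counting only
strictly greater permutations would then report p ≈ 0 for a pure-noise
feature — the opposite of what the test exists to detect. With ties counted,
the null p-value stays super-uniform (the standard guarantee for
permutation tests with atoms), while an informative feature still yields
p ≈ 0 because no shuffle reaches the observed count at all.

## The synthetic benchmark

`simulate_psm_dataset()` generates the target/decoy PSM populations used
throughout the tests. The model: each target PSM is correct with
probability `prop_correct` (decoys are never correct) — the mixture
assumption underlying target-decoy FDR. Features follow a Gaussian location
model in which a feature of separation AUC *a* shifts correct targets by
√2·Φ⁻¹(*a*) standard deviations against the shared null of incorrect
targets and decoys. The base feature block emulates a search-engine feature
set: one dominant informative feature (the analog of the main match score)
at `base_feature_auc` plus four uninformative auxiliary columns, with
uninformative precursor m/z and retention-time columns alongside. Giving
every base feature the full AUC would make their combination separate
almost perfectly, leaving no headroom for abundance features to act — the
single-dominant-feature design is what makes the feature-gain phenomenon
expressible at all. Abundance features are generated on a log2 scale and
exponentiated, so they arrive as non-negative raw values whose AUC survives
the pipeline's log transform exactly (monotone maps preserve AUC). A
correlation knob couples the two abundance features' noise, since
transcript and peptide abundance are positively correlated in real data;
the default is independence given correctness.

What the generator does *not* emulate: heavy-tailed search-engine score
distributions, charge- and length-dependent feature structure, shared
peptides across proteins, retention-time-correlated XIC failures, and
cross-run abundance alignment. Passing tests on this benchmark demonstrate
the statistical mechanics (FDR calibration, feature gain, null safety,
permutation behaviour), not performance on any particular instrument's
data.

`simulate_ms1_map()` builds MS1 maps from Gaussian elution peaks of known
closed-form area (A·σ·√2π), which the XIC tests must recover within 1%;
`simulate_reference_resources()` builds toy proteomes, log-normal FPKM
tables and translatable novel transcripts that round-trip through the
package's readers.

## Default study sizes

The statistical property checks run at 5,000 target + 5,000 decoy PSMs,
`prop_correct` 0.5, a base feature of AUC 0.85, abundance analogs at AUC
0.75 (informative) and 0.50 (null), across 20-seed ensembles; permutation
behaviour is checked on 2,000-PSM populations with 50 shuffles. At these
sizes, the acceptance count at 1% FDR is set by the pooled rank of the
first one or two decoys — an extreme order statistic. Two consequences are
documented rather than hidden: per-run empirical FDR ratios are noisy at
tens of accepted PSMs (the calibration check therefore pools false and
accepted counts across the ensemble), and identification counts can swing
tens of percent between statistically equivalent rankings, which bounds how
consistently a genuine feature gain can manifest seed by seed.

## Numerical and degenerate-input choices

* All randomness flows from one run-level seed, fanned out to per-stage
  generators (`fold_assignment`, decoy FPKM draws, shuffles), so any stage
  can be re-run reproducibly in isolation; every pipeline stage is
  bit-identical across same-seed runs.
* Standardization parameters are frozen per fold from its training split;
  constant columns get unit scale instead of dividing by zero.
* An empty extraction window yields an empty chromatogram (area 0), not an
  error; a PSM without precursor coordinates gets XIC 0 with a warning.
* Palindromic sequences reversed into identical decoys are permitted and
  reported.
* A fold with no positives at `train_fdr` after initialization falls back
  to its initial single-feature direction with a warning.
* Ties in q-value ranking are broken decoy-first (conservative); ties in
  translation are broken by frame then position (deterministic).

## Known limitations

* Protein-level inference, posterior error probabilities, and multi-engine
  combination are out of scope.
* Fold assignment is at spectrum level; peptides shared across folds can
  leak peptide-level information between training and held-out scoring (a
  simplification over peptide-level partitioning).
* The XIC integrator uses the monoisotopic trace only; isotope-envelope
  deconvolution and cross-run alignment are not attempted.
* The FPKM filter operates per transcript; gene-level aggregation is not
  implemented.
* At small PSM counts (hundreds), the initial-direction search can latch
  onto spurious single-feature rankings in individual folds; the benchmark
  sizes above avoid this regime.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_target_psms = 2000, n_decoy_psms = 2000,
                         fpkm_feature_auc = 0.75, xic_feature_auc = 0.75,
                         seed = 7)
sim <- simulate_psm_dataset(cfg)

base_fit <- rescore_psms(sim$matrix, rescore_config(seed = 7))
full_fit <- rescore_psms(
  build_feature_matrix(sim$psms, extra = sim$extras,
                       add = c("FPKM", "XIC")),
  rescore_config(seed = 7))

count_identifications(peptide_level_rollup(base_fit))
count_identifications(peptide_level_rollup(full_fit))
coef(full_fit)

pt <- run_permutation_test(
  build_feature_matrix(sim$psms, extra = sim$extras,
                       add = c("FPKM", "XIC")),
  c("FPKM", "XIC"), n_permutations = 50, config = rescore_config(seed = 7))
pt
```
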