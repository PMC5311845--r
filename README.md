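# psmrescore

RNA-Seq-informed rescoring of peptide-spectrum matches (PSMs) for shotgun
proteomics.

Database search engines score each PSM, but at a fixed false discovery rate
many genuine peptides remain below the acceptance threshold. `psmrescore`
raises identification sensitivity by bringing two kinds of external
abundance evidence into a Percolator-style semi-supervised rescorer:

* **F_mRNA — transcript abundance.** The FPKM of the transcripts encoding a
  PSM's proteins (max over matched proteins; zero for untranscribed
  sequences; a random draw from the target pool for decoys, preserving the
  null marginal).
* **F_peptide — peptide abundance.** The MS1 extracted-ion-chromatogram
  (XIC) area of the PSM's precursor, integrated by trapezoid between
  boundaries at 1% of the peak apex within a ±150 s window at 10 ppm.

Around the rescorer the package provides the full proteogenomic workflow:
customized protein databases (reference proteins filtered at FPKM < 0.1,
plus six-frame translations of novel transcripts with Cuffcompare class
codes `j`/`u`, plus reversed or shuffled decoys), PIN (Percolator input)
and FASTA/quant-table I/O, mzML/mzXML MS1 reading, target-decoy q-values at
PSM and peptide level, a permutation test for feature validity, and a
synthetic-data generator with tunable feature informativeness for
benchmarking the whole pipeline.

## The model in brief

Scores are learned by semi-supervised target-decoy iteration under 3-fold
cross-validation: within each training split, positives are targets at
q ≤ 1% under the current ranking (initialized from the best single
feature), negatives are all decoys, and a class-weighted primal L2-SVM
(squared hinge, BFGS) is refit each iteration with its soft-margin cost
chosen on a nested split. Held-out scores are affinely normalized per fold
(decoy median → 0, acceptance threshold → 1) and pooled. q-values use the
simple target-decoy estimate q(s) = min over thresholds t ≤ s of
(#decoys ≥ t)/(#targets ≥ t), decoys ranked first at ties. The permutation
test re-runs the full training on row-shuffled feature assignments and
reports p = #(permuted count ≥ observed)/n.

## Worked example

```r
library(psmrescore)

cfg <- simulation_config(n_target_psms = 2000, n_decoy_psms = 2000,
                         fpkm_feature_auc = 0.75, xic_feature_auc = 0.75,
                         seed = 7)
sim <- simulate_psm_dataset(cfg)

base_fit <- rescore_psms(sim$matrix, rescore_config(seed = 7))
full_mat <- build_feature_matrix(sim$psms, extra = sim$extras,
                                 add = c("FPKM", "XIC"))
full_fit <- rescore_psms(full_mat, rescore_config(seed = 7))

count_identifications(peptide_level_rollup(base_fit))   # 53
count_identifications(peptide_level_rollup(full_fit))   # 105
```

Base features alone accept 53 peptides at 1% FDR; adding the two abundance
features nearly doubles that to 105. The fold-averaged standardized weights
show where the signal lives — the dominant search score plus the two
abundance columns:

```r
round(coef(full_fit), 3)
#>        score1        score2        score3        score4        score5
#>         0.399         0.048         0.019        -0.023        -0.035
#>   PrecursorMz RetentionTime          FPKM           XIC   (Intercept)
#>        -0.001         0.024         0.133         0.227        -0.693
```

The permutation test confirms the gain is tied to the feature-to-PSM
assignment, not to the mere presence of extra columns:

```r
run_permutation_test(full_mat, c("FPKM", "XIC"), n_permutations = 50,
                     config = rescore_config(seed = 7))
#> Permutation test (50 shuffles of FPKM+XIC, peptide level, q <= 0.01):
#>   observed 105 identifications; permuted median 53 (range 40-53); p = 0
```

A shell front end wrapping the same functions (subcommands `simulate`,
`builddb`, `xic`, `rescore`, `permtest`, `run`) is installed at
`exec/psmrescore` inside the package directory.

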