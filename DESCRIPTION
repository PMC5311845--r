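Package: psmrescore
Title: RNA-Seq-Informed Rescoring of Peptide-Spectrum Matches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Proteogenomic peptide identification toolkit: builds RNA-Seq
    customized protein databases (FPKM filtering of reference proteins,
    six-frame translation of novel transcripts, decoy generation), attaches
    transcript-abundance (FPKM) and peptide-abundance (MS1 extracted-ion
    chromatogram) features to peptide-spectrum matches, rescores them with a
    Percolator-style semi-supervised linear support-vector machine under
    three-fold cross-validation, estimates target-decoy q-values at PSM and
    peptide level, and validates feature contributions with a permutation
    test. Includes a synthetic-data generator for target/decoy PSM
    populations with tunable feature informativeness and simulated MS1 maps
    with known peak areas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    mzR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    seqinr,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
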