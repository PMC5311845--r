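make_ref <- function(fpkm, threshold_names = NULL) {
  n <- length(fpkm)
  protein_db(sprintf("p%d", seq_len(n)),
             rep("MKTAYIAKQR", n),
             transcript_ids = as.list(sprintf("t%d", seq_len(n))))
}

test_that("FPKM filter removes below-threshold entries with strict less-than", {
  db <- make_ref(c(0.05, 0.1, 3.0))
  quant <- quant_table(c("t1", "t2", "t3"), c(0.05, 0.1, 3.0))
  kept <- filter_by_fpkm(db, quant, threshold = 0.1)
  expect_equal(kept$accession, c("p2", "p3"))  # 0.1 retained, 0.05 removed

  # max rule over multiple transcripts
  db2 <- protein_db("pm", "MKTA", transcript_ids = list(c("ta", "tb")))
  q2 <- quant_table(c("ta", "tb"), c(0.0, 3.0))
  expect_equal(nrow(filter_by_fpkm(db2, q2, 0.1)), 1L)

  # no transcript ids or unquantified -> FPKM 0, removed for positive threshold
  db3 <- protein_db(c("px", "py"), c("MK", "AA"),
                    transcript_ids = list(character(), "unknown_tx"))
  expect_equal(nrow(filter_by_fpkm(db3, quant, 0.1)), 0L)
  expect_equal(nrow(filter_by_fpkm(db3, quant, 0)), 2L)  # 0 >= 0 retained
})

test_that("FPKM filter is idempotent and monotone in the threshold", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    db <- make_ref(runif(n))
    quant <- quant_table(sprintf("t%d", 1:n), rlnorm(n, 0, 2))
    prev <- Inf
    for (thr in c(0, 0.1, 1, 10)) {
      kept <- filter_by_fpkm(db, quant, thr)
      expect_identical(filter_by_fpkm(kept, quant, thr), kept)
      expect_lte(nrow(kept), prev)
      prev <- nrow(kept)
    }
  }
})

test_that("novel transcript translation picks the longest stop-free peptide", {
  tr <- translate_novel_transcript("t1", "ATGAAATAA", "j", strand = "plus",
                                   min_length = 1)
  expect_s3_class(tr, "protein_db")
  expect_equal(tr$sequence, "MK")
  expect_equal(tr$source, "novel_isoform_j")
  expect_equal(tr$transcript_ids[[1]], "t1")

  # below the minimum identifiable length -> rejected with reason
  rej <- translate_novel_transcript("t2", "ATGAAATAA", "u", strand = "plus")
  expect_true(is.list(rej) && isTRUE(rej$rejected))
  expect_match(rej$reason, "below minimum")

  # no stop-free segment in any readable frame
  rej2 <- translate_novel_transcript("t3", "TAA", "u", strand = "plus",
                                     min_length = 1)
  expect_true(isTRUE(rej2$rejected))
  expect_match(rej2$reason, "no stop-free")
})

test_that("translation agrees with an independent six-frame oracle", {
  set.seed(17)
  for (i in 1:25) {
    len <- sample(30:200, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    strand <- sample(c("plus", "minus", "unknown"), 1)
    ours <- translate_novel_transcript(paste0("t", i), s, "u", strand = strand,
                                       min_length = 1)
    oracle <- oracle_longest_peptide(s, strand)
    if (is.null(oracle)) {
      expect_true(isTRUE(ours$rejected))
    } else {
      expect_equal(ours$sequence, oracle$peptide, info = s)
      expect_equal(attr(ours, "frame"), oracle$frame, info = s)
      expect_equal(attr(ours, "start"), oracle$start, info = s)
    }
  }
})

test_that("unknown-strand translation is symmetric under reverse complement", {
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  set.seed(23)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    segs_fwd <- psmrescore:::translate_frames(s, "unknown")
    segs_rev <- psmrescore:::translate_frames(revcomp(s), "unknown")
    peps <- function(z) sort(vapply(z, `[[`, character(1), "peptide"))
    expect_equal(peps(segs_fwd), peps(segs_rev))
    # the chosen peptide has the same (maximal) length either way; the
    # tie-break on frame index may select a different equal-length segment
    a <- translate_novel_transcript("x", s, "u", strand = "unknown",
                                    min_length = 1)
    b <- translate_novel_transcript("x", revcomp(s), "u", strand = "unknown",
                                    min_length = 1)
    expect_equal(nchar(a$sequence), nchar(b$sequence))
  }
})

test_that("database build combines filtered reference and translated novels", {
  ref <- make_ref(1:5)
  quant <- quant_table(sprintf("t%d", 1:5), c(0.01, 0.05, 0.5, 1, 2))
  novel <- data.frame(
    transcript_id = c("TC1", "TC2"),
    class_code = c("j", "u"),
    sequence = c(paste0("ATG", strrep("AAA", 10), "TAA"),
                 paste0("ATG", strrep("GCT", 12), "TGA")),
    strand = c("plus", "unknown"), stringsAsFactors = FALSE)
  class(novel) <- c("novel_transcripts", "data.frame")

  out <- build_customized_database(ref, novel, quant, threshold = 0.1)
  expect_equal(out$report$n_reference_in, 5L)
  expect_equal(out$report$n_reference_retained, 3L)
  expect_equal(out$report$n_novel_added, 2L)
  expect_equal(out$report$n_total, 5L)
  expect_equal(nrow(out$db), 5L)
  expect_equal(sum(out$db$source != "reference"), 2L)

  # empty novel list -> filtered reference only
  out2 <- build_customized_database(ref, NULL, quant, threshold = 0.1)
  expect_equal(out2$db$accession, c("p3", "p4", "p5"))

  # threshold 0 retains every quantified entry
  out3 <- build_customized_database(ref, NULL, quant, threshold = 0)
  expect_equal(nrow(out3$db), 5L)
})

test_that("database build rejects accession collisions", {
  ref <- protein_db("novj_TC1", "MKTAYIAK")
  novel <- data.frame(transcript_id = "TC1", class_code = "j",
                      sequence = paste0("ATG", strrep("AAA", 10), "TAA"),
                      strand = "plus", stringsAsFactors = FALSE)
  class(novel) <- c("novel_transcripts", "data.frame")
  expect_error(
    build_customized_database(ref, novel, quant_table(character(), numeric()),
                              threshold = 0),
    "collision")
})

test_that("decoy generation reverses or shuffles and preserves composition", {
  db <- protein_db(c("a", "b"), c("MKTA", "ACDEFGHIK"))
  dec <- generate_decoy_entries(db, "reverse")
  expect_equal(dec$sequence[1], "ATKM")
  expect_equal(dec$accession, c("decoy_a", "decoy_b"))
  expect_equal(dec$source, c("decoy", "decoy"))

  # palindrome: identical decoy allowed, reported
  pal <- protein_db("p", "MKKM")
  expect_message(dpal <- generate_decoy_entries(pal, "reverse"), "identical")
  expect_equal(dpal$sequence, "MKKM")

  # shuffle: deterministic given seed, anagram of the target
  s1 <- generate_decoy_entries(db, "shuffle", seed = 7)
  s2 <- generate_decoy_entries(db, "shuffle", seed = 7)
  expect_identical(s1, s2)
  for (i in 1:2) {
    expect_equal(sort(strsplit(s1$sequence[i], "")[[1]]),
                 sort(strsplit(db$sequence[i], "")[[1]]))
  }
  expect_error(generate_decoy_entries(db[0, ], "reverse"), "empty")
})
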