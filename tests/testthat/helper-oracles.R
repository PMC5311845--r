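# Independent oracles used by the tests. These deliberately avoid the code
# paths of the implementation they check.

# Brute-force target-decoy q-values: walk the full ranking (decoy-first at
# equal scores), compute at every position FDR = #decoys at or above /
# #targets at or above, then take for each item the minimum FDR over all
# cutoffs that accept it. O(n^2) by construction.
oracle_qvalues <- function(scores, labels, plus_one = FALSE) {
  ord <- order(-scores, labels == "target")  # decoys first on ties
  s <- scores[ord]; l <- labels[ord]
  m <- length(s)
  fdr <- numeric(m)
  for (i in seq_len(m)) {
    nt <- sum(l[1:i] == "target")
    nd <- i - nt
    num <- nd + if (plus_one) 1 else 0
    fdr[i] <- if (nt > 0) min(num / nt, 1) else 1
  }
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(fdr[i:m])
  q[order(ord)]
}

# Six-frame translation oracle built on seqinr: returns all stop-free
# peptide segments with their frame index and start, mirroring the
# documented frame numbering (0-2 forward, 3-5 reverse complement).
oracle_longest_peptide <- function(sequence, strand) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  strands <- switch(strand,
                    plus = list(sequence),
                    minus = list(revcomp(sequence)),
                    unknown = list(sequence, revcomp(sequence)))
  out <- list()
  fr <- 0L
  for (s in strands) {
    for (off in 0:2) {
      sub <- substring(s, off + 1)
      len <- nchar(sub) %/% 3 * 3
      if (len >= 3) {
        aa <- paste(seqinr::translate(seqinr::s2c(substr(sub, 1, len)),
                                      ambiguous = TRUE), collapse = "")
        pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
        starts <- c(0L, cumsum(nchar(pieces) + 1L))[seq_along(pieces)] + 1L
        for (k in seq_along(pieces)) {
          if (nzchar(pieces[k])) {
            out[[length(out) + 1]] <- list(peptide = pieces[k], frame = fr,
                                           start = starts[k])
          }
        }
      }
      fr <- fr + 1L
    }
  }
  if (!length(out)) return(NULL)
  lens <- vapply(out, function(z) nchar(z$peptide), integer(1))
  frames <- vapply(out, `[[`, integer(1), "frame")
  starts <- vapply(out, `[[`, integer(1), "start")
  out[[order(-lens, frames, starts)[1]]]
}

# Random PSM table for round-trip tests.
random_psm_table <- function(n, n_features = 3, seed = 1) {
  set.seed(seed)
  lab <- sample(c("target", "decoy"), n, replace = TRUE)
  feats <- matrix(round(rnorm(n * n_features), 6), n,
                  dimnames = list(NULL, paste0("f", seq_len(n_features))))
  prots <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    if (lab[i] == "decoy") paste0("decoy_p", sample(99, k)) else paste0("p", sample(99, k))
  })
  psm_table(spec_id = sprintf("s%04d", seq_len(n)), label = lab,
            scan_number = seq_len(n) * 2L,
            peptide = sprintf("PEP%03dK", sample(999, n, replace = TRUE)),
            proteins = prots, features = feats)
}
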