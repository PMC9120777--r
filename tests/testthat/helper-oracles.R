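# Independent oracles and small construction helpers shared by the tests.

# Brute-force local aligner: plain cubic dynamic program that scans every
# gap length explicitly (no Gotoh gap states).  Score of a length-L gap is
# gap_open + L * gap_extend, as in the package engine.  Score only.
oracle_local_score <- function(a, b, scheme = scoring_scheme()) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  mat <- scheme$matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag <- H[i, j] + mat[A[i], B[j]]
      up <- max(H[seq_len(i), j + 1] + go + ge * rev(seq_len(i)))
      left <- max(H[i + 1, seq_len(j)] + go + ge * rev(seq_len(j)))
      H[i + 1, j + 1] <- max(0, diag, up, left)
    }
  }
  max(H)
}

# Biostrings local alignment score for cross-checks (independent C
# implementation of the same scoring model).
biostrings_local_score <- function(a, b, scheme = scoring_scheme()) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = -scheme$gap_open,
    gapExtension = -scheme$gap_extend,
    scoreOnly = TRUE)
}

random_seq <- function(n, alphabet, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A synthetic ccmM-like pair: an active reference carrying the two
# disulfide cysteines at the configured positions, and an inactive
# homolog heavily diverged in the domain.
make_gamma_refs <- function(seed = 9, config = gamma_ca_config()) {
  act <- random_protein(260, seed = seed)
  ch <- strsplit(act, "")[[1]]
  ch[config$cysteine_positions] <- "C"
  act <- paste(ch, collapse = "")
  inact <- mutate_protein(act, 40, seed = seed + 1)
  list(active = act, inactive = inact)
}

# Small fixed reference set reused by orthology/pipeline tests.
test_refset <- function(symbols = c("rbcL", "rbcS", "ccmM", "ccmK1", "sbtA"),
                        seed = 1000) {
  generate_reference_set(symbols = symbols, seed = seed)
}
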