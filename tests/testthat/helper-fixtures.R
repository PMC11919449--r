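# Shared fixtures and independent oracles, built in code at test time.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_dna_fixed <- function(n, seed) withr::with_seed(seed, rand_dna(n))

# Substitute the bases at 1-based positions `pos` with a different base.
mutate_at <- function(seq, pos) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

# A small tokenizer trained on a fixed synthetic corpus (cheap to rebuild).
small_tokenizer <- function(vocab_size = 200, corpus_bp = 20000, seed = 101) {
  g <- generate_synthetic_genome(corpus_bp, seed = seed)
  train_vocab(substring(g$chromosomes[[1]],
                        seq(1, corpus_bp - 999, by = 1000),
                        seq(1000, corpus_bp, by = 1000)),
              vocab_size = vocab_size)
}

# Independent brute-force affine-gap local-alignment oracle (minimization
# convention), written as a plain three-state DP with no shared code with
# the package kernel.  Returns only the optimal score.
sw_oracle <- function(read, frag, match = -2, mismatch = 1, gap_open = 0.5,
                      gap_extend = 0.1) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  f <- strsplit(frag, "", fixed = TRUE)[[1]]
  Q <- length(r); L <- length(f)
  H <- matrix(0, Q + 1, L + 1)
  E <- matrix(-Inf, Q + 1, L + 1)  # gap consuming fragment
  Fm <- matrix(-Inf, Q + 1, L + 1)  # gap consuming read
  best <- 0
  for (i in 2:(Q + 1)) {
    for (j in 2:(L + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open, E[i, j - 1] - gap_extend)
      Fm[i, j] <- max(H[i - 1, j] - gap_open, Fm[i - 1, j] - gap_extend)
      s <- if (r[i - 1] == f[j - 1]) -match else -mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], Fm[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  -best
}
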