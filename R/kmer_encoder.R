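#' Deterministic k-mer-profile hash encoder
#'
#' A training-free encoder used to exercise the sharding / retrieval /
#' fine-alignment plumbing independently of representation learning: each
#' sequence is mapped to the L2-normalized signed-hash ("feature hashing")
#' projection of its k-mer count profile.  A read that is a substring of a
#' fragment shares almost all of its k-mers with it, so cosine distance
#' ranks containing fragments first.  Deterministic given `(k, dim, seed)`.
#'
#' @param k k-mer length.
#' @param dim embedding dimension.
#' @param seed seed fixing the hash bucket and sign assignment.
#' @return a `kmer_encoder` object usable with [embed_sequences()].
#' @export
kmer_encoder <- function(k = 6L, dim = 256L, seed = 1L) {
  k <- as.integer(k); dim <- as.integer(dim)
  stopifnot(k >= 1, k <= 12, dim >= 2)
  n_kmers <- 4L^k
  with_seed(seed, {
    bucket <- sample.int(dim, n_kmers, replace = TRUE)
    sign <- sample(c(-1, 1), n_kmers, replace = TRUE)
  })
  structure(list(k = k, dim = dim, seed = as.integer(seed),
                 bucket = bucket, sign = sign),
            class = "kmer_encoder")
}

#' @export
print.kmer_encoder <- function(x, ...) {
  cat("k-mer profile hash encoder: k =", x$k, "-> R^", x$dim,
      "(seed", x$seed, ")\n")
  invisible(x)
}

# Base-4 integer codes of all k-mers of `seq` (1-based kmer index).
kmer_codes <- function(seq, k) {
  v <- match(strsplit(seq, "", fixed = TRUE)[[1]], BASES) - 1L
  if (anyNA(v)) stop("sequence contains a character outside {A,C,G,T}")
  n <- length(v)
  if (n < k) return(integer(0))
  code <- v[seq_len(n - k + 1L)]
  for (j in seq_len(k - 1L)) code <- code * 4L + v[(1L + j):(n - k + 1L + j)]
  code + 1L
}

#' @rdname embed_sequences
#' @export
embed_sequences.kmer_encoder <- function(encoder, seqs, ...) {
  out <- matrix(0, nrow = length(seqs), ncol = encoder$dim)
  for (i in seq_along(seqs)) {
    codes <- kmer_codes(seqs[i], encoder$k)
    if (length(codes) == 0) stop("sequence shorter than k")
    v <- vapply(split(encoder$sign[codes], encoder$bucket[codes]), sum,
                numeric(1))
    row <- numeric(encoder$dim)
    row[as.integer(names(v))] <- v
    out[i, ] <- row / max(sqrt(sum(row^2)), 1e-12)
  }
  out
}
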