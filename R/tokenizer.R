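#' Train a byte-pair-encoding vocabulary over DNA
#'
#' Classic BPE: starting from the four single bases, the most frequent
#' adjacent token pair is merged repeatedly until `vocab_size` entries exist
#' (or no pair occurs twice).  Frequency ties are broken by the
#' lexicographically smallest merged string, so training is deterministic for
#' a fixed corpus.  The four single bases are always retained, guaranteeing
#' that any `{A,C,G,T}` string can be segmented without unknown tokens.
#'
#' Ids are dense and 0-based: `<pad>`=0, `<unk>`=1, `<cls>`=2, then `A`,`C`,
#' `G`,`T`, then merged tokens in merge order.
#'
#' @param corpus character vector of training sequences over `{A,C,G,T}`.
#' @param vocab_size maximum vocabulary size including the three specials
#'   (default 10000).
#' @param seed reserved for corpus subsampling by callers; the merge loop
#'   itself is deterministic.
#' @return a `DnaTokenizer`.
#' @export
train_vocab <- function(corpus, vocab_size = 10000L, seed = 1L) {
  if (length(corpus) == 0 || all(!nzchar(corpus))) stop("empty corpus")
  vocab_size <- as.integer(vocab_size)
  if (vocab_size < 8L) stop("vocab_size must be at least 8 (specials + bases)")
  n_merges <- vocab_size - 7L
  toks <- bpe_train_cpp(corpus, n_merges)
  dna_tokenizer(c("<pad>", "<unk>", "<cls>", toks))
}

# Internal constructor; `tokens` must start with the three specials followed
# by the four bases.
dna_tokenizer <- function(tokens) {
  stopifnot(identical(tokens[1:7], c("<pad>", "<unk>", "<cls>",
                                     "A", "C", "G", "T")))
  structure(list(tokens = tokens,
                 specials = c(pad = 0L, unk = 1L, cls = 2L),
                 vocab_size = length(tokens),
                 max_token_len = max(nchar(tokens[-(1:3)]))),
            class = "DnaTokenizer")
}

#' @export
print.DnaTokenizer <- function(x, ...) {
  cat("DnaTokenizer:", x$vocab_size, "tokens (3 specials), longest token",
      x$max_token_len, "bp\n")
  invisible(x)
}

#' Encode sequences to token ids
#'
#' Greedy longest-match segmentation over the vocabulary trie; lossless
#' (`tok_decode(tok_encode(s)) == s`) because single bases are always present.
#'
#' @param tokenizer a `DnaTokenizer`.
#' @param seqs character vector over `{A,C,G,T}`.
#' @return list of 0-based integer id vectors (empty vector for `""`).
#' @export
tok_encode <- function(tokenizer, seqs) {
  stopifnot(inherits(tokenizer, "DnaTokenizer"))
  out <- vector("list", length(seqs))
  nz <- nzchar(seqs)
  if (any(nz)) {
    seq_tokens <- tokenizer$tokens[-(1:3)]
    ids <- seq_along(seq_tokens) + 2L  # 0-based ids 3..V-1
    out[nz] <- bpe_encode_cpp(seqs[nz], seq_tokens, ids)
  }
  out[!nz] <- list(integer(0))
  out
}

#' Decode token ids back to a sequence
#'
#' @param tokenizer a `DnaTokenizer`.
#' @param ids 0-based integer id vector; `<pad>` ids are dropped, other
#'   special ids are an error.
#' @return a single character string.
#' @export
tok_decode <- function(tokenizer, ids) {
  stopifnot(inherits(tokenizer, "DnaTokenizer"))
  if (length(ids) == 0) return("")
  ids <- ids[ids != tokenizer$specials[["pad"]]]
  if (any(ids < 0 | ids >= tokenizer$vocab_size)) stop("token id out of range")
  if (any(ids %in% tokenizer$specials[c("unk", "cls")]))
    stop("cannot decode special token")
  paste(tokenizer$tokens[ids + 1L], collapse = "")
}

#' Serialize / restore a tokenizer as JSON
#'
#' @param tokenizer a `DnaTokenizer`.
#' @param path JSON path.
#' @export
tokenizer_save <- function(tokenizer, path) {
  stopifnot(inherits(tokenizer, "DnaTokenizer"))
  jsonlite::write_json(list(tokens = tokenizer$tokens), path)
  invisible(path)
}

#' @rdname tokenizer_save
#' @export
tokenizer_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dna_tokenizer(obj$tokens)
}
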