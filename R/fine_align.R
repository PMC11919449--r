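#' Smith-Waterman scoring scheme (minimization convention)
#'
#' Lower scores are better: match contributes `match` (< 0), mismatch
#' `mismatch` (>= 0), and an affine gap is charged `gap_open` on its first
#' base and `gap_extend` on each subsequent base.  The defaults are the
#' benchmark settings: match -2, mismatch +1, open +0.5, extend +0.1.
#'
#' @param match match score (negative).
#' @param mismatch mismatch penalty (non-negative).
#' @param gap_open,gap_extend affine gap penalties (non-negative).
#' @return a `ScoringScheme`.
#' @export
scoring_scheme <- function(match = -2, mismatch = 1, gap_open = 0.5,
                           gap_extend = 0.1) {
  if (!(match < 0 && mismatch >= 0)) stop("need match < 0 <= mismatch")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "ScoringScheme")
}

#' Align a read against one fragment
#'
#' Local alignment minimizing the total score (realized internally by
#' negating the scheme and running a maximizing affine-gap Gotoh
#' recurrence).  Ties on the optimal score resolve to the smallest fragment
#' offset.
#'
#' @param read,fragment_seq sequences over `{A,C,G,T}`.
#' @param scheme a [scoring_scheme()].
#' @return list with `v` (optimal score, lower is better), `offset`
#'   (0-based fragment position where the aligned region begins),
#'   `frag_end`, `read_begin`, `read_end` (half-open), and a SAM `cigar`
#'   with soft clips.
#' @export
sw_align <- function(read, fragment_seq, scheme = scoring_scheme()) {
  if (!nzchar(read) || !nzchar(fragment_seq)) stop("empty sequence")
  sw_align_cpp(read, fragment_seq, scheme$match, scheme$mismatch,
               scheme$gap_open, scheme$gap_extend)
}

#' Normalized distance of an alignment score from the optimum
#'
#' `d_SW = (v - m*Q) / ((n - m) * Q)` where `m` is the match score, `n` the
#' mismatch penalty, and `Q` the read length; 0 for a perfect full-length
#' match, and roughly the mismatch fraction for substitution-only
#' differences.
#'
#' @param v optimal SW score for the read.
#' @param Q read length.
#' @param scheme a [scoring_scheme()].
#' @return the normalized fraction (>= 0 up to numerical noise).
#' @export
compute_d_sw <- function(v, Q, scheme = scoring_scheme()) {
  if (Q < 1) stop("Q must be >= 1")
  (v - scheme$match * Q) / ((scheme$mismatch - scheme$match) * Q)
}

#' Best alignment of a read over a slate of retrieved fragments
#'
#' Scores the read (and optionally its reverse complement) against every
#' hit, keeps the minimum score, and reconstructs the global position
#' `q* = offset + fragment_start`.  Ties on the optimal score are broken by
#' (chromosome order, global position) and flagged.
#'
#' @param read_seq the read sequence.
#' @param hits a non-empty hit table from [query()] (needs `chrom`,
#'   `start0`, `seq`, and optionally `frag_id`).
#' @param scheme a [scoring_scheme()].
#' @param search_rc also align the reverse complement and keep the better
#'   orientation.
#' @param chrom_levels chromosome order for tie-breaking (defaults to order
#'   of appearance in `hits`).
#' @return an `AlignmentResult`: `frag_id`, `chrom`, `frag_start0`, `v_star`,
#'   `offset`, `q_star`, `d_sw`, `strand`, `tie`, `cigar`, `read_begin`,
#'   `read_end`.
#' @export
best_alignment <- function(read_seq, hits, scheme = scoring_scheme(),
                           search_rc = FALSE, chrom_levels = NULL) {
  if (is.null(hits) || nrow(hits) == 0) stop("empty hit list")
  if (is.null(chrom_levels)) chrom_levels <- unique(hits$chrom)
  Q <- nchar(read_seq)
  scores <- sw_score_batch_cpp(read_seq, hits$seq, scheme$match,
                               scheme$mismatch, scheme$gap_open,
                               scheme$gap_extend)
  strands <- rep("+", nrow(hits))
  if (search_rc) {
    rc <- revcomp(read_seq)
    scores_rc <- sw_score_batch_cpp(rc, hits$seq, scheme$match,
                                    scheme$mismatch, scheme$gap_open,
                                    scheme$gap_extend)
    scores <- c(scores, scores_rc)
    strands <- c(strands, rep("-", nrow(hits)))
  }
  eps <- 1e-6
  vmin <- min(scores)
  tied <- which(scores <= vmin + eps)
  cand <- lapply(tied, function(i) {
    h <- hits[(i - 1L) %% nrow(hits) + 1L, ]
    qseq <- if (strands[i] == "+") read_seq else revcomp(read_seq)
    aln <- sw_align_cpp(qseq, h$seq, scheme$match, scheme$mismatch,
                        scheme$gap_open, scheme$gap_extend)
    list(hit = h, strand = strands[i], aln = aln,
         q_star = h$start0 + aln$offset)
  })
  co <- vapply(cand, function(x) match(x$hit$chrom, chrom_levels), integer(1))
  qs <- vapply(cand, function(x) x$q_star, numeric(1))
  pick <- order(co, qs)[1]
  best <- cand[[pick]]
  tie <- length(unique(paste(co, qs))) > 1
  structure(list(frag_id = best$hit$frag_id %||% NA_character_,
                 chrom = best$hit$chrom, frag_start0 = best$hit$start0,
                 v_star = best$aln$v, offset = best$aln$offset,
                 q_star = best$q_star,
                 d_sw = compute_d_sw(best$aln$v, Q, scheme),
                 strand = best$strand, tie = tie, cigar = best$aln$cigar,
                 read_begin = best$aln$read_begin,
                 read_end = best$aln$read_end),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult: %s:%d (%s)  v*=%.1f  d_sw=%.4f%s\n",
              x$chrom, x$q_star, x$strand, x$v_star, x$d_sw,
              if (x$tie) "  [tie]" else ""))
  invisible(x)
}

#' Write alignments as SAM
#'
#' One record per read; 1-based `POS` from `q*`, CIGAR from the DP
#' traceback, optimal score and normalized distance in the custom tags
#' `ZS:f` and `ZD:f`.  Reads with no alignment get the unmapped flag.
#' Reverse-strand alignments store the reverse-complemented sequence with
#' reversed qualities, per SAM convention.
#'
#' @param results list of `AlignmentResult` (or `NULL` for unaligned),
#'   parallel to `reads`.
#' @param reads the `ReadSet` that was aligned.
#' @param genome the reference, for `@SQ` header lines.
#' @param path output SAM path.
#' @export
write_sam <- function(results, reads, genome, path) {
  stopifnot(length(results) == nrow(reads))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           vapply(names(genome$chromosomes), function(nm) {
             sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(genome$chromosomes[[nm]]))
           }, character(1)),
           "@PG\tID:esalign\tPN:esalign")
  rec <- vapply(seq_len(nrow(reads)), function(i) {
    r <- results[[i]]
    if (is.null(r)) {
      return(paste(reads$read_id[i], 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                   reads$seq[i], reads$qual[i], sep = "\t"))
    }
    flag <- if (r$strand == "-") 16L else 0L
    seq <- if (flag == 16L) revcomp(reads$seq[i]) else reads$seq[i]
    qual <- if (flag == 16L)
      paste(rev(strsplit(reads$qual[i], "", fixed = TRUE)[[1]]), collapse = "")
    else reads$qual[i]
    paste(reads$read_id[i], flag, r$chrom, r$q_star + 1L, 255L, r$cigar, "*",
          0L, 0L, seq, qual,
          sprintf("ZS:f:%g\tZD:f:%g", r$v_star, r$d_sw), sep = "\t")
  }, character(1))
  writeLines(c(hdr, rec), path)
  invisible(path)
}
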