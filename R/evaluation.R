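#' Judge one alignment against its ground truth
#'
#' Success criteria:
#' * `exact_location`: same chromosome, same strand (when both sides carry
#'   one), and `|q* - qhat*| <= tolerance` (default 2, absorbing soft-clip
#'   end effects from mutations at read ends);
#' * `d_sw_bound`: `d_sw <= bound` regardless of position, which credits
#'   optimal alignments to a different copy of a repeat;
#' * `either`: logical OR of the two.
#'
#' @param result an `AlignmentResult`.
#' @param truth list/row with `chrom`, `start0`, and optionally `strand`.
#' @param criterion one of `"either"`, `"exact_location"`, `"d_sw_bound"`.
#' @param d_sw_bound distance bound (default 0.02).
#' @param tolerance positional tolerance in bases (default 2).
#' @return logical success flag.
#' @export
judge <- function(result, truth,
                  criterion = c("either", "exact_location", "d_sw_bound"),
                  d_sw_bound = 0.02, tolerance = 2L) {
  criterion <- match.arg(criterion)
  if (is.null(truth) || is.null(truth$chrom) || is.na(truth$chrom) ||
      is.null(truth$start0) || is.na(truth$start0))
    stop("missing truth record")
  strand_ok <- TRUE
  if (!is.null(truth$strand) && !is.na(truth$strand) &&
      !is.null(result$strand))
    strand_ok <- identical(result$strand, truth$strand)
  exact <- identical(result$chrom, truth$chrom) && strand_ok &&
    abs(result$q_star - truth$start0) <= tolerance
  dsw <- result$d_sw <= d_sw_bound + 1e-12
  switch(criterion, exact_location = exact, d_sw_bound = dsw,
         either = exact || dsw)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Computed from Beta-distribution quantiles; the lower bound is 0 when
#' there are no successes and the upper bound 1 when all trials succeed.
#'
#' @param successes,n success and trial counts.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)`.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("successes must be in [0, n]")
  a <- 1 - level
  lo <- if (successes == 0) 0 else qbeta(a / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else qbeta(1 - a / 2, successes + 1, n - successes)
  c(lo, hi)
}

#' Evaluate recall of the full embed-search-align loop
#'
#' For every read: embed, retrieve the top-K fragments (per chromosome when
#' the diversity prior is on), fine-align the slate, and judge the result
#' against the truth table.  Both sub-verdicts (exact location and distance
#' bound) are logged per read; the reported recall uses `criterion`.
#'
#' @param reads a `ReadSet` with truth columns.
#' @param store a `VectorStore` over the same genome.
#' @param encoder the encoder the store was built with.
#' @param K retrieved fragments per chromosome (or in total when
#'   `diversity = FALSE`).
#' @param criterion,d_sw_bound,tolerance see [judge()].
#' @param scheme a [scoring_scheme()].
#' @param diversity apply the per-chromosome retrieval prior.
#' @param search_rc align both orientations; default: only when the truth
#'   table contains reverse-strand reads.
#' @param level confidence level of the Clopper-Pearson interval.
#' @return a `RecallReport`: counts, recall, exact binomial CI, parameters,
#'   and a `per_read` data frame
#'   (`read_id`, `chrom`, `q_star`, `v_star`, `d_sw`, `success_exact`,
#'   `success_dsw`, `success`).
#' @export
evaluate <- function(reads, store, encoder, K = 50L,
                     criterion = c("either", "exact_location", "d_sw_bound"),
                     d_sw_bound = 0.02, tolerance = 2L,
                     scheme = scoring_scheme(), diversity = TRUE,
                     search_rc = NULL, level = 0.95) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(store, "VectorStore"))
  if (anyNA(reads$chrom) || anyNA(reads$start0))
    stop("reads lack truth records; evaluation needs simulated reads")
  if (is.null(search_rc)) search_rc <- any(reads$strand == "-", na.rm = TRUE)
  embs <- embed_sequences(encoder, reads$seq)
  embs_rc <- if (search_rc) embed_sequences(encoder, revcomp(reads$seq)) else NULL
  n <- nrow(reads)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- query(store, embs[i, ], K = K, diversity = diversity)
    if (search_rc) {
      # a reverse-strand read only resembles fragments through its
      # reverse complement, so both orientations contribute candidates
      hits_rc <- query(store, embs_rc[i, ], K = K, diversity = diversity)
      hits <- rbind(hits, hits_rc[!hits_rc$frag_id %in% hits$frag_id, ])
    }
    res <- best_alignment(reads$seq[i], hits, scheme = scheme,
                          search_rc = search_rc,
                          chrom_levels = store$chrom_levels)
    truth <- list(chrom = reads$chrom[i], start0 = reads$start0[i],
                  strand = if (search_rc) reads$strand[i] else NA)
    ok_exact <- judge(res, truth, "exact_location", d_sw_bound, tolerance)
    ok_dsw <- judge(res, truth, "d_sw_bound", d_sw_bound, tolerance)
    rows[[i]] <- data.frame(read_id = reads$read_id[i], chrom = res$chrom,
                            q_star = res$q_star, v_star = res$v_star,
                            d_sw = res$d_sw,
                            success_exact = ok_exact, success_dsw = ok_dsw,
                            success = switch(criterion,
                                             exact_location = ok_exact,
                                             d_sw_bound = ok_dsw,
                                             either = ok_exact || ok_dsw),
                            stringsAsFactors = FALSE)
  }
  per_read <- do.call(rbind, rows)
  n_success <- sum(per_read$success)
  structure(list(n_reads = n, n_success = n_success,
                 recall = n_success / n,
                 ci = clopper_pearson(n_success, n, level),
                 criterion = criterion,
                 parameters = list(K = K, d_sw_bound = d_sw_bound,
                                   tolerance = tolerance, level = level,
                                   diversity = diversity,
                                   search_rc = search_rc),
                 per_read = per_read),
            class = "RecallReport")
}

#' @export
print.RecallReport <- function(x, ...) {
  cat(sprintf(
    "RecallReport: %d/%d reads (recall %.4f, %d%% CI [%.4f, %.4f])\n",
    x$n_success, x$n_reads, x$recall, round(100 * x$parameters$level),
    x$ci[1], x$ci[2]))
  cat("  criterion:", x$criterion, " K:", x$parameters$K,
      " d_SW bound:", x$parameters$d_sw_bound, "\n")
  invisible(x)
}

#' Write a recall report (aggregate JSON + per-read TSV)
#'
#' @param report a `RecallReport`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @export
write_report <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "RecallReport"))
  if (!is.null(json_path)) {
    agg <- report[c("n_reads", "n_success", "recall", "criterion",
                    "parameters")]
    agg$ci_lo <- report$ci[1]; agg$ci_hi <- report$ci[2]
    jsonlite::write_json(agg, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path))
    write.table(report$per_read, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(report)
}
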