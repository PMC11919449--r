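#' Simulator configuration
#'
#' Parameters of the ART-like read simulator.  Per-base Phred scores are
#' drawn uniformly from `phred_range`; each base is substituted with
#' probability `10^(-phred/10)`; insertions and deletions are position-wise
#' Bernoulli events at rates `ins_rate` / `del_rate`, after which the read is
#' cropped (or extended from the reference) back to exactly `Q` bases.
#' The defaults mirror the benchmark conditions this package evaluates
#' under: 250-bp MiSeq-like reads, indel rates of 1e-2, and the middle
#' Phred band `[30,60]` of the three canonical bands `[10,30]`, `[30,60]`,
#' `[60,90]`.
#'
#' @param Q read length (bp).
#' @param phred_range integer `c(lo, hi)` of per-base Phred scores.
#' @param ins_rate,del_rate per-position insertion / deletion probabilities.
#' @param n_reads number of reads to simulate.
#' @param strand_mode `"forward_only"` or `"both"` (fair coin per read,
#'   reverse-complemented with the strand recorded in the truth table).
#' @param seed RNG seed.
#' @return a `SimulatorConfig` list.
#' @export
simulator_config <- function(Q = 250L, phred_range = c(30L, 60L),
                             ins_rate = 0.01, del_rate = 0.01,
                             n_reads = 1000L,
                             strand_mode = c("forward_only", "both"),
                             seed = 1L) {
  strand_mode <- match.arg(strand_mode)
  Q <- as.integer(Q)
  phred_range <- as.integer(phred_range)
  if (Q < 1) stop("Q must be >= 1")
  if (length(phred_range) != 2 || phred_range[1] > phred_range[2] ||
      phred_range[1] < 0)
    stop("phred_range must be c(lo, hi) with 0 <= lo <= hi")
  if (ins_rate < 0 || ins_rate > 1 || del_rate < 0 || del_rate > 1)
    stop("indel rates must be in [0, 1]")
  if (n_reads < 1) stop("n_reads must be >= 1")
  structure(list(Q = Q, phred_range = phred_range, ins_rate = ins_rate,
                 del_rate = del_rate, n_reads = as.integer(n_reads),
                 strand_mode = strand_mode, seed = as.integer(seed)),
            class = "SimulatorConfig")
}

# Apply the noise walk to a reference window: per position, an insertion
# (random base, does not consume the window) may precede the position's
# base, which is itself emitted unless deleted.  Returns the first Q bases.
noise_walk <- function(window, Q, ins_rate, del_rate) {
  refv <- strsplit(window, "", fixed = TRUE)[[1]]
  n <- length(refv)
  ins <- if (ins_rate > 0) runif(n) < ins_rate else rep(FALSE, n)
  del <- if (del_rate > 0) runif(n) < del_rate else rep(FALSE, n)
  e1 <- rep(NA_character_, n)
  if (any(ins)) e1[ins] <- BASES[sample.int(4L, sum(ins), replace = TRUE)]
  e2 <- refv
  e2[del] <- NA_character_
  out <- as.vector(rbind(e1, e2))
  out <- out[!is.na(out)]
  if (length(out) < Q)  # window exhausted by deletions: pad with random bases
    out <- c(out, BASES[sample.int(4L, Q - length(out), replace = TRUE)])
  out[seq_len(Q)]
}

#' Simulate reads with Phred-governed noise and ground truth
#'
#' Start positions are uniform over all valid positions genome-wide
#' (chromosomes weighted by their number of length-`Q` windows).  The truth
#' table records the pre-noise origin: chromosome, 0-based forward-strand
#' start, and strand.
#'
#' @param genome a [reference_genome()].
#' @param config a [simulator_config()].
#' @return a `ReadSet`: a data frame with columns `read_id`, `seq`, `qual`
#'   (Phred+33 string), `chrom`, `start0`, `strand`.
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(inherits(genome, "ReferenceGenome"),
            inherits(config, "SimulatorConfig"))
  Q <- config$Q
  lens <- nchar(genome$chromosomes)
  if (any(lens < Q))
    stop("chromosome shorter than read length Q=", Q, ": ",
         paste(names(lens)[lens < Q], collapse = ", "))
  nm <- names(genome$chromosomes)
  with_seed(config$seed, {
    n <- config$n_reads
    ci <- sample.int(length(lens), n, replace = TRUE, prob = lens - Q + 1)
    q <- vapply(ci, function(i) sample.int(lens[i] - Q + 1L, 1L) - 1L, integer(1))
    strand <- if (config$strand_mode == "both")
      sample(c("+", "-"), n, replace = TRUE) else rep("+", n)
    slack <- 60L + as.integer(ceiling(4 * Q * config$del_rate))
    seqs <- character(n); quals <- character(n)
    for (i in seq_len(n)) {
      len <- lens[ci[i]]
      window <- if (strand[i] == "+") {
        genome_slice(genome, nm[ci[i]], q[i], min(Q + slack, len - q[i]))
      } else {
        revcomp(genome_slice(genome, nm[ci[i]], max(q[i] - slack, 0L),
                             q[i] + Q - max(q[i] - slack, 0L)))
      }
      base <- noise_walk(window, Q, config$ins_rate, config$del_rate)
      phred <- config$phred_range[1] +
        sample.int(config$phred_range[2] - config$phred_range[1] + 1L, Q,
                   replace = TRUE) - 1L
      sub <- runif(Q) < 10^(-phred / 10)
      if (any(sub)) {
        cur <- match(base[sub], BASES)
        base[sub] <- BASES[(cur - 1L + sample.int(3L, sum(sub), replace = TRUE)) %% 4L + 1L]
      }
      seqs[i] <- paste(base, collapse = "")
      quals[i] <- intToUtf8(phred + 33L)
    }
    structure(data.frame(read_id = sprintf("read_%05d", seq_len(n)),
                         seq = seqs, qual = quals, chrom = nm[ci],
                         start0 = q, strand = strand,
                         stringsAsFactors = FALSE),
              class = c("ReadSet", "data.frame"), Q = Q)
  })
}

#' Write reads as FASTQ (Phred+33) with a truth-table sidecar
#'
#' @param reads a `ReadSet`.
#' @param path output FASTQ path.
#' @param truth_path optional TSV path for the ground-truth table
#'   (`read_id`, `chrom`, `start0`, `strand`); defaults to
#'   `<path>.truth.tsv` when truth is present.
#' @export
write_fastq <- function(reads, path, truth_path = NULL) {
  stopifnot(is.data.frame(reads))
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$read_id
  Biostrings::writeXStringSet(set, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  if (!is.null(reads$chrom) && !all(is.na(reads$chrom))) {
    if (is.null(truth_path)) truth_path <- paste0(path, ".truth.tsv")
    write.table(reads[, c("read_id", "chrom", "start0", "strand")],
                truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a FASTQ file (optionally joining a truth table)
#'
#' @param path FASTQ path.
#' @param truth_path optional truth TSV written by [write_fastq()].
#' @return a `ReadSet` (truth columns `NA` when no table is supplied).
#' @export
read_fastq <- function(path, truth_path = NULL) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  reads <- data.frame(read_id = names(set),
                      seq = as.character(set),
                      qual = as.character(S4Vectors::mcols(set)$qualities),
                      chrom = NA_character_, start0 = NA_integer_,
                      strand = NA_character_, stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  if (!is.null(truth_path)) {
    truth <- read.delim(truth_path, stringsAsFactors = FALSE)
    m <- match(reads$read_id, truth$read_id)
    if (anyNA(m)) stop("truth table is missing reads: ",
                       paste(head(reads$read_id[is.na(m)]), collapse = ", "))
    reads$chrom <- truth$chrom[m]
    reads$start0 <- truth$start0[m]
    reads$strand <- truth$strand[m]
  }
  structure(reads, class = c("ReadSet", "data.frame"),
            Q = max(nchar(reads$seq)))
}
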