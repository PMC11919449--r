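genome_5k <- generate_synthetic_genome(c(3000, 2000), seed = 11)

test_that("noise-free reads are exact substrings at their recorded origin", {
  sc <- simulator_config(Q = 100, phred_range = c(90, 90), ins_rate = 0,
                         del_rate = 0, n_reads = 60, strand_mode = "both",
                         seed = 2)
  reads <- simulate_reads(genome_5k, sc)
  for (i in seq_len(nrow(reads))) {
    ref <- substr(genome_5k$chromosomes[[reads$chrom[i]]],
                  reads$start0[i] + 1, reads$start0[i] + 100)
    if (reads$strand[i] == "-") ref <- esalign:::revcomp(ref)
    expect_identical(reads$seq[i], ref)
  }
  expect_true(all(reads$start0 >= 0))
  expect_true(all(reads$start0 + 100 <=
                    nchar(genome_5k$chromosomes)[match(reads$chrom,
                                                       names(genome_5k$chromosomes))]))
})

test_that("high-quality settings give >= 99.9% base identity", {
  sc <- simulator_config(Q = 250, phred_range = c(60, 90), ins_rate = 0,
                         del_rate = 0, n_reads = 200, seed = 3)
  reads <- simulate_reads(genome_5k, sc)
  ref <- vapply(seq_len(nrow(reads)), function(i) {
    substr(genome_5k$chromosomes[[reads$chrom[i]]],
           reads$start0[i] + 1, reads$start0[i] + 250)
  }, character(1))
  match_frac <- mean(mapply(function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }, reads$seq, ref))
  expect_gte(match_frac, 0.999)
})

test_that("substitution counts follow the Phred error model", {
  # Phred fixed at 20 => p = 0.01, expected 2.5 substitutions per 250-bp read
  sc <- simulator_config(Q = 250, phred_range = c(20, 20), ins_rate = 0,
                         del_rate = 0, n_reads = 1000, seed = 4)
  reads <- simulate_reads(genome_5k, sc)
  subs <- vapply(seq_len(nrow(reads)), function(i) {
    ref <- substr(genome_5k$chromosomes[[reads$chrom[i]]],
                  reads$start0[i] + 1, reads$start0[i] + 250)
    sum(strsplit(reads$seq[i], "")[[1]] != strsplit(ref, "")[[1]])
  }, numeric(1))
  expect_gt(mean(subs), 2.0)   # 2.5 +- 3 sigma over the simulation
  expect_lt(mean(subs), 3.0)
})

test_that("indel noise preserves the exact read length", {
  sc <- simulator_config(Q = 250, phred_range = c(30, 60), ins_rate = 0.01,
                         del_rate = 0.01, n_reads = 300, seed = 5)
  reads <- simulate_reads(genome_5k, sc)
  expect_true(all(nchar(reads$seq) == 250))
  expect_true(all(nchar(reads$qual) == 250))
  # same seed reproduces bit-identically
  reads2 <- simulate_reads(genome_5k, sc)
  expect_identical(reads, reads2)
})

test_that("FASTQ round-trips with Phred+33 qualities and a truth sidecar", {
  sc <- simulator_config(Q = 80, n_reads = 40, strand_mode = "both", seed = 6)
  reads <- simulate_reads(genome_5k, sc)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  truth <- paste0(fq, ".truth.tsv")
  expect_true(file.exists(truth))
  expect_identical(nrow(read.delim(truth)), 40L)
  back <- read_fastq(fq, truth_path = truth)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$qual, reads$qual)
  expect_identical(back$start0, reads$start0)
  expect_identical(back$strand, reads$strand)
  # Phred 0 encodes as '!'
  one <- data.frame(read_id = "r1", seq = "ACGT",
                    qual = intToUtf8(c(0, 20, 40, 0) + 33),
                    chrom = NA, start0 = NA, strand = NA)
  write_fastq(one, fq)
  expect_identical(readLines(fq)[4], "!5I!")
  expect_error(simulate_reads(genome_5k,
                              simulator_config(Q = 2500, n_reads = 1)),
               "shorter than read length")
})
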