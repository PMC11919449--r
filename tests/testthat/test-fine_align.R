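test_that("perfect and contained matches score m*Q at the right offset", {
  withr::local_seed(1)
  r <- rand_dna(250)
  a <- sw_align(r, r)
  expect_equal(a$v, -500)
  expect_identical(a$offset, 0L)
  expect_identical(a$cigar, "250M")
  frag <- paste0(rand_dna(100), r, rand_dna(120))
  a2 <- sw_align(r, frag)
  expect_equal(a2$v, -2 * 250)
  expect_identical(a2$offset, 100L)
  # one mid-read substitution costs n - m = 3
  a3 <- sw_align(mutate_at(r, 125), frag)
  expect_equal(a3$v, -497)
  expect_error(sw_align("", "ACGT"), "empty")
})

test_that("scores agree exactly with an independent brute-force DP oracle", {
  withr::local_seed(42)
  for (i in 1:200) {
    rl <- sample(5:30, 1); fl <- sample(10:60, 1)
    frag <- rand_dna(fl)
    # half the pairs share a (possibly mutated) substring, half are random
    r <- if (i %% 2 == 0 && fl > rl) {
      s <- sample(fl - rl + 1, 1)
      x <- substr(frag, s, s + rl - 1)
      if (i %% 4 == 0) mutate_at(x, sample(rl, min(2, rl))) else x
    } else rand_dna(rl)
    got <- sw_score_batch_cpp(r, frag, -2, 1, 0.5, 0.1)
    expect_equal(got, sw_oracle(r, frag), tolerance = 1e-9)
    expect_equal(sw_align(r, frag)$v, got, tolerance = 1e-9)
  }
})

test_that("scores agree with Biostrings pairwiseAlignment on affine local alignment", {
  # independent library cross-check; gap length L costs 0.5 + 0.1(L-1)
  # = 0.4 + 0.1 L, i.e. gapOpening 0.4 / gapExtension 0.1 in Biostrings terms
  submat <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T")))
  diag(submat) <- 2
  withr::local_seed(7)
  for (i in 1:40) {
    r <- rand_dna(sample(8:25, 1))
    f <- rand_dna(sample(20:60, 1))
    ours <- sw_score_batch_cpp(r, f, -2, 1, 0.5, 0.1)
    theirs <- Biostrings::pairwiseAlignment(r, f, type = "local",
                                            substitutionMatrix = submat,
                                            gapOpening = 0.4,
                                            gapExtension = 0.1,
                                            scoreOnly = TRUE)
    expect_equal(ours, -theirs, tolerance = 1e-6)  # Biostrings uses float32
  }
})

test_that("substitutions never improve the alignment score", {
  withr::local_seed(3)
  frag <- rand_dna(400)
  r <- substr(frag, 51, 300)
  pos <- sample(250, 12)
  prev <- sw_align(r, frag)$v
  for (k in seq_along(pos)) {
    v <- sw_align(mutate_at(r, pos[seq_len(k)]), frag)$v
    expect_gte(v, prev - 1e-9)
    prev <- v
  }
})

test_that("the d_SW formula evaluates exactly", {
  expect_equal(compute_d_sw(-500, 250), 0)
  expect_equal(compute_d_sw(-497, 250), 3 / 750)
  expect_equal(compute_d_sw(-485, 250), 0.02)
  expect_error(compute_d_sw(-500, 0), "Q must be")
  expect_error(scoring_scheme(match = 1), "match")
})

test_that("local alignment soft-clips noisy read ends in the CIGAR", {
  withr::local_seed(9)
  frag <- rand_dna(500)
  core <- substr(frag, 101, 340)  # 240 matching bases
  # flanks guaranteed to mismatch the fragment continuation base by base
  flank <- function(pos) paste(vapply(pos, function(p) {
    setdiff(c("A", "C", "G", "T"), substr(frag, p, p))[1]
  }, character(1)), collapse = "")
  read <- paste0(flank(96:100), core, flank(341:345))
  # under a scheme where gaps are expensive, mismatching flanks are clipped
  stiff <- scoring_scheme(match = -2, mismatch = 1, gap_open = 5,
                          gap_extend = 2)
  a <- sw_align(read, frag, stiff)
  expect_identical(a$offset, 100L)
  expect_identical(a$cigar, "5S240M5S")
  expect_identical(a$read_begin, 5L)
  expect_identical(a$read_end, 245L)
  # under the default cheap-gap scheme the optimum is at least as good as
  # aligning the core alone (gaps may profitably stitch flank bases in)
  b <- sw_align(read, frag)
  expect_lte(b$v, -2 * 240)
})

test_that("best_alignment reconstructs global positions and resolves ties", {
  g <- generate_synthetic_genome(c(8000, 8000),
                                 repeat_spec = list(c(400, 2)), seed = 13)
  frags <- shard(g, frag_len = 1000, overlap = 300)
  # read from inside the first repeat copy
  rp <- g$repeats[order(g$repeats$chrom, g$repeats$start0), ]
  read <- substr(g$chromosomes[[rp$chrom[1]]], rp$start0[1] + 51,
                 rp$start0[1] + 300)
  res <- best_alignment(read, frags, chrom_levels = names(g$chromosomes))
  expect_equal(res$v_star, -500)
  expect_equal(res$d_sw, 0)
  expect_true(res$tie)
  # both copies contain the read; the lower (chrom order, position) wins
  cand <- data.frame(chrom = rp$chrom, q = rp$start0 + 50)
  cand <- cand[order(match(cand$chrom, names(g$chromosomes)), cand$q), ]
  expect_identical(res$chrom, cand$chrom[1])
  expect_equal(res$q_star, cand$q[1])

  # reverse-complement search recovers the forward coordinates
  fwd <- substr(g$chromosomes[["chr1"]], 2001, 2250)
  rc <- esalign:::revcomp(fwd)
  res_rc <- best_alignment(rc, frags, search_rc = TRUE,
                           chrom_levels = names(g$chromosomes))
  expect_identical(res_rc$strand, "-")
  expect_equal(res_rc$q_star, 2000)
  expect_equal(res_rc$v_star, -500)
  expect_error(best_alignment(fwd, frags[0, ]), "empty hit list")
})

test_that("SAM output has one well-formed record per read", {
  g <- generate_synthetic_genome(4000, seed = 17)
  sc <- simulator_config(Q = 100, ins_rate = 0, del_rate = 0,
                         phred_range = c(90, 90), n_reads = 5, seed = 1)
  reads <- simulate_reads(g, sc)
  frags <- shard(g, frag_len = 1000, overlap = 200)
  results <- lapply(seq_len(nrow(reads)), function(i) {
    best_alignment(reads$seq[i], frags, chrom_levels = names(g$chromosomes))
  })
  results[5] <- list(NULL)  # simulate one unaligned read
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(results, reads, g, sam)
  lines <- readLines(sam)
  hdr <- grep("^@", lines, value = TRUE)
  expect_true(any(grepl("^@SQ\tSN:chr1\tLN:4000$", hdr)))
  rec <- strsplit(grep("^@", lines, value = TRUE, invert = TRUE), "\t")
  expect_length(rec, 5)
  for (i in 1:4) {
    expect_identical(rec[[i]][1], reads$read_id[i])
    expect_identical(as.integer(rec[[i]][4]), results[[i]]$q_star + 1L)
    expect_identical(rec[[i]][6], results[[i]]$cigar)
  }
  expect_identical(rec[[5]][2], "4")  # unmapped flag
})
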