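fake_result <- function(chrom = "chr1", q_star = 100, d_sw = 0, strand = "+") {
  structure(list(chrom = chrom, q_star = q_star, d_sw = d_sw,
                 strand = strand), class = "AlignmentResult")
}

test_that("judging applies the positional tolerance and distance bound", {
  truth <- list(chrom = "chr1", start0 = 100, strand = "+")
  expect_true(judge(fake_result(q_star = 100), truth, "exact_location"))
  expect_true(judge(fake_result(q_star = 102), truth, "exact_location"))
  expect_false(judge(fake_result(q_star = 103), truth, "exact_location"))
  expect_false(judge(fake_result(chrom = "chr2"), truth, "exact_location"))
  expect_false(judge(fake_result(strand = "-"), truth, "exact_location"))
  # a perfect-score alignment at a different repeat copy: exact fails,
  # the distance bound succeeds, `either` accepts
  far <- fake_result(q_star = 5000, d_sw = 0)
  expect_false(judge(far, truth, "exact_location"))
  expect_true(judge(far, truth, "d_sw_bound"))
  expect_true(judge(far, truth, "either"))
  expect_false(judge(fake_result(q_star = 5000, d_sw = 0.021), truth,
                     "d_sw_bound", d_sw_bound = 0.02))
  expect_true(judge(fake_result(q_star = 5000, d_sw = 0.02), truth,
                    "d_sw_bound", d_sw_bound = 0.02))
  expect_error(judge(fake_result(), list(chrom = NA, start0 = NA)),
               "missing truth")
})

test_that("Clopper-Pearson intervals match the closed-form edge cases", {
  ci <- clopper_pearson(0, 10, 0.95)
  expect_identical(ci[1], 0)
  expect_equal(ci[2], 1 - 0.025^(1 / 10), tolerance = 1e-12)
  ci2 <- clopper_pearson(10, 10, 0.95)
  expect_equal(ci2[1], 0.025^(1 / 10), tolerance = 1e-12)
  expect_identical(ci2[2], 1)
  ci3 <- clopper_pearson(5, 10, 0.95)
  expect_lt(ci3[1], 0.5)
  expect_gt(ci3[2], 0.5)
  expect_error(clopper_pearson(3, 0), "n must be")
  expect_error(clopper_pearson(11, 10), "successes")
})

test_that("the evaluation loop is exact, monotone in K, and reproducible", {
  g <- generate_synthetic_genome(20000, seed = 41)
  fr <- shard(g, 1000, 250)
  enc <- kmer_encoder(k = 6, dim = 128, seed = 1)
  store <- build_index(fr, enc)
  sc <- simulator_config(Q = 150, phred_range = c(90, 90), ins_rate = 0,
                         del_rate = 0, n_reads = 50, seed = 9)
  reads <- simulate_reads(g, sc)
  rep5 <- evaluate(reads, store, enc, K = 5, criterion = "exact_location")
  expect_identical(rep5$recall, 1)
  expect_identical(rep5$n_success, 50L)
  expect_identical(rep5$ci[2], 1)
  expect_equal(rep5$recall, rep5$n_success / rep5$n_reads)
  expect_gte(rep5$recall, rep5$ci[1])
  # monotone in K
  rep1 <- evaluate(reads, store, enc, K = 1, criterion = "exact_location")
  expect_lte(rep1$recall, rep5$recall)
  # bit-reproducible
  rep5b <- evaluate(reads, store, enc, K = 5, criterion = "exact_location")
  expect_identical(rep5$per_read, rep5b$per_read)
  # report writing
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep5, jp, tp)
  agg <- jsonlite::read_json(jp)
  expect_identical(agg$n_success, 50L)
  expect_identical(nrow(read.delim(tp)), 50L)
  expect_error(evaluate(structure(data.frame(read_id = "r", seq = "ACGT",
                                             qual = "IIII", chrom = NA,
                                             start0 = NA, strand = NA),
                                  class = c("ReadSet", "data.frame")),
                        store, enc), "truth")
})
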