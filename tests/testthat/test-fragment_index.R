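test_that("sharding covers chromosomes with right-anchored terminal fragments", {
  g3k <- reference_genome(c(chrA = rand_dna_fixed(3000, 5)))
  fr <- shard(g3k, frag_len = 1250, overlap = 250)
  expect_identical(fr$start0, c(0L, 1000L, 1750L))
  expect_true(all(fr$length == 1250))
  expect_identical(fr$seq, vapply(fr$start0, function(s)
    substr(g3k$chromosomes[[1]], s + 1, s + 1250), character(1)))
  # every window of length <= overlap is fully contained in some fragment
  contained <- vapply(0:(3000 - 250), function(w) {
    any(fr$start0 <= w & w + 250 <= fr$start0 + fr$length)
  }, logical(1))
  expect_true(all(contained))

  # boundary: chromosome exactly one fragment long
  g1 <- reference_genome(c(c1 = rand_dna_fixed(1250, 6)))
  fr1 <- shard(g1, 1250, 250)
  expect_identical(nrow(fr1), 1L)
  expect_identical(fr1$start0, 0L)
  # short chromosome collapses to one whole-chromosome fragment
  gs <- reference_genome(c(s1 = rand_dna_fixed(700, 7)))
  frs <- shard(gs, 1250, 250)
  expect_identical(frs$length, 700L)
  expect_error(shard(g1, 1000, 1000), "overlap")
})

test_that("closed-form shard counts match materialized plans", {
  g <- generate_synthetic_genome(c(40000, 25600), seed = 23)
  fr <- shard(g, 1250, 250)
  n_formula <- shard_count(40000, 1250, 250) + shard_count(25600, 1250, 250)
  expect_identical(nrow(fr), as.integer(n_formula))
  # coverage (union of fragment intervals is the whole chromosome)
  for (nm in names(g$chromosomes)) {
    f <- fr[fr$chrom == nm, ]
    f <- f[order(f$start0), ]
    expect_identical(f$start0[1], 0L)
    expect_true(all(f$start0[-1] <= (f$start0 + f$length)[-nrow(f)]))
    expect_identical(max(f$start0 + f$length),
                     nchar(g$chromosomes[[nm]]))
  }
})

test_that("the vector store preserves counts and retrieves itself", {
  g <- generate_synthetic_genome(20000, seed = 29)
  fr <- shard(g, 1000, 250)
  enc <- kmer_encoder(k = 5, dim = 64, seed = 1)
  store <- build_index(fr, enc)
  expect_identical(nrow(store$vectors), nrow(fr))
  # querying a stored fragment's own embedding returns it at rank 1, dist 0
  for (i in c(1, 7, nrow(fr))) {
    hits <- query(store, store$vectors[i, ], K = 3)
    expect_identical(hits$frag_id[1], fr$frag_id[i])
    expect_equal(hits$dist[1], 0, tolerance = 1e-12)
  }
  expect_error(query(structure(list(vectors = matrix(0, 0, 2)),
                               class = "VectorStore"), c(1, 0)), "empty")
})

test_that("the diversity prior returns top-K per chromosome", {
  g <- generate_synthetic_genome(c(10000, 10000), seed = 31)
  fr <- shard(g, 1000, 250)
  enc <- kmer_encoder(k = 5, dim = 64, seed = 1)
  store <- build_index(fr, enc)
  q <- embed_sequences(enc, substr(g$chromosomes[[1]], 501, 750))
  hits <- query(store, q[1, ], K = 2, diversity = TRUE)
  expect_lte(nrow(hits), 4)
  expect_true(all(table(hits$chrom) <= 2))
  # saturation: K >= fragments per chromosome returns all of them
  all_hits <- query(store, q[1, ], K = 1000, diversity = TRUE)
  expect_identical(nrow(all_hits), nrow(fr))
  # global top-K mode
  glob <- query(store, q[1, ], K = 3, diversity = FALSE)
  expect_identical(nrow(glob), 3L)
  expect_true(!is.unsorted(glob$dist))

  # single chromosome: diversity on/off agree
  g1 <- generate_synthetic_genome(10000, seed = 33)
  fr1 <- shard(g1, 1000, 250)
  s1 <- build_index(fr1, enc)
  q1 <- embed_sequences(enc, substr(g1$chromosomes[[1]], 2001, 2250))
  expect_identical(query(s1, q1[1, ], K = 4, diversity = TRUE),
                   query(s1, q1[1, ], K = 4, diversity = FALSE))
})

test_that("exact and IVF backends agree on nearly all top-1 hits", {
  withr::local_seed(17)
  n <- 10000; d <- 32
  vec <- matrix(rnorm(n * d), n)
  vec <- vec / sqrt(rowSums(vec^2))
  meta <- data.frame(frag_id = paste0("f", 1:n), chrom = "chr1",
                     start0 = seq_len(n) * 10L, length = 100L, seq = "A")
  mk <- function(backend, ivf = NULL)
    structure(list(vectors = vec, meta = meta, backend = backend, ivf = ivf,
                   chrom_levels = "chr1", frag_len = 100, overlap = 10),
              class = "VectorStore")
  exact <- mk("exact")
  nl <- as.integer(2 * ceiling(sqrt(n)))
  km <- kmeans(vec, centers = nl, iter.max = 25)
  approx <- mk("approx", list(centers = km$centers, assign = km$cluster,
                              n_probe = as.integer(ceiling(0.2 * nl))))
  agree <- 0
  for (i in 1:1000) {
    target <- vec[sample(n, 1), ] + rnorm(d, sd = 0.05)
    target <- target / sqrt(sum(target^2))
    t1 <- query(exact, target, K = 1, diversity = FALSE)$frag_id
    t2 <- query(approx, target, K = 1, diversity = FALSE)$frag_id
    agree <- agree + (t1 == t2)
  }
  expect_gte(agree / 1000, 0.99)
})

test_that("stores persist to flat files and reload against the genome", {
  g <- generate_synthetic_genome(15000, seed = 37)
  fr <- shard(g, 1000, 250)
  enc <- kmer_encoder(k = 5, dim = 48, seed = 2)
  store <- build_index(fr, enc)
  dir <- withr::local_tempdir()
  save_store(store, dir)
  expect_true(all(file.exists(file.path(dir, c("vectors.bin", "meta.tsv",
                                               "manifest.json")))))
  back <- load_store(dir, g)
  expect_equal(back$vectors, store$vectors, ignore_attr = TRUE)
  expect_identical(back$meta$seq, store$meta$seq)
  expect_identical(back$meta$start0, store$meta$start0)
  bed <- file.path(dir, "frags.bed")
  export_fragments_bed(fr, bed)
  b <- read.delim(bed, header = FALSE)
  expect_identical(nrow(b), nrow(fr))
  expect_true(all(b$V3 - b$V2 == fr$length))
})
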