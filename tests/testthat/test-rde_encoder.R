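tiny_cfg <- encoder_config(n_layers = 2, n_heads = 2, model_width = 8,
                           projection_dim = 5, ff_width = 12, dropout = 0,
                           max_tokens = 64)

test_that("analytic gradients match central finite differences", {
  tok <- small_tokenizer(vocab_size = 40, corpus_bp = 5000)
  m <- init_rde(tok, tiny_cfg, seed = 7)
  ccfg <- esalign:::cpp_config(tiny_cfg, tok$vocab_size)
  withr::local_seed(3)
  reads <- vapply(1:3, function(i) rand_dna(12), character(1))
  frags <- vapply(reads, function(r) paste0(r, rand_dna(8)), character(1))
  br <- esalign:::pad_batch(tok, reads, 64)
  bf <- esalign:::pad_batch(tok, frags, 64)
  # double-precision path for clean finite differences
  res <- esalign:::rde_loss_grad_cpp(m$params, ccfg, br$ids, br$lens,
                                     bf$ids, bf$lens, 0.05, 0, 1,
                                     single = FALSE)
  idx <- sample(length(m$params), 80)
  h <- 1e-5
  num <- vapply(idx, function(i) {
    p1 <- m$params; p1[i] <- p1[i] + h
    p2 <- m$params; p2[i] <- p2[i] - h
    l1 <- esalign:::rde_loss_grad_cpp(p1, ccfg, br$ids, br$lens, bf$ids,
                                      bf$lens, 0.05, 0, 1, FALSE, FALSE)$loss
    l2 <- esalign:::rde_loss_grad_cpp(p2, ccfg, br$ids, br$lens, bf$ids,
                                      bf$lens, 0.05, 0, 1, FALSE, FALSE)$loss
    (l1 - l2) / (2 * h)
  }, numeric(1))
  ana <- res$grad[idx]
  expect_lt(max(abs(num - ana) / pmax(abs(num) + abs(ana), 1e-6)), 1e-3)
  # the single-precision default agrees with the double path
  res32 <- esalign:::rde_loss_grad_cpp(m$params, ccfg, br$ids, br$lens,
                                       bf$ids, bf$lens, 0.05, 0, 1)
  expect_equal(res32$loss, res$loss, tolerance = 1e-4)
  expect_lt(max(abs(res32$grad - res$grad)), 1e-3)
})

test_that("evaluation-mode embeddings are deterministic unit vectors", {
  tok <- small_tokenizer(vocab_size = 60, corpus_bp = 5000)
  cfg <- encoder_config(n_layers = 1, n_heads = 2, model_width = 16,
                        projection_dim = 8, ff_width = 16, dropout = 0.1,
                        max_tokens = 128)
  m <- init_rde(tok, cfg, seed = 2)
  withr::local_seed(5)
  seqs <- vapply(1:4, function(i) rand_dna(150), character(1))
  e1 <- embed_sequences(m, seqs)
  e2 <- embed_sequences(m, seqs)
  expect_identical(e1, e2)  # dropout is off outside training
  expect_equal(rowSums(e1^2), rep(1, 4), tolerance = 1e-6)
  # cosine distance of a sequence to itself is zero
  expect_equal(1 - sum(e1[1, ] * e1[1, ]), 0, tolerance = 1e-6)
  # too-long input is refused, not truncated silently
  expect_error(embed_sequences(m, rand_dna(5000)), "max_tokens")
})

test_that("contrastive loss reproduces closed-form identities", {
  # all embeddings identical: softmax over B equal logits -> log(B)
  E <- matrix(rep(c(1, 0, 0), each = 16), nrow = 16)
  expect_equal(contrastive_loss(E, E, tau = 0.05), log(16), tolerance = 1e-12)
  # B = 2 with d(positive) = 0 and d(negative) = 2 at tau = 0.05:
  # loss = log(1 + exp(-40)) ~ 4.25e-18, indistinguishable from 0 in
  # double precision
  er <- rbind(c(1, 0), c(-1, 0))
  l2 <- contrastive_loss(er, er, tau = 0.05)
  expect_gte(l2, 0)
  expect_lt(l2, 1e-15)
  expect_error(contrastive_loss(er, er, tau = 0), "positive")
  expect_error(contrastive_loss(er, er[1, , drop = FALSE]), "mismatch")
})

test_that("loss is monotone in the positive-pair distance and batch-order invariant", {
  withr::local_seed(8)
  B <- 6; P <- 16
  ef <- matrix(rnorm(B * P), B)
  ef <- ef / sqrt(rowSums(ef^2))
  # move read i along the geodesic away from its positive fragment
  losses <- vapply(seq(0, 1, by = 0.1), function(alpha) {
    er <- (1 - alpha) * ef + alpha * matrix(rnorm(B * P, sd = 0.1), B)
    er <- er / sqrt(rowSums(er^2))
    contrastive_loss(er, ef, 0.05)
  }, numeric(1))
  # alpha = 0 means positives coincide: minimal loss of the sweep
  expect_identical(which.min(losses), 1L)
  er <- matrix(rnorm(B * P), B); er <- er / sqrt(rowSums(er^2))
  p <- sample(B)
  expect_equal(contrastive_loss(er[p, ], ef[p, ], 0.05),
               contrastive_loss(er, ef, 0.05), tolerance = 1e-12)
})

test_that("training batches respect the sampling recipe", {
  g <- generate_synthetic_genome(30000, seed = 21)
  tc <- train_config(batch_size = 16, frag_len_range = c(800, 2000),
                     read_len_range = c(150, 500), noise_read_frac = 0)
  withr::local_seed(4)
  fl <- c(); contained <- c()
  for (i in 1:40) {
    b <- sample_training_batch(g, tc)
    fl <- c(fl, nchar(b$frags))
    contained <- c(contained, mapply(grepl, b$reads, b$frags, fixed = TRUE))
  }
  expect_true(all(contained))  # noise off: reads are fragment substrings
  expect_true(all(fl >= 800 & fl <= 2000))
  # mean fragment length near the uniform mean 1400 (640 draws, sd ~ 13.7)
  expect_gt(mean(fl), 1345)
  expect_lt(mean(fl), 1455)
  # noise on: ~40% of reads get substitutions
  tcn <- train_config(batch_size = 16, noise_read_frac = 0.4)
  noised <- c()
  for (i in 1:40) noised <- c(noised, sample_training_batch(g, tcn)$noised)
  expect_gt(mean(noised), 0.32)
  expect_lt(mean(noised), 0.48)
})

test_that("a short training run decreases the contrastive loss", {
  g <- generate_synthetic_genome(30000, seed = 31)
  tok <- small_tokenizer(vocab_size = 150, corpus_bp = 20000)
  cfg <- encoder_config(n_layers = 1, n_heads = 2, model_width = 32,
                        projection_dim = 16, ff_width = 32, dropout = 0.1,
                        max_tokens = 256)
  tc <- train_config(steps = 25, batch_size = 8, grad_accum = 4,
                     frag_len_range = c(500, 700), read_len_range = c(100, 200),
                     lr_peak = 3e-4, seed = 5)
  m <- train_rde(g, tok, cfg, tc, verbose = FALSE)
  expect_identical(nrow(m$loss_trace), 25L)
  expect_true(all(is.finite(m$loss_trace$loss)))
  # a fresh model cannot beat the uniform-similarity ceiling log(B)
  expect_lt(m$loss_trace$loss[1], 1.5 * log(8))
  expect_lt(mean(tail(m$loss_trace$loss, 5)),
            mean(head(m$loss_trace$loss, 5)))
  # checkpoints round-trip
  path <- withr::local_tempfile(fileext = ".rds")
  save_rde(m, path)
  m2 <- load_rde(path)
  s <- rand_dna(200)
  expect_identical(embed_sequences(m2, s), embed_sequences(m, s))
})
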