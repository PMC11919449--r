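#' Derive a per-stage child seed from the global pipeline seed
#'
#' Stable hash of the stage name folded into the global seed, kept inside
#' the 32-bit integer range, so every stage has an independent but
#' replayable stream.
#'
#' @param global_seed integer pipeline seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483629 + 1)
}

write_manifest <- function(path, stage, config, seed, inputs = character(0),
                           counts = list()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(list(stage = stage, seed = seed, config = config,
                            input_md5 = sums, counts = counts),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

require_artifact <- function(path, producer) {
  if (!all(file.exists(path)))
    stop("missing artifact ", paste(path[!file.exists(path)], collapse = ", "),
         "; run the `", producer, "` stage first", call. = FALSE)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Orchestrates the end-to-end workflow as replayable stages; each stage
#' writes its artifact plus a JSON manifest (config snapshot, seed, input
#' checksums, counts).  Stage names and their key config entries:
#'
#' * `simulate-genome`: `chrom_lengths`, optional `repeats` (list of
#'   `c(length, copies)`), `genome` (output FASTA).
#' * `simulate-reads`: `genome`, `reads` (output FASTQ), simulator fields
#'   (`Q`, `phred_range`, `ins_rate`, `del_rate`, `n_reads`, `strand_mode`).
#' * `train`: `genome`, `checkpoint` (output RDS), `vocab_size`,
#'   `corpus_mb` (tokenizer corpus size), encoder/training fields
#'   (`profile` = "small"/"paper", `steps`, `lr_peak`, ...).
#' * `build-index`: `genome`, `checkpoint`, `store` (output dir),
#'   `frag_len`, `overlap`, `backend`.
#' * `align`: `genome`, `reads`, `store`, `checkpoint`, `sam`/`results`
#'   outputs, `top_k`, `diversity`, `search_rc`.
#' * `evaluate`: as `align` plus `truth`, `criterion`, `d_sw_bound`,
#'   `report` (output JSON).
#'
#' @param name stage name (see above).
#' @param config a named list or the path of a YAML file; `seed` is the
#'   global seed (default 1), fanned out per stage via [stage_seed()].
#' @return the stage's primary artifact path(s), invisibly.
#' @export
run_subcommand <- function(name, config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- stage_seed(config$seed %||% 1L, name)
  switch(name,
    "simulate-genome" = stage_simulate_genome(config, seed),
    "simulate-reads" = stage_simulate_reads(config, seed),
    "train" = stage_train(config, seed),
    "build-index" = stage_build_index(config, seed),
    "align" = stage_align(config, seed),
    "evaluate" = stage_evaluate(config, seed),
    stop("unknown stage: ", name)
  )
}

stage_simulate_genome <- function(cfg, seed) {
  out <- cfg$genome %||% stop("config needs `genome` (output FASTA path)")
  genome <- generate_synthetic_genome(cfg$chrom_lengths %||% 1e6,
                                      repeat_spec = cfg$repeats, seed = seed)
  write_fasta(genome, out)
  write_repeats_json(genome, paste0(out, ".repeats.json"))
  write_manifest(paste0(out, ".manifest.json"), "simulate-genome", cfg, seed,
                 counts = list(chromosomes = length(genome$chromosomes),
                               bases = genome$N))
  message("simulate-genome: ", genome$N, " bases -> ", out)
  invisible(out)
}

stage_simulate_reads <- function(cfg, seed) {
  require_artifact(cfg$genome, "simulate-genome")
  genome <- load_fasta(cfg$genome)
  sc <- simulator_config(Q = cfg$Q %||% 250L,
                         phred_range = cfg$phred_range %||% c(30L, 60L),
                         ins_rate = cfg$ins_rate %||% 0.01,
                         del_rate = cfg$del_rate %||% 0.01,
                         n_reads = cfg$n_reads %||% 1000L,
                         strand_mode = cfg$strand_mode %||% "forward_only",
                         seed = seed)
  reads <- simulate_reads(genome, sc)
  out <- cfg$reads %||% stop("config needs `reads` (output FASTQ path)")
  write_fastq(reads, out)
  write_manifest(paste0(out, ".manifest.json"), "simulate-reads",
                 cfg, seed, inputs = cfg$genome,
                 counts = list(reads = nrow(reads)))
  message("simulate-reads: ", nrow(reads), " reads -> ", out)
  invisible(out)
}

stage_train <- function(cfg, seed) {
  require_artifact(cfg$genome, "simulate-genome")
  genome <- load_fasta(cfg$genome)
  corpus <- train_corpus(genome, mb = cfg$corpus_mb %||% 0.5, seed = seed)
  tokenizer <- train_vocab(corpus, vocab_size = cfg$vocab_size %||% 10000L)
  enc <- if (identical(cfg$profile %||% "small", "paper"))
    encoder_config() else encoder_config_small()
  tc <- train_config(steps = cfg$steps %||% 30L,
                     batch_size = cfg$batch_size %||% 16L,
                     grad_accum = cfg$grad_accum %||% 16L,
                     lr_peak = cfg$lr_peak %||% 5e-5,
                     frag_len_range = cfg$frag_len_range %||% c(800L, 2000L),
                     read_len_range = cfg$read_len_range %||% c(150L, 500L),
                     seed = seed)
  model <- train_rde(genome, tokenizer, enc, tc,
                     verbose = isTRUE(cfg$verbose %||% TRUE))
  out <- cfg$checkpoint %||% stop("config needs `checkpoint` (output path)")
  save_rde(model, out)
  write.table(model$loss_trace, paste0(out, ".loss.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write_manifest(paste0(out, ".manifest.json"), "train", cfg, seed,
                 inputs = cfg$genome,
                 counts = list(updates = nrow(model$loss_trace),
                               final_loss = model$loss_trace$loss[nrow(model$loss_trace)]))
  message("train: ", nrow(model$loss_trace), " updates -> ", out)
  invisible(out)
}

# Sample a tokenizer-training corpus (~`mb` megabases) of 2 kb windows.
# Windows are drawn without overlap so no long substring is duplicated in the
# corpus, which would otherwise let BPE merge corpus-specific giant tokens.
train_corpus <- function(genome, mb = 0.5, seed = 1L) {
  with_seed(seed, {
    win <- 2000L
    n_win <- max(1L, ceiling(mb * 1e6 / win))
    slots <- do.call(rbind, lapply(names(genome$chromosomes), function(nm) {
      len <- nchar(genome$chromosomes[[nm]])
      starts <- seq.int(0L, len - min(win, len), by = win)
      data.frame(chrom = nm, start0 = starts,
                 w = pmin(win, len - starts), stringsAsFactors = FALSE)
    }))
    pick <- slots[sample.int(nrow(slots), min(n_win, nrow(slots))), ]
    unlist(Map(function(ch, s, w) genome_slice(genome, ch, s, w),
               pick$chrom, pick$start0, pick$w), use.names = FALSE)
  })
}

stage_build_index <- function(cfg, seed) {
  require_artifact(c(cfg$genome, cfg$checkpoint), "train")
  genome <- load_fasta(cfg$genome)
  model <- load_rde(cfg$checkpoint)
  frags <- shard(genome, frag_len = cfg$frag_len %||% 1250L,
                 overlap = cfg$overlap %||% 250L)
  store <- build_index(frags, model, backend = cfg$backend %||% "exact",
                       seed = seed)
  out <- cfg$store %||% stop("config needs `store` (output directory)")
  save_store(store, out)
  export_fragments_bed(frags, file.path(out, "fragments.bed"))
  write_manifest(file.path(out, "stage-manifest.json"), "build-index", cfg,
                 seed, inputs = c(cfg$genome, cfg$checkpoint),
                 counts = list(fragments = nrow(frags)))
  message("build-index: ", nrow(frags), " fragments -> ", out)
  invisible(out)
}

stage_align <- function(cfg, seed, want_truth = FALSE) {
  require_artifact(cfg$reads, "simulate-reads")
  if (is.null(cfg$store)) stop("config needs `store`; run the `build-index` stage first",
                               call. = FALSE)
  require_artifact(file.path(cfg$store, "manifest.json"), "build-index")
  require_artifact(c(cfg$genome, cfg$checkpoint), "train")
  genome <- load_fasta(cfg$genome)
  model <- load_rde(cfg$checkpoint)
  store <- load_store(cfg$store, genome)
  truth <- cfg$truth %||% paste0(cfg$reads, ".truth.tsv")
  reads <- read_fastq(cfg$reads,
                      truth_path = if (file.exists(truth)) truth else NULL)
  K <- cfg$top_k %||% 50L
  scheme <- scoring_scheme()
  diversity <- cfg$diversity %||% TRUE
  search_rc <- cfg$search_rc %||% any(reads$strand == "-", na.rm = TRUE)
  embs <- embed_sequences(model, reads$seq)
  embs_rc <- if (search_rc) embed_sequences(model, revcomp(reads$seq)) else NULL
  results <- lapply(seq_len(nrow(reads)), function(i) {
    hits <- query(store, embs[i, ], K = K, diversity = diversity)
    if (search_rc) {
      hits_rc <- query(store, embs_rc[i, ], K = K, diversity = diversity)
      hits <- rbind(hits, hits_rc[!hits_rc$frag_id %in% hits$frag_id, ])
    }
    best_alignment(reads$seq[i], hits, scheme = scheme,
                   search_rc = search_rc, chrom_levels = store$chrom_levels)
  })
  sam <- cfg$sam %||% stop("config needs `sam` (output path)")
  write_sam(results, reads, genome, sam)
  tsv <- cfg$results %||% paste0(sam, ".results.tsv")
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(chrom = r$chrom, q_star = r$q_star, v_star = r$v_star,
               d_sw = r$d_sw, strand = r$strand, tie = r$tie)
  }))
  df <- cbind(read_id = reads$read_id, df)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(paste0(sam, ".manifest.json"), "align", cfg, seed,
                 inputs = c(cfg$reads, cfg$genome, cfg$checkpoint),
                 counts = list(reads = nrow(reads)))
  message("align: ", nrow(reads), " reads -> ", sam)
  if (want_truth) list(reads = reads, results = results, store = store,
                       model = model) else invisible(sam)
}

stage_evaluate <- function(cfg, seed) {
  require_artifact(cfg$reads, "simulate-reads")
  if (is.null(cfg$store)) stop("config needs `store`; run the `build-index` stage first",
                               call. = FALSE)
  require_artifact(file.path(cfg$store, "manifest.json"), "build-index")
  genome <- load_fasta(cfg$genome)
  model <- load_rde(cfg$checkpoint)
  store <- load_store(cfg$store, genome)
  truth <- cfg$truth %||% paste0(cfg$reads, ".truth.tsv")
  require_artifact(truth, "simulate-reads")
  reads <- read_fastq(cfg$reads, truth_path = truth)
  report <- evaluate(reads, store, model, K = cfg$top_k %||% 50L,
                     criterion = cfg$criterion %||% "either",
                     d_sw_bound = cfg$d_sw_bound %||% 0.02,
                     diversity = cfg$diversity %||% TRUE,
                     search_rc = cfg$search_rc)
  out <- cfg$report %||% stop("config needs `report` (output JSON path)")
  write_report(report, json_path = out, tsv_path = paste0(out, ".per_read.tsv"))
  write_manifest(paste0(out, ".manifest.json"), "evaluate", cfg, seed,
                 inputs = c(cfg$reads, cfg$genome),
                 counts = list(reads = report$n_reads,
                               successes = report$n_success,
                               recall = report$recall))
  message(sprintf("evaluate: recall %.4f [%.4f, %.4f] -> %s", report$recall,
                  report$ci[1], report$ci[2], out))
  invisible(out)
}
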