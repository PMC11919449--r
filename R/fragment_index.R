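#' Shard a genome into overlapping fragments
#'
#' Fragments start at `0, stride, 2*stride, ...` with
#' `stride = frag_len - overlap`; a final fragment is right-anchored at the
#' chromosome end so coverage is total.  Consecutive fragments overlap by at
#' least `overlap` bases, which guarantees that every substring of length
#' `<= overlap` (i.e. every read up to the design read length) is fully
#' contained in at least one fragment.  A chromosome shorter than `frag_len`
#' yields one whole-chromosome fragment.
#'
#' @param genome a [reference_genome()].
#' @param frag_len fragment length (default 1250).
#' @param overlap minimum overlap between consecutive fragments (default
#'   250, the design maximum read length).
#' @return a `FragmentSet` data frame: `frag_id`, `chrom`, `start0`,
#'   `length`, `seq`; fragment ids are stable (`chrom:start0`).
#' @export
shard <- function(genome, frag_len = 1250L, overlap = 250L) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  frag_len <- as.integer(frag_len); overlap <- as.integer(overlap)
  if (overlap < 1 || overlap >= frag_len)
    stop("need frag_len > overlap >= 1")
  stride <- frag_len - overlap
  pieces <- lapply(names(genome$chromosomes), function(nm) {
    len <- nchar(genome$chromosomes[[nm]])
    if (len <= frag_len) {
      starts <- 0L
      fl <- len
    } else {
      starts <- seq.int(0L, len - frag_len, by = stride)
      if (max(starts) < len - frag_len) starts <- c(starts, len - frag_len)
      fl <- frag_len
    }
    data.frame(frag_id = paste0(nm, ":", starts), chrom = nm,
               start0 = as.integer(starts), length = as.integer(fl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$seq <- unlist(Map(function(ch, s, l) genome_slice(genome, ch, s, l),
                        out$chrom, out$start0, out$length), use.names = FALSE)
  structure(out, class = c("FragmentSet", "data.frame"),
            frag_len = frag_len, overlap = overlap,
            chrom_levels = names(genome$chromosomes))
}

#' Closed-form fragment count of the sharding plan
#'
#' Number of fragments a chromosome of length `n` yields under
#' `frag_len`/`overlap` sharding (per-chromosome; sum over chromosomes for a
#' genome).  Used for capacity arithmetic without materializing fragments.
#'
#' @param n chromosome length (bases).
#' @param frag_len,overlap sharding parameters.
#' @return fragment count (numeric, exact).
#' @export
shard_count <- function(n, frag_len = 1250L, overlap = 250L) {
  if (overlap >= frag_len) stop("need frag_len > overlap")
  stride <- frag_len - overlap
  if (n <= frag_len) return(1)
  regular <- floor((n - frag_len) / stride) + 1
  regular + as.numeric((regular - 1) * stride != n - frag_len)
}

#' Export fragment intervals as BED
#'
#' @param fragments a `FragmentSet`.
#' @param path output BED path.
#' @export
export_fragments_bed <- function(fragments, path) {
  bed <- data.frame(fragments$chrom, fragments$start0,
                    fragments$start0 + fragments$length, fragments$frag_id)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Build a vector store over fragment embeddings
#'
#' Embeds every fragment with the supplied encoder and stores one vector per
#' fragment together with its metadata (chromosome, start, raw sequence).
#' The `exact` backend is a brute-force cosine scan; the `approx` backend is
#' an inverted-file (IVF) index -- a k-means coarse quantizer whose
#' `n_probe` nearest cells are scanned per query.
#'
#' @param fragments a [shard()] result.
#' @param encoder an encoder accepted by [embed_sequences()].
#' @param backend `"exact"` or `"approx"`.
#' @param n_list,n_probe IVF cells and probed cells (defaults:
#'   `~2*sqrt(n)` cells, 20% probed); ignored for `exact`.
#' @param seed seed for the k-means quantizer.
#' @return a `VectorStore`.
#' @export
build_index <- function(fragments, encoder, backend = c("exact", "approx"),
                        n_list = NULL, n_probe = NULL, seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(inherits(fragments, "FragmentSet"))
  vectors <- embed_sequences(encoder, fragments$seq)
  stopifnot(nrow(vectors) == nrow(fragments))
  ivf <- NULL
  if (backend == "approx") {
    n <- nrow(vectors)
    if (is.null(n_list)) n_list <- max(2L, min(n, as.integer(2 * ceiling(sqrt(n)))))
    if (is.null(n_probe)) n_probe <- max(2L, ceiling(0.2 * n_list))
    km <- with_seed(seed, kmeans(vectors, centers = n_list, iter.max = 25,
                                 nstart = 1))
    ivf <- list(centers = km$centers, assign = km$cluster,
                n_probe = as.integer(min(n_probe, n_list)))
  }
  structure(list(vectors = vectors,
                 meta = fragments[, c("frag_id", "chrom", "start0", "length",
                                      "seq")],
                 backend = backend, ivf = ivf,
                 chrom_levels = attr(fragments, "chrom_levels"),
                 frag_len = attr(fragments, "frag_len"),
                 overlap = attr(fragments, "overlap"),
                 encoder_fingerprint = encoder_fingerprint(encoder)),
            class = "VectorStore")
}

# Compact identity of the encoder a store was built with, recorded in the
# store manifest so stale store/checkpoint pairings are detectable.
encoder_fingerprint <- function(encoder) {
  if (inherits(encoder, "rde_model"))
    sprintf("rde:%d:%.10e", length(encoder$params), sum(encoder$params))
  else if (inherits(encoder, "kmer_encoder"))
    sprintf("kmer:k%d:d%d:s%d", encoder$k, encoder$dim, encoder$seed)
  else
    class(encoder)[1]
}

#' @export
print.VectorStore <- function(x, ...) {
  cat("VectorStore:", nrow(x$vectors), "fragment vectors in R^",
      ncol(x$vectors), "(", x$backend, "backend )\n")
  invisible(x)
}

#' Query the vector store for nearest fragments
#'
#' Hits are ranked by cosine distance ascending with deterministic
#' tie-breaking on (chromosome order, start).  With `diversity = TRUE`
#' (the per-chromosome prior) the top-K nearest fragments *within each
#' chromosome* are returned, concatenated; otherwise the global top-K.
#'
#' @param store a `VectorStore`.
#' @param read_embedding unit-norm numeric vector.
#' @param K hits per chromosome (diversity) or in total.
#' @param diversity apply the per-chromosome prior.
#' @return data frame of hits (`frag_id`, `chrom`, `start0`, `length`,
#'   `seq`, `dist`, `rank`).
#' @export
query <- function(store, read_embedding, K = 50L, diversity = TRUE) {
  stopifnot(inherits(store, "VectorStore"), K >= 1)
  if (nrow(store$vectors) == 0) stop("empty store")
  cand <- seq_len(nrow(store$vectors))
  if (store$backend == "approx") {
    cdist <- 1 - as.vector(store$ivf$centers %*% read_embedding) /
      pmax(sqrt(rowSums(store$ivf$centers^2)), 1e-12)
    cells <- order(cdist)[seq_len(store$ivf$n_probe)]
    cand <- which(store$ivf$assign %in% cells)
    if (length(cand) == 0) cand <- seq_len(nrow(store$vectors))
  }
  dist <- 1 - as.vector(store$vectors[cand, , drop = FALSE] %*% read_embedding)
  meta <- store$meta[cand, , drop = FALSE]
  ord <- order(dist, match(meta$chrom, store$chrom_levels), meta$start0)
  if (isTRUE(diversity)) {
    keep <- unlist(lapply(split(ord, match(meta$chrom[ord],
                                           store$chrom_levels)),
                          head, n = K), use.names = FALSE)
    keep <- keep[order(dist[keep], match(meta$chrom[keep], store$chrom_levels),
                       meta$start0[keep])]
  } else {
    keep <- head(ord, K)
  }
  hits <- meta[keep, , drop = FALSE]
  hits$dist <- dist[keep]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}

#' Persist / restore a vector store
#'
#' Vectors go to a flat binary array (`vectors.bin`), metadata to a TSV
#' (`frag_id`, `chrom`, `start0`, `len`), and a JSON manifest records the
#' sharding parameters and dimensions.  Fragment sequences are reconstructed
#' from the genome on load, so the on-disk store stays compact.
#'
#' @param store a `VectorStore`.
#' @param dir directory to create/use.
#' @export
save_store <- function(store, dir) {
  stopifnot(inherits(store, "VectorStore"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "vectors.bin"), "wb")
  writeBin(as.vector(store$vectors), con)
  close(con)
  meta <- store$meta[, c("frag_id", "chrom", "start0", "length")]
  names(meta)[4] <- "len"
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(n = nrow(store$vectors), dim = ncol(store$vectors),
                            backend = store$backend,
                            frag_len = store$frag_len,
                            overlap = store$overlap,
                            chrom_levels = store$chrom_levels,
                            encoder_fingerprint =
                              store$encoder_fingerprint %||% NA),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_store
#' @param genome the [reference_genome()] the store was built from (used to
#'   reconstruct fragment sequences).
#' @export
load_store <- function(dir, genome) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  con <- file(file.path(dir, "vectors.bin"), "rb")
  vec <- readBin(con, what = "double", n = man$n * man$dim)
  close(con)
  meta <- read.delim(file.path(dir, "meta.tsv"), stringsAsFactors = FALSE)
  names(meta)[4] <- "length"
  meta$seq <- unlist(Map(function(ch, s, l) genome_slice(genome, ch, s, l),
                         meta$chrom, meta$start0, meta$length),
                     use.names = FALSE)
  structure(list(vectors = matrix(vec, nrow = man$n, ncol = man$dim),
                 meta = meta, backend = "exact", ivf = NULL,
                 chrom_levels = man$chrom_levels, frag_len = man$frag_len,
                 overlap = man$overlap),
            class = "VectorStore")
}
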