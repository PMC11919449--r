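#' Construct a reference genome object
#'
#' A `ReferenceGenome` holds named chromosome sequences over the strict
#' alphabet `{A,C,G,T}` plus the total length `N`.  Coordinates throughout the
#' package are 0-based, half-open; conversion to 1-based happens only at the
#' SAM boundary.
#'
#' @param chromosomes named character vector of chromosome sequences.
#' @param repeats optional data frame of planted-repeat positions
#'   (`repeat_id`, `chrom`, `start0`, `length`), recorded by
#'   [generate_synthetic_genome()] so repeat-aware tests can probe
#'   multi-mapping behaviour.
#' @return an object of class `ReferenceGenome` with elements `chromosomes`,
#'   `N` and (possibly `NULL`) `repeats`.
#' @export
reference_genome <- function(chromosomes, repeats = NULL) {
  if (length(chromosomes) == 0) stop("genome has no chromosomes")
  nm <- names(chromosomes)
  if (is.null(nm) || any(!nzchar(nm))) stop("chromosome names must be non-empty")
  if (anyDuplicated(nm)) stop("duplicate chromosome names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(nchar(chromosomes) == 0)) stop("chromosome with empty sequence")
  bad <- grepl("[^ACGT]", chromosomes)
  if (any(bad)) stop("sequence contains characters outside {A,C,G,T} in: ",
                     paste(nm[bad], collapse = ", "))
  structure(list(chromosomes = chromosomes,
                 N = sum(nchar(chromosomes)),
                 repeats = repeats),
            class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", length(x$chromosomes), "chromosome(s),",
      format(x$N, big.mark = ","), "bp\n")
  for (nm in names(x$chromosomes))
    cat("  ", nm, ": ", nchar(x$chromosomes[[nm]]), " bp\n", sep = "")
  if (!is.null(x$repeats))
    cat("  planted repeats:", nrow(x$repeats), "copies\n")
  invisible(x)
}

# 0-based half-open slice of one chromosome.
genome_slice <- function(genome, chrom, start0, len) {
  substr(genome$chromosomes[[chrom]], start0 + 1L, start0 + len)
}

#' Load a reference genome from FASTA
#'
#' One chromosome per record, in file order.  Sequences are uppercased.
#' IUPAC ambiguity codes (including `N`) are replaced by a concrete base
#' drawn uniformly from the bases the code denotes, using a dedicated seeded
#' stream; the number of replaced bases is reported with a warning so the
#' substitution is never silent.
#'
#' @param path FASTA file (plain text, multi-record).
#' @param ambiguity_seed seed for the ambiguity-resolution stream.
#' @return a [reference_genome()] object.
#' @export
load_fasta <- function(path, ambiguity_seed = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(set) == 0) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) stop("FASTA record with empty name in ", path)
  if (anyDuplicated(nm)) stop("duplicate FASTA record names in ", path)
  if (any(nchar(seqs) == 0)) stop("FASTA record with empty sequence in ", path)
  n_amb <- 0L
  iupac <- Biostrings::IUPAC_CODE_MAP
  seqs <- with_seed(ambiguity_seed, vapply(seqs, function(s) {
    hits <- gregexpr("[^ACGT]", s)[[1]]
    if (hits[1] == -1L) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in hits) {
      code <- iupac[[chars[i]]]
      if (is.null(code)) stop("character '", chars[i], "' is not a nucleotide code")
      opts <- strsplit(code, "", fixed = TRUE)[[1]]
      chars[i] <- if (length(opts) == 1) opts else sample(opts, 1)
    }
    n_amb <<- n_amb + length(hits)
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE))
  if (n_amb > 0)
    warning(n_amb, " ambiguous base(s) replaced by seeded-random concrete bases")
  names(seqs) <- nm
  reference_genome(seqs)
}

#' Write a reference genome to FASTA
#'
#' Round-trips exactly through [load_fasta()].
#'
#' @param genome a `ReferenceGenome`.
#' @param path output path.
#' @param line_width maximum sequence characters per line.
#' @export
write_fasta <- function(genome, path, line_width = 60L) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  if (length(genome$chromosomes) == 0) stop("refusing to write an empty genome")
  if (line_width < 1) stop("line_width must be positive")
  set <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(line_width))
  invisible(path)
}

#' Generate a synthetic genome with planted repeats
#'
#' Chromosome sequences are i.i.d. uniform over `{A,C,G,T}`; optionally,
#' exact repeat units are planted at recorded, non-overlapping positions so
#' that multi-mapping reads can be constructed on purpose.  Generation is
#' bit-reproducible for a fixed seed.
#'
#' @param chrom_lengths integer vector of chromosome lengths (bp).
#' @param repeat_spec optional list of `c(length, n_copies)` pairs (or a
#'   2-column matrix/data.frame); each unit is a fresh random sequence copied
#'   verbatim `n_copies` times.
#' @param seed RNG seed.
#' @param chrom_names optional names; default `chr1`, `chr2`, ...
#' @return a [reference_genome()] with the `repeats` table filled in when
#'   repeats were planted.
#' @export
generate_synthetic_genome <- function(chrom_lengths, repeat_spec = NULL,
                                      seed = 1L, chrom_names = NULL) {
  chrom_lengths <- as.integer(chrom_lengths)
  if (length(chrom_lengths) == 0 || any(chrom_lengths < 1))
    stop("chromosome lengths must be positive")
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_along(chrom_lengths))
  if (!is.null(repeat_spec)) {
    rs <- do.call(rbind, lapply(repeat_spec, function(x) as.integer(x[1:2])))
    colnames(rs) <- c("length", "copies")
    if (any(rs < 1)) stop("repeat lengths and copy counts must be positive")
    if (sum(rs[, "length"] * rs[, "copies"]) >= sum(chrom_lengths))
      stop("repeat footprint exceeds genome size")
  }
  with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(n) {
      paste(BASES[sample.int(4L, n, replace = TRUE)], collapse = "")
    }, character(1))
    names(seqs) <- chrom_names
    repeats <- NULL
    if (!is.null(repeat_spec)) {
      occupied <- lapply(seqs, function(s) integer(0))  # starts of planted slots
      rows <- list()
      for (r in seq_len(nrow(rs))) {
        len <- rs[r, "length"]
        unit <- paste(BASES[sample.int(4L, len, replace = TRUE)], collapse = "")
        for (cp in seq_len(rs[r, "copies"])) {
          placed <- FALSE
          for (try in 1:1000) {
            ci <- sample.int(length(seqs), 1,
                             prob = pmax(chrom_lengths - len + 1, 0))
            start0 <- sample.int(chrom_lengths[ci] - len + 1, 1) - 1L
            clash <- any(vapply(rows, function(x) {
              x$chrom == chrom_names[ci] &&
                start0 < x$start0 + x$length && x$start0 < start0 + len
            }, logical(1)))
            if (!clash) {
              substr(seqs[ci], start0 + 1L, start0 + len) <- unit
              rows[[length(rows) + 1L]] <-
                list(repeat_id = r, chrom = chrom_names[ci],
                     start0 = start0, length = len)
              placed <- TRUE
              break
            }
          }
          if (!placed) stop("could not place repeat copy without overlap")
        }
      }
      repeats <- do.call(rbind.data.frame, rows)
    }
    reference_genome(seqs, repeats = repeats)
  })
}

#' Write planted-repeat metadata as a JSON sidecar
#'
#' @param genome a `ReferenceGenome` with a `repeats` table.
#' @param path output JSON path.
#' @export
write_repeats_json <- function(genome, path) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  jsonlite::write_json(genome$repeats %||% list(), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
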