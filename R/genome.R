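#' Reference genome container
#'
#' A reference genome is a named set of uppercase nucleotide sequences over
#' the alphabet A, C, G, T, N. Toy and simulated genomes stand in for a real
#' assembly; the object is deliberately lightweight (a named character vector)
#' so that the simulator can mutate sequences by string surgery.
#'
#' @param sequences Named character vector or list of nucleotide strings, or a
#'   [Biostrings::DNAStringSet].
#' @return An object of class `ref_genome`: a named character vector with the
#'   sequences uppercased and validated.
#' @examples
#' g <- ref_genome(c(chr1 = "AATAGCCTAG", chr2 = "TTTACGT"))
#' seq_lengths(g)
#' @export
ref_genome <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  sequences <- toupper(unlist(sequences))
  if (length(sequences) == 0L) {
    stop("no sequences")
  }
  nms <- names(sequences)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(nms)) {
    stop("sequence names must be unique")
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequence(s) ", paste(nms[bad], collapse = ", "),
         " contain characters outside A/C/G/T/N")
  }
  structure(sequences, class = "ref_genome")
}

#' @rdname ref_genome
#' @param x A `ref_genome`.
#' @export
seq_lengths <- function(x) {
  x <- as_ref_genome(x)
  setNames(nchar(unclass(x)), names(x))
}

as_ref_genome <- function(x) {
  if (inherits(x, "ref_genome")) x else ref_genome(x)
}

#' @export
print.ref_genome <- function(x, ...) {
  len <- seq_lengths(x)
  cat("ref_genome with", length(x), "sequence(s),", sum(len), "bp total\n")
  for (nm in head(names(x), 10L)) {
    cat(sprintf("  %s  %d bp\n", nm, len[[nm]]))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Read and write reference genomes as FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that coerce to/from [ref_genome()]. FASTA
#' description lines are truncated at the first whitespace on read.
#'
#' @param path File path.
#' @param genome A `ref_genome` (or coercible).
#' @return `read_genome()` returns a `ref_genome`; `write_genome()` returns
#'   `path` invisibly.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  ref_genome(dss)
}

#' @rdname read_genome
#' @export
write_genome <- function(genome, path) {
  genome <- as_ref_genome(genome)
  dss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

#' Generate a random genome
#'
#' Uniform i.i.d. nucleotide sequences, used throughout the simulator. The
#' expected TA density of such a sequence is 1/16 per position.
#'
#' @param lengths Named integer vector of sequence lengths (names become
#'   sequence names).
#' @param gc GC content in (0, 1); default 0.5 (uniform base composition).
#' @param seed Integer seed; the draw is reproducible given `(lengths, gc,
#'   seed)`.
#' @return A `ref_genome`.
#' @examples
#' g <- random_genome(c(chr1 = 1000), seed = 1)
#' @export
random_genome <- function(lengths, gc = 0.5, seed = NULL) {
  stopifnot(all(lengths >= 1), gc > 0, gc < 1)
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    names(lengths) <- paste0("chr", seq_along(lengths))
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(n) {
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  ref_genome(seqs)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Index all TA dinucleotides in a genome
#'
#' Records the 1-based position of the T of every plus-strand "TA". TA is its
#' own reverse complement, so a single strandless index covers both strands,
#' and two TA occurrences can never overlap.
#'
#' @param genome A `ref_genome` (or coercible).
#' @return An object of class `ta_index`: a list with `positions` (named list
#'   of strictly increasing integer vectors, one per sequence) and
#'   `total_ta_count`.
#' @examples
#' build_ta_index(c(chr = "AATAGC"))$positions$chr  # 3 (1-based T)
#' @export
build_ta_index <- function(genome) {
  genome <- as_ref_genome(genome)
  pos <- lapply(unclass(genome), function(s) {
    m <- gregexpr("TA", s, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  })
  structure(
    list(positions = pos, total_ta_count = sum(lengths(pos))),
    class = "ta_index"
  )
}

#' @export
print.ta_index <- function(x, ...) {
  cat("ta_index:", x$total_ta_count, "TA site(s) across",
      length(x$positions), "sequence(s)\n")
  invisible(x)
}

#' TA sites as a data frame
#'
#' @param index A `ta_index`.
#' @return Data frame with columns `seqname`, `pos` (1-based position of the
#'   T).
#' @export
ta_sites <- function(index) {
  stopifnot(inherits(index, "ta_index"))
  data.frame(
    seqname = rep(names(index$positions), lengths(index$positions)),
    pos = unlist(index$positions, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
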