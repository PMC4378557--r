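# Mappability correction at TA dinucleotides: mock reads anchored at each TA,
# a built-in exhaustive small-genome aligner (Biostrings-backed), the
# minimum-unique-read-length computation, and experimental read filtering.
# For genomes beyond toy scale an external aligner satisfying the same
# per-read hit-table contract can be substituted.

#' Generate mock reads anchored at TA dinucleotides
#'
#' For each TA and each strand, emits the genomic sequence starting at the TA
#' and extending `length` bp in the strand direction (reverse-complemented on
#' the minus strand), at lengths 10–65 bp in 5-bp steps by default. Screen
#' reads begin at the ITR/genome junction adjacent to the TA, so every mock
#' read starts with `TA` on its own strand (the anchor offset is fixed at the
#' TA). Reads that would run past a sequence end are skipped.
#'
#' @param genome A `ref_genome`.
#' @param positions Data frame (`seqname`, `pos`) of TA positions, or a
#'   `ta_index` for all of them.
#' @param lengths Ascending read lengths. Default `seq(10, 65, by = 5)`.
#' @return Data frame with `seqname`, `ta_pos`, `strand`, `length`, `read`.
#' @export
generate_mock_reads <- function(genome, positions,
                                lengths = seq(10L, 65L, by = 5L)) {
  stopifnot(!is.unsorted(lengths), all(lengths >= 2))
  genome <- as_ref_genome(genome)
  if (inherits(positions, "ta_index")) positions <- ta_sites(positions)
  len <- seq_lengths(genome)
  out <- list()
  for (i in seq_len(nrow(positions))) {
    nm <- positions$seqname[i]
    pos <- positions$pos[i]
    s <- genome[[nm]]
    for (L in lengths) {
      if (pos + L - 1L <= len[[nm]]) {
        out[[length(out) + 1L]] <- data.frame(
          seqname = nm, ta_pos = pos, strand = "+", length = L,
          read = substr(s, pos, pos + L - 1L), stringsAsFactors = FALSE)
      }
      if (pos + 2L - L >= 1L) {
        out[[length(out) + 1L]] <- data.frame(
          seqname = nm, ta_pos = pos, strand = "-", length = L,
          read = revcomp(substr(s, pos + 2L - L, pos + 1L)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seqname = character(), ta_pos = integer(),
                      strand = character(), length = integer(),
                      read = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Align reads against a genome by exhaustive mismatch scan
#'
#' The built-in aligner enumerates every position on both strands at which a
#' read matches with at most `max_mismatch` substitutions (no indels), scores
#' hits as `match +1 / mismatch -1` (a perfect L-mer scores L), and returns
#' up to `max_reported_hits` best hits per read. Minus-strand hits are
#' reported at plus-strand coordinates of the match footprint. Suitable for
#' toy genomes; an external aligner adapter can provide the same hit-table
#' schema at assembly scale.
#'
#' @param reads Character vector of read sequences (names become query ids;
#'   unnamed reads are numbered), or a data frame with a `read` column.
#' @param genome A `ref_genome`.
#' @param max_mismatch Maximum substitutions per hit. Default 2.
#' @param max_reported_hits Hits retained per read, best score first.
#'   Default 10.
#' @return Data frame with `query`, `seqname`, `start` (1-based, plus
#'   strand), `strand`, `mismatches`, `score`, ordered by query then
#'   decreasing score.
#' @export
align_reads <- function(reads, genome, max_mismatch = 2L,
                        max_reported_hits = 10L) {
  genome <- as_ref_genome(genome)
  if (is.data.frame(reads)) {
    ids <- if ("query" %in% names(reads)) reads$query
    else as.character(seq_len(nrow(reads)))
    reads <- setNames(reads$read, ids)
  }
  if (is.null(names(reads))) names(reads) <- as.character(seq_along(reads))
  subjects <- lapply(unclass(genome), Biostrings::DNAString)
  out <- list()
  for (qi in seq_along(reads)) {
    read <- reads[[qi]]
    L <- nchar(read)
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else revcomp(read)
      pat_ds <- Biostrings::DNAString(pat)
      for (nm in names(subjects)) {
        if (L > length(subjects[[nm]])) next
        m <- Biostrings::matchPattern(pat_ds, subjects[[nm]],
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (length(m) == 0L) next
        starts <- IRanges::start(m)
        mm <- Biostrings::neditStartingAt(pat_ds, subjects[[nm]],
                                          starting.at = starts,
                                          with.indels = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          query = names(reads)[qi], seqname = nm, start = starts,
          strand = strand, mismatches = as.integer(mm),
          score = L - 2L * as.integer(mm), stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) {
      h <- do.call(rbind, hits)
      h <- h[order(-h$score, h$seqname, h$start, h$strand), , drop = FALSE]
      out[[length(out) + 1L]] <- head(h, max_reported_hits)
    }
  }
  if (!length(out)) {
    return(data.frame(query = character(), seqname = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), score = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Minimum read length for accurate, unique mapping at each TA
#'
#' For each TA position and strand, mock reads of increasing length are
#' aligned to the genome; a length qualifies when (a) the hit at the
#' originating locus has alignment score strictly greater than `score_min`,
#' and (b) no hit exists at any *other* locus with fewer than
#' `alt_mismatch_limit` mismatches (i.e. uniqueness demands every alternative
#' carry at least that many mismatches). The record stores the smallest
#' qualifying tested length, or `NA` ("unmappable") when none qualifies.
#'
#' With the built-in `match +1 / mismatch -1` scoring, a perfect 10-mer
#' scores exactly 10 and fails `score > 10`, so the smallest attainable
#' minimum on the default grid is 15.
#'
#' @param genome A `ref_genome`.
#' @param positions Data frame (`seqname`, `pos`) of TA positions, or a
#'   `ta_index`.
#' @param lengths Ascending candidate read lengths. Default
#'   `seq(10, 65, by = 5)`.
#' @param score_min Minimum originating-locus score (exclusive). Default 10.
#' @param alt_mismatch_limit Alternative hits with fewer mismatches than this
#'   disqualify the length. Default 2.
#' @param strands Strands to evaluate. Default both.
#' @return Data frame of class `mappability`: `seqname`, `ta_pos`, `strand`,
#'   `min_len` (`NA` = unmappable).
#' @export
min_unique_length <- function(genome, positions,
                              lengths = seq(10L, 65L, by = 5L),
                              score_min = 10, alt_mismatch_limit = 2L,
                              strands = c("+", "-")) {
  genome <- as_ref_genome(genome)
  if (inherits(positions, "ta_index")) positions <- ta_sites(positions)
  grid <- expand.grid(row = seq_len(nrow(positions)), strand = strands,
                      stringsAsFactors = FALSE)
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    i <- grid$row[g]
    strand <- grid$strand[g]
    nm <- positions$seqname[i]
    pos <- positions$pos[i]
    min_len <- NA_integer_
    for (L in lengths) {
      mock <- generate_mock_reads(genome,
                                  data.frame(seqname = nm, pos = pos),
                                  lengths = L)
      mock <- mock[mock$strand == strand, , drop = FALSE]
      if (nrow(mock) == 0L) next  # read would run off the sequence end
      hits <- align_reads(setNames(mock$read, "q"), genome,
                          max_mismatch = alt_mismatch_limit,
                          max_reported_hits = .Machine$integer.max)
      origin_start <- if (strand == "+") pos else pos + 2L - L
      at_origin <- hits$seqname == nm & hits$start == origin_start &
        hits$strand == strand
      accurate <- any(at_origin & hits$score > score_min)
      ambiguous <- any(!at_origin & hits$mismatches < alt_mismatch_limit)
      if (accurate && !ambiguous) {
        min_len <- L
        break
      }
    }
    res[[g]] <- data.frame(seqname = nm, ta_pos = pos, strand = strand,
                           min_len = min_len, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$seqname, out$ta_pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mappability", "data.frame")
  out
}

#' Filter experimental reads by the mappability minimum
#'
#' A read is retained iff its length is at least the minimum unique length of
#' its (TA, strand); reads at unmappable records, and reads at sites with no
#' record, are discarded. The discard log counts reads per reason.
#'
#' @param reads Data frame with `seqname`, `pos`, `strand`, `length` (one row
#'   per read; extra columns pass through).
#' @param mappability A `mappability` table from [min_unique_length()].
#' @return List with `retained` (data frame), `discarded` (with a `reason`
#'   column: `too_short`, `unmappable`, `no_record`) and `summary` (named
#'   counts; retained + discarded = input rows).
#' @export
filter_reads <- function(reads, mappability) {
  key <- paste(reads$seqname, reads$pos, reads$strand)
  mkey <- paste(mappability$seqname, mappability$ta_pos, mappability$strand)
  idx <- match(key, mkey)
  min_len <- mappability$min_len[idx]
  reason <- rep(NA_character_, nrow(reads))
  reason[is.na(idx)] <- "no_record"
  reason[!is.na(idx) & is.na(min_len)] <- "unmappable"
  reason[!is.na(min_len) & reads$length < min_len] <- "too_short"
  keep <- is.na(reason)
  discarded <- reads[!keep, , drop = FALSE]
  discarded$reason <- reason[!keep]
  summary <- c(
    retained = sum(keep),
    too_short = sum(reason == "too_short", na.rm = TRUE),
    unmappable = sum(reason == "unmappable", na.rm = TRUE),
    no_record = sum(reason == "no_record", na.rm = TRUE)
  )
  list(retained = reads[keep, , drop = FALSE], discarded = discarded,
       summary = summary)
}
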