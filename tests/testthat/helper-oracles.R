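# Brute-force oracles kept deliberately independent of the package internals:
# naive position-by-position scans against which the indexed/vectorized
# implementations are checked.

naive_ta_scan <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(integer(0))
  which(vapply(seq_len(n - 1L),
               function(i) substr(s, i, i + 1L) == "TA", logical(1)))
}

iupac_match_char <- function(pattern_char, base) {
  switch(pattern_char,
         A = base == "A", C = base == "C", G = base == "G", T = base == "T",
         W = base %in% c("A", "T"),
         N = base %in% c("A", "C", "G", "T"),
         FALSE)
}

naive_motif_scan <- function(s, motif, both_strands = TRUE) {
  scan_strand <- function(pat) {
    L <- nchar(pat)
    pat_chars <- strsplit(pat, "")[[1L]]
    hits <- integer(0)
    for (i in seq_len(max(0L, nchar(s) - L + 1L))) {
      ok <- all(mapply(iupac_match_char, pat_chars,
                       strsplit(substr(s, i, i + L - 1L), "")[[1L]]))
      if (ok) hits <- c(hits, i)
    }
    hits
  }
  out <- data.frame(start = scan_strand(motif), strand = "+")
  if (both_strands) {
    rc <- revcomp(motif)
    out <- rbind(out, data.frame(start = scan_strand(rc), strand = "-"))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# Hamming-distance scan of one read against every position / both strands.
naive_align <- function(read, genome, max_mismatch = 2L) {
  genome <- unclass(sbkit::ref_genome(genome))
  L <- nchar(read)
  read_fwd <- strsplit(read, "")[[1L]]
  read_rev <- strsplit(revcomp(read), "")[[1L]]
  out <- list()
  for (nm in names(genome)) {
    chars <- strsplit(genome[[nm]], "")[[1L]]
    n <- length(chars)
    if (L > n) next
    starts <- seq_len(n - L + 1L)
    for (strand in c("+", "-")) {
      rc <- if (strand == "+") read_fwd else read_rev
      mm <- integer(length(starts))
      for (j in seq_len(L)) {
        mm <- mm + (chars[starts + j - 1L] != rc[j])
      }
      hit <- which(mm <= max_mismatch)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          seqname = nm, start = starts[hit], strand = strand,
          mismatches = mm[hit], score = L - 2L * mm[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seqname = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      score = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$seqname, res$start, res$strand), , drop = FALSE]
}

# Small annotated toy genome shared by annotation-dependent tests.
toy_annotation <- function() {
  annotation_set(data.frame(
    seqname = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(101, 121, 161, 301, 51),
    end = c(200, 140, 180, 400, 150),
    feature = c("gene", "exon", "exon", "gene", "gene"),
    label = c("GeneA", "GeneA", "GeneA", "GeneB", "GeneC"),
    stringsAsFactors = FALSE
  ))
}
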