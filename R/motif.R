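# IUPAC motif scanning. Only the codes the footprint/restriction motifs need
# are supported (A C G T plus N and W); an assembly-gap N in the genome is
# never matched, even by pattern N -- conservative handling of gaps.

IUPAC_CLASSES <- c(
  A = "A", C = "C", G = "G", T = "T",
  N = "[ACGT]", W = "[AT]"
)

iupac_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1L]]
  bad <- setdiff(chars, names(IUPAC_CLASSES))
  if (length(bad)) {
    stop("invalid IUPAC code(s) in motif: ", paste(unique(bad), collapse = ", "))
  }
  paste(IUPAC_CLASSES[chars], collapse = "")
}

#' Reverse-complement a nucleotide or IUPAC motif string
#'
#' Handles A/C/G/T/N plus the ambiguity code W (A or T), which is its own
#' complement.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("TACAGTA")
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTNWacgtnw", "TGCANWtgcanw", x)
  vapply(strsplit(flipped, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

#' Scan a genome for an IUPAC motif
#'
#' Finds every occurrence (including overlapping ones) of `motif` on the plus
#' strand and, optionally, the minus strand. Minus-strand hits are reported at
#' plus-strand coordinates of the matched footprint. A palindromic motif such
#' as the SB footprint consensus TACWGTA therefore yields a hit on each strand
#' at the same coordinates; double counting is intentionally not collapsed.
#'
#' Supported IUPAC codes: A, C, G, T, N (any base) and W (A or T). An `N` in
#' the genome matches nothing.
#'
#' @param genome A `ref_genome` (or coercible).
#' @param motif IUPAC pattern string, e.g. `"ACNGT"` (HpyCH4III site) or
#'   `"TACWGTA"` (footprint consensus).
#' @param both_strands Scan the minus strand too? Default `TRUE`.
#' @param motif_id Label stored in the output; defaults to `motif`.
#' @return Data frame with columns `seqname`, `start`, `end` (1-based
#'   inclusive, plus-strand frame), `strand`, `motif_id`, sorted by sequence
#'   and position.
#' @examples
#' scan_motif(c(chr = "AATACTGTAGC"), "TACWGTA")
#' @export
scan_motif <- function(genome, motif, both_strands = TRUE, motif_id = motif) {
  genome <- as_ref_genome(genome)
  len <- nchar(motif)
  scan_one <- function(seqname, pattern, strand) {
    # zero-width lookahead so overlapping occurrences are all reported
    m <- gregexpr(paste0("(?=", pattern, ")"), genome[[seqname]], perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(
      seqname = seqname, start = as.integer(m), end = as.integer(m) + len - 1L,
      strand = strand, motif_id = motif_id, stringsAsFactors = FALSE
    )
  }
  fwd <- iupac_regex(motif)
  rev <- iupac_regex(revcomp(motif))
  out <- list()
  for (nm in names(genome)) {
    out[[length(out) + 1L]] <- scan_one(nm, fwd, "+")
    if (both_strands) {
      out[[length(out) + 1L]] <- scan_one(nm, rev, "-")
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      motif_id = character(), stringsAsFactors = FALSE)
  }
  out[order(out$seqname, out$start, out$strand), , drop = FALSE]
}
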