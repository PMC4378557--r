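#' Annotation interval sets
#'
#' An annotation set holds genomic intervals of feature types `gene`, `exon`,
#' `intron` and `repeat`. Internally coordinates are 1-based inclusive; the
#' BED-like TSV reader/writer ([read_annotation()]) converts from/to 0-based
#' half-open at the file boundary.
#'
#' @param intervals Data frame with columns `seqname`, `start`, `end`
#'   (1-based inclusive), `feature` (one of gene/exon/intron/repeat) and
#'   optionally `label`.
#' @return An `annotation_set`: the validated data frame.
#' @examples
#' annotation_set(data.frame(seqname = "chr1", start = 101, end = 200,
#'                           feature = "gene", label = "GeneA"))
#' @export
annotation_set <- function(intervals) {
  required <- c("seqname", "start", "end", "feature")
  missing <- setdiff(required, names(intervals))
  if (length(missing)) {
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"label" %in% names(intervals)) intervals$label <- ""
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  if (any(intervals$start > intervals$end)) {
    stop("annotation intervals must satisfy start <= end")
  }
  ok <- intervals$feature %in% c("gene", "exon", "intron", "repeat")
  if (!all(ok)) {
    stop("unknown feature type(s): ",
         paste(unique(intervals$feature[!ok]), collapse = ", "))
  }
  intervals <- intervals[, c("seqname", "start", "end", "feature", "label")]
  class(intervals) <- c("annotation_set", "data.frame")
  intervals
}

#' Read/write BED-like annotation TSV
#'
#' File schema: tab-separated `chrom`, `start`, `end`, `feature`, `label`
#' with 0-based half-open coordinates (BED convention), no header. Reading
#' converts to the internal 1-based inclusive frame.
#'
#' @param path File path.
#' @param annot An `annotation_set`.
#' @return `read_annotation()` returns an `annotation_set`.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("annotation TSV needs >= 4 columns")
  names(df)[1:4] <- c("seqname", "start", "end", "feature")
  names(df)[5] <- if (ncol(df) >= 5L) "label" else names(df)[5]
  if (ncol(df) < 5L) df$label <- ""
  df$start <- df$start + 1L  # 0-based half-open -> 1-based inclusive
  annotation_set(df[, c("seqname", "start", "end", "feature", "label")])
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annot, path) {
  annot <- as.data.frame(annot)
  out <- data.frame(annot$seqname, annot$start - 1L, annot$end,
                    annot$feature, annot$label)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

annot_granges <- function(annot, features, seqlevels = NULL) {
  sub <- annot[annot$feature %in% features, , drop = FALSE]
  nm <- if (is.null(seqlevels)) sub$seqname
  else factor(sub$seqname, levels = seqlevels)
  GenomicRanges::GRanges(nm, IRanges::IRanges(sub$start, sub$end))
}

#' Classify genomic positions as exon, intron or intergenic
#'
#' A position overlapping an exon interval is `exon` regardless of other
#' overlaps (exon precedence reflects the mutational-consequence emphasis on
#' coding sequence); a position inside a gene or explicit intron interval but
#' no exon is `intron`; anything else is `intergenic`.
#'
#' @param seqnames,positions Parallel vectors of sequence names and 1-based
#'   positions.
#' @param annot An `annotation_set`.
#' @param known_seqnames Optional character vector of valid sequence names
#'   (e.g. `names(genome)`). A queried name found neither here nor in the
#'   annotation raises an error.
#' @return Character vector in `{exon, intron, intergenic}`.
#' @examples
#' ann <- annotation_set(data.frame(
#'   seqname = "chr1", start = c(101, 121), end = c(200, 140),
#'   feature = c("gene", "exon"), label = "GeneA"))
#' classify_sites("chr1", c(130, 150, 50), ann)
#' @export
classify_sites <- function(seqnames, positions, annot,
                           known_seqnames = NULL) {
  if (length(seqnames) == 1L) seqnames <- rep_len(seqnames, length(positions))
  stopifnot(length(seqnames) == length(positions))
  valid <- union(unique(annot$seqname), known_seqnames)
  unknown <- setdiff(unique(seqnames), valid)
  if (length(unknown)) {
    stop("unknown sequence name(s): ", paste(unknown, collapse = ", "))
  }
  if (length(positions) == 0L) return(character(0))
  gr <- GenomicRanges::GRanges(factor(seqnames, levels = valid),
                               IRanges::IRanges(positions, positions))
  hit_any <- function(features) {
    target <- annot_granges(annot, features, seqlevels = valid)
    GenomicRanges::countOverlaps(gr, target) > 0L
  }
  out <- rep("intergenic", length(gr))
  out[hit_any(c("gene", "intron"))] <- "intron"
  out[hit_any("exon")] <- "exon"
  out
}

#' Genomic TA composition by feature class
#'
#' Fraction of indexed TA dinucleotides falling in exons, introns and
#' intergenic space, classifying each TA by the position of its T.
#'
#' @param index A `ta_index`.
#' @param annot An `annotation_set`.
#' @param known_seqnames Passed to [classify_sites()].
#' @return Named numeric vector `c(exon=, intron=, intergenic=)` summing to 1.
#' @export
ta_composition <- function(index, annot, known_seqnames = NULL) {
  stopifnot(inherits(index, "ta_index"))
  if (index$total_ta_count == 0L) stop("TA index is empty")
  sites <- ta_sites(index)
  cls <- classify_sites(sites$seqname, sites$pos, annot,
                        known_seqnames = known_seqnames)
  tab <- table(factor(cls, levels = c("exon", "intron", "intergenic")))
  setNames(as.numeric(tab) / sum(tab), names(tab))
}
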