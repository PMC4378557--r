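# Shared I/O: the site-table TSV schema consumed and produced by every
# module, BED writers, and the 0-based/1-based coordinate converters used at
# file boundaries (internal coordinates are 1-based inclusive throughout).

#' Convert between internal and BED coordinates
#'
#' Internal coordinates are 1-based inclusive; BED files are 0-based
#' half-open. `to_bed_coords()` and `from_bed_coords()` are the only places
#' the conversion happens.
#'
#' @param start,end Interval bounds (vectors).
#' @return A two-column data frame `start`, `end` in the target convention.
#' @export
to_bed_coords <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

#' @rdname to_bed_coords
#' @export
from_bed_coords <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

SITE_TABLE_COLS <- c("sample", "seqname", "pos", "strand",
                     "read_count", "ligation_point_count")

#' Read a site table TSV
#'
#' Schema (tab-separated, with header): `sample`, `seqname`, `pos` (1-based),
#' `strand` (+/-), `read_count`, `ligation_point_count`. Duplicate
#' `(sample, seqname, pos, strand)` rows are summed with a warning. Rows with
#' malformed coordinates or negative counts raise an error naming the line.
#'
#' @param path File path.
#' @param genome Optional `ref_genome`; when given, positions are checked
#'   against sequence bounds.
#' @return Data frame with the schema columns plus convenience aliases
#'   `reads` and `ligation_points`.
#' @export
read_site_table <- function(path, genome = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(SITE_TABLE_COLS, names(df))
  if (length(missing)) {
    stop("site table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, SITE_TABLE_COLS]
  check_int <- function(col, min) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | v < min)
    if (length(bad)) {
      stop("malformed '", col, "' at line ", bad[1] + 1L, " of ", path)
    }
    v
  }
  df$pos <- check_int("pos", 1L)
  df$read_count <- check_int("read_count", 0L)
  df$ligation_point_count <- check_int("ligation_point_count", 0L)
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("malformed 'strand' at line ", bad_strand[1] + 1L, " of ", path)
  }
  if (!is.null(genome)) {
    len <- seq_lengths(as_ref_genome(genome))
    unknown <- setdiff(unique(df$seqname), names(len))
    if (length(unknown)) {
      stop("site table names unknown sequence(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(df$pos > len[df$seqname])) {
      stop("site positions exceed sequence lengths")
    }
  }
  key <- paste(df$sample, df$seqname, df$pos, df$strand)
  if (anyDuplicated(key)) {
    warning("duplicate site rows summed in ", path)
    df <- do.call(rbind, lapply(split(df, key), function(d) {
      d$read_count[1] <- sum(d$read_count)
      d$ligation_point_count[1] <- sum(d$ligation_point_count)
      d[1, , drop = FALSE]
    }))
    df <- df[order(df$sample, df$seqname, df$pos, df$strand), , drop = FALSE]
    rownames(df) <- NULL
  }
  df$reads <- df$read_count
  df$ligation_points <- df$ligation_point_count
  df
}

#' Write a site table TSV
#'
#' Inverse of [read_site_table()]; accepts profiles with `reads` /
#' `ligation_points` aliases and fills missing schema columns.
#'
#' @param sites Data frame.
#' @param path Output path.
#' @param sample_id Used when `sites` lacks a `sample` column.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path, sample_id = "sample1") {
  df <- as.data.frame(sites)
  if (!"sample" %in% names(df)) df$sample <- sample_id
  if (!"read_count" %in% names(df)) {
    df$read_count <- if ("reads" %in% names(df)) df$reads else 0L
  }
  if (!"ligation_point_count" %in% names(df)) {
    df$ligation_point_count <-
      if ("ligation_points" %in% names(df)) df$ligation_points else 0L
  }
  if (!"strand" %in% names(df)) df$strand <- "+"
  write.table(df[, SITE_TABLE_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write intervals or sites as BED
#'
#' BED3+ writer (0-based half-open) for motif hits, TA positions or windows.
#' Point features (a `pos` column) are written as 1-bp intervals; interval
#' features use `start`/`end`. A `strand` column, when present, is written as
#' BED6 with the `name`/`score` columns filled.
#'
#' @param x Data frame with `seqname` and either `pos` or `start`+`end`;
#'   optional `strand`, `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if ("pos" %in% names(x)) {
    start <- x$pos  # 1-bp feature: the T position itself
    end <- x$pos
  } else {
    start <- x$start
    end <- x$end
  }
  bed <- cbind(x$seqname, to_bed_coords(start, end))
  names(bed) <- c("chrom", "start", "end")
  if ("strand" %in% names(x)) {
    bed$name <- if ("name" %in% names(x)) x$name else "."
    bed$score <- 0L
    bed$strand <- x$strand
  }
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bias-scan window report
#'
#' TSV mirroring the columns of a window-enrichment report: 1-based window
#' label, TA count, observed/expected site counts, raw and
#' Bonferroni-corrected p-values, flags and overlapping gene labels.
#'
#' @param windows Window table from [window_pvalues()] /[flag_windows()].
#' @param path Output path.
#' @param annot Optional `annotation_set` supplying gene labels.
#' @return `path`, invisibly.
#' @export
write_window_report <- function(windows, path, annot = NULL) {
  df <- as.data.frame(windows)
  if (!is.null(annot)) {
    genes <- annot[annot$feature == "gene", , drop = FALSE]
    gr_g <- GenomicRanges::GRanges(genes$seqname,
                                   IRanges::IRanges(genes$start, genes$end))
    gr_w <- GenomicRanges::GRanges(df$seqname,
                                   IRanges::IRanges(df$start, df$end))
    ov <- GenomicRanges::findOverlaps(gr_w, gr_g)
    lab <- tapply(genes$label[subjectHits(ov)], queryHits(ov),
                  function(g) paste(unique(g), collapse = ","))
    df$genes <- ""
    df$genes[as.integer(names(lab))] <- unname(lab)
  }
  keep <- intersect(c("label", "seqname", "start", "end", "ta_count",
                      "observed", "expected", "p_raw", "p_bonferroni",
                      "enriched", "local_chromosome", "within_local_window",
                      "repeat_overlap", "genes"), names(df))
  write.table(df[, keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
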