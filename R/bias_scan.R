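# Detection-bias scan: fixed-width window partition, Poisson Regression
# Insertion Model (PRIM) expected counts, exact Poisson upper-tail p-values
# with Bonferroni correction, and local/repeat flagging.

#' Format a window label in 1-based inclusive report coordinates
#'
#' Internal coordinates are 1-based inclusive; report labels render them with
#' thousands separators, e.g. `chr11:3,180,001-3,200,000`.
#'
#' @param seqname,start,end Window coordinates (1-based inclusive).
#' @return Character vector of labels.
#' @export
format_window_label <- function(seqname, start, end) {
  sprintf("%s:%s-%s", seqname,
          formatC(start, format = "d", big.mark = ","),
          formatC(end, format = "d", big.mark = ","))
}

#' Partition a genome into fixed-width windows
#'
#' Non-overlapping tiling of each sequence from its first base; the final
#' partial window is retained. Each window records its TA-dinucleotide count
#' (a TA belongs to the window containing its T).
#'
#' @param genome A `ref_genome` (or coercible).
#' @param width Window width in bp. Default 20000.
#' @param ta_index Optional precomputed [build_ta_index()].
#' @return Data frame with `seqname`, `start`, `end` (1-based inclusive),
#'   `label`, `ta_count`.
#' @export
partition_windows <- function(genome, width = 20000L, ta_index = NULL) {
  stopifnot(width > 0)
  genome <- as_ref_genome(genome)
  if (is.null(ta_index)) ta_index <- build_ta_index(genome)
  len <- seq_lengths(genome)
  out <- lapply(names(genome), function(nm) {
    starts <- seq.int(1L, len[[nm]], by = width)
    ends <- pmin(starts + width - 1L, len[[nm]])
    pos <- ta_index$positions[[nm]]
    counts <- if (length(pos)) {
      tabulate(findInterval(pos, starts), nbins = length(starts))
    } else {
      integer(length(starts))
    }
    data.frame(seqname = nm, start = starts, end = ends,
               label = format_window_label(nm, starts, ends),
               ta_count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Distinct insertion sites per sample: one site per (sample, seqname, pos),
# collapsing reads and the two ITR orientations.
dedup_sites <- function(sites) {
  if (!"sample" %in% names(sites)) sites$sample <- "pooled"
  sites[!duplicated(sites[, c("sample", "seqname", "pos")]), , drop = FALSE]
}

assign_windows <- function(windows, sites) {
  hit <- rep(NA_integer_, nrow(sites))
  for (nm in unique(sites$seqname)) {
    w <- which(windows$seqname == nm)
    if (!length(w)) next
    rows <- which(sites$seqname == nm)
    hit[rows] <- w[findInterval(sites$pos[rows], windows$start[w])]
  }
  hit
}

#' Fit the Poisson Regression Insertion Model (PRIM)
#'
#' Log-linear Poisson model of per-window distinct insertion-site counts with
#' `log(ta_count)` as covariate and chromosome as a factor (dropped when only
#' one chromosome is present). Insertions are deduplicated to one site per
#' sample per TA before pooling across samples. Windows with zero TA
#' dinucleotides cannot receive an insertion and are excluded from fitting.
#'
#' Under an unbiased integration pattern (each TA equally likely), the
#' expected count is proportional to the window's TA count: the
#' `log(ta_count)` coefficient is 1 and chromosome effects are log rate
#' ratios.
#'
#' @param windows Window table from [partition_windows()].
#' @param sites Site table pooled across samples (columns `seqname`, `pos`,
#'   optional `sample`).
#' @return Object of class `prim_fit`: list with `fit` (the [stats::glm()]
#'   object), `windows` (with `observed` and `expected` columns; untested
#'   windows have `expected = NA`), `total_insertions`, `n_tested`.
#' @export
fit_prim <- function(windows, sites) {
  sites <- dedup_sites(sites)
  windows$observed <- tabulate(assign_windows(windows, sites),
                               nbins = nrow(windows))
  tested <- windows$ta_count > 0L
  dat <- windows[tested, , drop = FALSE]
  if (sum(dat$observed) == 0L) {
    stop("degenerate design: no insertion sites fall in tested windows")
  }
  formula <- if (length(unique(dat$seqname)) > 1L) {
    observed ~ log(ta_count) + seqname
  } else {
    observed ~ log(ta_count)
  }
  fit <- glm(formula, family = poisson(), data = dat)
  windows$expected <- NA_real_
  windows$expected[tested] <- as.numeric(predict(fit, type = "response"))
  structure(list(fit = fit, windows = windows,
                 total_insertions = nrow(sites),
                 n_tested = sum(tested)),
            class = "prim_fit")
}

#' @export
print.prim_fit <- function(x, ...) {
  cat("PRIM fit:", x$n_tested, "tested windows,",
      x$total_insertions, "pooled insertion sites\n")
  print(coef(x$fit))
  invisible(x)
}

#' Per-window enrichment p-values with Bonferroni correction
#'
#' Compares each tested window's observed distinct-site count to its
#' PRIM-expected mean using the exact Poisson upper tail,
#' `P(X >= observed | expected)` — reproducible and conservative at small
#' means. Bonferroni correction multiplies by the number of tested windows.
#' Windows with no TA sites are reported with `p_raw = 1` and excluded from
#' the correction family.
#'
#' @param prim A `prim_fit` from [fit_prim()].
#' @param alpha Family-wise significance level applied to the
#'   Bonferroni-corrected p-value. Default 0.05.
#' @return The window table with `p_raw`, `p_bonferroni` and logical
#'   `enriched` columns; attribute `n_tested`.
#' @export
window_pvalues <- function(prim, alpha = 0.05) {
  stopifnot(inherits(prim, "prim_fit"))
  w <- prim$windows
  tested <- w$ta_count > 0L
  w$p_raw <- 1
  w$p_raw[tested] <- ppois(w$observed[tested] - 1L, w$expected[tested],
                           lower.tail = FALSE)
  w$p_bonferroni <- 1
  w$p_bonferroni[tested] <- pmin(1, w$p_raw[tested] * prim$n_tested)
  w$enriched <- tested & w$p_bonferroni < alpha
  attr(w, "n_tested") <- prim$n_tested
  attr(w, "alpha") <- alpha
  w
}

#' Flag windows for local hopping and repeat overlap
#'
#' * `local_chromosome`: the window's sequence hosts a donor concatemer.
#' * `within_local_window`: additionally within `local_window` bp of one.
#' * `repeat_overlap`: the window intersects a repeat interval (from an
#'   optional repeat annotation track).
#'
#' The non-local report of a bias scan excludes `local_chromosome` windows.
#'
#' @param windows Window table (from [window_pvalues()] or
#'   [partition_windows()]).
#' @param concatemers List of [concatemer_spec()] objects (possibly empty).
#' @param local_window Local-hopping half-width in bp. Default 6e6.
#' @param repeats Optional `annotation_set` whose `repeat` intervals are
#'   used.
#' @return The window table with logical `local_chromosome`,
#'   `within_local_window`, `repeat_overlap` columns.
#' @export
flag_windows <- function(windows, concatemers = list(), local_window = 6e6,
                         repeats = NULL) {
  if (inherits(concatemers, "concatemer_spec")) {
    concatemers <- list(concatemers)
  }
  windows$local_chromosome <- FALSE
  windows$within_local_window <- FALSE
  for (cc in concatemers) {
    on_chr <- windows$seqname == cc$seqname
    windows$local_chromosome <- windows$local_chromosome | on_chr
    near <- on_chr &
      windows$start <= cc$position + local_window &
      windows$end >= cc$position - local_window
    windows$within_local_window <- windows$within_local_window | near
  }
  windows$repeat_overlap <- FALSE
  if (!is.null(repeats)) {
    lev <- union(unique(windows$seqname), unique(repeats$seqname))
    rep_gr <- annot_granges(repeats, "repeat", seqlevels = lev)
    if (length(rep_gr)) {
      win_gr <- GenomicRanges::GRanges(
        factor(windows$seqname, levels = lev),
        IRanges::IRanges(windows$start, windows$end))
      windows$repeat_overlap <-
        GenomicRanges::countOverlaps(win_gr, rep_gr) > 0L
    }
  }
  windows
}

#' Simulate unselected insertion sites with per-chromosome rates
#'
#' Uniform (selection-free) integration model used for bias-scan evaluation:
#' every TA dinucleotide is hit independently with its chromosome's
#' probability, yielding distinct sites whose per-window counts are binomial
#' in the window's TA count — the regime PRIM models.
#'
#' @param ta_index A `ta_index`.
#' @param p_insert Per-TA insertion probability: single value or named vector
#'   (per sequence).
#' @param sample_id Sample label. Default `"pooled"`.
#' @param seed Integer seed.
#' @return Site table (`sample`, `seqname`, `pos`, `strand`).
#' @export
simulate_uniform_insertions <- function(ta_index, p_insert,
                                        sample_id = "pooled", seed = NULL) {
  stopifnot(inherits(ta_index, "ta_index"), all(p_insert >= 0),
            all(p_insert <= 1))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  out <- lapply(names(ta_index$positions), function(nm) {
    pos <- ta_index$positions[[nm]]
    p <- if (length(p_insert) == 1L) p_insert else p_insert[[nm]]
    hit <- runif(length(pos)) < p
    if (!any(hit)) return(NULL)
    data.frame(sample = sample_id, seqname = nm, pos = pos[hit],
               strand = sample(c("+", "-"), sum(hit), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sample = character(), seqname = character(),
                      pos = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out
}
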