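# Footprint-calling pipeline: sequential filters on footprint-library site
# tables, depth-based confidence tiers, genic annotation, validation-scaled
# estimation of the true footprint burden, and the exon-enrichment test.

site_key <- function(df) paste(df$seqname, df$pos, sep = ":")

#' Call candidate excision footprints from footprint-library site tables
#'
#' Applies, in order, the four filters that distill raw footprint-library
#' loci into candidate excision footprints:
#'
#' 1. sites also detected in the tissue-matched normal sample are removed
#'    (endogenous TACWGTA loci);
#' 2. sites in the sample's own set of clonally expanded transposon
#'    insertions are removed (every ITR/genome junction carries an
#'    HpyCH4III site);
#' 3. sites detected in more than one tumor are removed from all samples
#'    (true footprints are expected to be private to a sample);
#' 4. only sites supported by at least one read on each strand are kept,
#'    which guarantees an intact 7-mer footprint across the locus.
#'
#' Filters 1–3 are set subtractions whose removal sets are computed from the
#' original inputs, so their order is immaterial.
#'
#' @param tumor_tables Named list of per-sample site tables (data frames with
#'   `seqname`, `pos`, `strand`, `reads`).
#' @param normal_table Site table of the matched normal sample. Required: the
#'   pipeline is undefined without a normal control.
#' @param clonal_insertions Named list (same names as `tumor_tables`) of data
#'   frames of each sample's clonally expanded insertion sites (`seqname`,
#'   `pos`); may be `NULL` for none.
#' @return Named list of candidate data frames with columns `seqname`, `pos`,
#'   `plus_reads`, `minus_reads`, sorted by coordinate.
#' @export
call_candidates <- function(tumor_tables, normal_table,
                            clonal_insertions = NULL) {
  if (is.null(normal_table)) {
    stop("a matched normal site table is required")
  }
  if (is.null(names(tumor_tables)) || any(!nzchar(names(tumor_tables)))) {
    stop("tumor_tables must be a named list")
  }
  normal_keys <- unique(site_key(normal_table))
  sample_keys <- lapply(tumor_tables, function(t) unique(site_key(t)))
  tally <- table(unlist(sample_keys))
  redundant <- names(tally)[tally > 1L]
  out <- list()
  for (nm in names(tumor_tables)) {
    tab <- tumor_tables[[nm]]
    clonal_keys <- if (!is.null(clonal_insertions[[nm]])) {
      unique(site_key(clonal_insertions[[nm]]))
    } else character(0)
    keys <- site_key(tab)
    keep <- !(keys %in% normal_keys) & !(keys %in% clonal_keys) &
      !(keys %in% redundant)
    tab <- tab[keep, , drop = FALSE]
    plus <- tab[tab$strand == "+", , drop = FALSE]
    minus <- tab[tab$strand == "-", , drop = FALSE]
    agg <- function(d) {
      if (nrow(d) == 0L) {
        return(data.frame(key = character(), reads = integer()))
      }
      r <- tapply(d$reads, site_key(d), sum)
      data.frame(key = names(r), reads = as.integer(r),
                 stringsAsFactors = FALSE)
    }
    p <- agg(plus); m <- agg(minus)
    both <- merge(p, m, by = "key", suffixes = c("_plus", "_minus"))
    if (nrow(both) == 0L) {
      out[[nm]] <- data.frame(seqname = character(), pos = integer(),
                              plus_reads = integer(), minus_reads = integer(),
                              stringsAsFactors = FALSE)
      next
    }
    parts <- strsplit(both$key, ":", fixed = TRUE)
    cand <- data.frame(
      seqname = vapply(parts, `[`, character(1), 1L),
      pos = as.integer(vapply(parts, `[`, character(1), 2L)),
      plus_reads = both$reads_plus,
      minus_reads = both$reads_minus,
      stringsAsFactors = FALSE
    )
    cand <- cand[order(cand$seqname, cand$pos), , drop = FALSE]
    rownames(cand) <- NULL
    out[[nm]] <- cand
  }
  out
}

#' Assign confidence tiers to footprint candidates
#'
#' A candidate is `high` confidence when its total sequencing depth
#' (`plus_reads + minus_reads`) is at least the `q`-th percentile of the
#' depths observed at simultaneously sequenced clonally expanded insertion
#' loci; otherwise `low`. The percentile uses linear interpolation
#' ([stats::quantile()] type 7). The cutoff percentile is a tunable of this
#' package (the comparison to clonal-site depth is the method; the exact
#' quantile is not pinned down by it).
#'
#' @param candidates Candidate data frame from [call_candidates()] (one
#'   sample) or a named list thereof.
#' @param clonal_depths Numeric vector of read depths at known clonal
#'   insertion loci. Must be non-empty.
#' @param q Percentile in \[0, 100\]. Default 25.
#' @return Input with a `confidence` column added (and `depth`).
#' @export
assign_confidence <- function(candidates, clonal_depths, q = 25) {
  if (length(clonal_depths) == 0L) {
    stop("clonal reference depths must be non-empty")
  }
  stopifnot(q >= 0, q <= 100)
  thr <- quantile(clonal_depths, probs = q / 100, names = FALSE, type = 7)
  one <- function(cand) {
    cand$depth <- cand$plus_reads + cand$minus_reads
    cand$confidence <- ifelse(cand$depth >= thr, "high", "low")
    cand
  }
  if (is.data.frame(candidates)) one(candidates) else lapply(candidates, one)
}

#' Estimate the number of bona fide footprints from validation rates
#'
#' Scales the predicted candidate counts in each confidence tier by the
#' fraction of tested candidates of that tier that validated, then rounds the
#' combined estimate up to the next whole number:
#' `ceiling(n_high * r_high + n_low * r_low)`.
#'
#' @param counts Named numeric vector `c(high = , low = )` of predicted
#'   candidate counts per tier.
#' @param validation Data frame with columns `tier` (high/low), `n_tested`,
#'   `n_confirmed` — typically pooled across samples.
#' @return Integer estimate of true footprints.
#' @examples
#' val <- data.frame(tier = c("high", "low"),
#'                   n_tested = c(12, 18), n_confirmed = c(12, 1))
#' estimate_true_footprints(c(high = 149, low = 69), val)  # 153
#' @export
estimate_true_footprints <- function(counts, validation) {
  stopifnot(all(c("high", "low") %in% names(counts)),
            all(c("tier", "n_tested", "n_confirmed") %in% names(validation)))
  rate <- function(tier) {
    row <- validation[validation$tier == tier, , drop = FALSE]
    if (nrow(row) != 1L) stop("validation must have exactly one row per tier")
    if (row$n_tested <= 0L) stop("zero candidates tested in tier '", tier, "'")
    if (row$n_confirmed < 0L || row$n_confirmed > row$n_tested) {
      stop("n_confirmed must lie in [0, n_tested]")
    }
    row$n_confirmed / row$n_tested
  }
  as.integer(ceiling(counts[["high"]] * rate("high") +
                       counts[["low"]] * rate("low")))
}

#' Per-tier validation rates
#'
#' Fraction of tested candidates per confidence tier that were confirmed by
#' targeted re-amplification and restriction digest.
#'
#' @param validation Data frame with `tier`, `n_tested`, `n_confirmed`.
#' @return Named numeric vector of confirmation rates, one per tier.
#' @examples
#' validation_rates(data.frame(tier = c("high", "low"),
#'                             n_tested = c(12, 18), n_confirmed = c(12, 1)))
#' @export
validation_rates <- function(validation) {
  if (any(validation$n_tested <= 0)) stop("n_tested must be positive")
  if (any(validation$n_confirmed < 0 |
            validation$n_confirmed > validation$n_tested)) {
    stop("n_confirmed must lie in [0, n_tested]")
  }
  setNames(validation$n_confirmed / validation$n_tested, validation$tier)
}

#' Annotate footprint candidates with genic feature classes
#'
#' Adds a `feature_class` column (exon/intron/intergenic, see
#' [classify_sites()]) to each sample's candidates.
#'
#' @param candidates Named list of candidate data frames (or a single data
#'   frame).
#' @param annot An `annotation_set`.
#' @param known_seqnames Passed to [classify_sites()].
#' @return Input with `feature_class` added.
#' @export
annotate_candidates <- function(candidates, annot, known_seqnames = NULL) {
  one <- function(cand) {
    cand$feature_class <- classify_sites(cand$seqname, cand$pos, annot,
                                         known_seqnames = known_seqnames)
    cand
  }
  if (is.data.frame(candidates)) one(candidates) else lapply(candidates, one)
}

#' Per-sample and pooled candidate summary
#'
#' Bookkeeping table in the style of a candidate-footprint report: total
#' candidates, intron and exon counts, and their percentages rounded to one
#' decimal place; one row per sample plus a pooled `total` row.
#'
#' @param candidates Named list of annotated candidate data frames (with
#'   `feature_class`).
#' @return Data frame with columns `sample`, `total`, `n_intron`,
#'   `pct_intron`, `n_exon`, `pct_exon`.
#' @export
footprint_summary <- function(candidates) {
  if (is.data.frame(candidates)) candidates <- list(sample = candidates)
  row <- function(nm, cand) {
    n <- nrow(cand)
    ni <- sum(cand$feature_class == "intron")
    ne <- sum(cand$feature_class == "exon")
    data.frame(
      sample = nm, total = n,
      n_intron = ni, pct_intron = if (n > 0) round(100 * ni / n, 1) else 0,
      n_exon = ne, pct_exon = if (n > 0) round(100 * ne / n, 1) else 0,
      stringsAsFactors = FALSE
    )
  }
  per <- do.call(rbind, Map(row, names(candidates), candidates))
  pooled <- row("total", do.call(rbind, candidates))
  out <- rbind(per, pooled)
  rownames(out) <- NULL
  out
}

#' Exon-enrichment test for footprint candidates
#'
#' Tests whether the observed proportion of exonic candidates differs from
#' the expected exonic fraction of TA sites (`p0`) using a one-sample
#' proportion z-test: `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)` with a
#' two-tailed standard-normal p-value. (A two-proportion z-test against a
#' genome-wide reference of effectively infinite size reduces to this form.)
#'
#' @param k Number of exonic candidates.
#' @param n Total candidates (> 0).
#' @param p0 Expected exonic TA fraction in (0, 1). In typical use this is the
#'   `exon` component of [ta_composition()] for the annotation at hand, not a
#'   hard-coded constant.
#' @return An object of class `htest` with the z statistic, p-value and
#'   estimate.
#' @examples
#' exon_enrichment_test(k = 13, n = 552, p0 = 0.015)
#' @export
exon_enrichment_test <- function(k, n, p0) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly between 0 and 1")
  if (n * p0 < 5 || n * (1 - p0) < 5) {
    warning("normal approximation may be poor: n*p0 or n*(1-p0) < 5")
  }
  phat <- k / n
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
  p <- 2 * pnorm(-abs(z))
  structure(list(
    statistic = c(z = z),
    p.value = min(p, 1),
    estimate = c(`observed proportion` = phat),
    null.value = c(`expected proportion` = p0),
    alternative = "two.sided",
    method = "One-sample proportion z-test (exonic footprint enrichment)",
    data.name = sprintf("%d exonic of %d candidates", k, n)
  ), class = "htest")
}
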