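# Semi-quantitative clonality stratification: percent-of-max normalization,
# abundance grouping, triplicate leave-one-out FDR, ligation-point counting
# and clonal-expansion summary metrics.

#' Normalize a read-count profile to its most abundant site
#'
#' Each site's count is expressed as a percentage of the maximum-count site
#' (the top site is set to 100%). When the profile contains declared site
#' classes (e.g. spike-in `standard` vs genomic sites), normalization is
#' performed within each class, mirroring how standards are scored against
#' the most abundant standard.
#'
#' @param profile Data frame with columns `seqname`, `pos`, `strand`, `reads`
#'   and optionally `ligation_points`, `class` (as produced by
#'   [simulate_replicates()] or [read_site_table()]).
#' @param metric `"reads"` (default) or `"ligation_points"`.
#' @param by_class Normalize within each level of a `class` column when
#'   present? Default `TRUE`.
#' @return The profile with a `pct_of_max` column in (0, 100].
#' @examples
#' p <- data.frame(seqname = "c", pos = 1:3, strand = "+",
#'                 reads = c(2000, 1000, 250))
#' normalize_to_max(p)$pct_of_max  # 100, 50, 12.5
#' @export
normalize_to_max <- function(profile, metric = c("reads", "ligation_points"),
                             by_class = TRUE) {
  metric <- match.arg(metric)
  if (!metric %in% names(profile)) {
    stop("profile has no '", metric, "' column")
  }
  vals <- profile[[metric]]
  if (nrow(profile) == 0L || all(vals == 0)) {
    stop("profile has no site with a positive count")
  }
  grp <- if (by_class && "class" %in% names(profile)) profile$class
  else rep("all", nrow(profile))
  top <- tapply(vals, grp, max)
  profile$pct_of_max <- 100 * vals / as.numeric(top[grp])
  profile
}

#' Group sites into abundance bins
#'
#' Assigns each site's normalized abundance to half-open bins `(lo, hi]`
#' defined by `edges`. Only the 5% boundary is anchored by the method (sites
#' at or above 5% of maximum are reproducibly detected); the remaining
#' default edges follow the spike-in tiers.
#'
#' @param values Numeric vector of normalized abundances in (0, 100], or a
#'   data frame with a `pct_of_max` column.
#' @param edges Strictly increasing bin edges starting at 0 and ending at
#'   100. Default `c(0, 1, 5, 12.5, 50, 100)`.
#' @return Factor of bin labels `(lo,hi]`, one per site (with a `bin` column
#'   added when `values` is a data frame).
#' @export
group_by_abundance <- function(values, edges = c(0, 1, 5, 12.5, 50, 100)) {
  stopifnot(all(diff(edges) > 0), edges[1] == 0,
            edges[length(edges)] == 100)
  if (is.data.frame(values)) {
    values$bin <- group_by_abundance(values$pct_of_max, edges)
    return(values)
  }
  if (any(values <= 0 | values > 100)) {
    stop("normalized abundances must lie in (0, 100]")
  }
  cut(values, breaks = edges, include.lowest = FALSE, right = TRUE)
}

#' Replicate-based false discovery rate for insertion-site detection
#'
#' Leave-one-out FDR over replicate libraries of one sample: each replicate
#' in turn is treated as a test set, the sites detected in *both* remaining
#' replicates form the true-positive set, and test-set sites absent from it
#' are false positives. The per-bin FDR (false positives / sites, binning
#' test-set sites by their normalized abundance within that replicate) is
#' averaged over the rotations; a bin unoccupied in a rotation does not
#' contribute to that bin's average. Presence is raw detection (count >= 1).
#'
#' @param replicates List of >= 2 profiles of the same sample (data frames
#'   with `seqname`, `pos`, `reads`). Normalization is recomputed per
#'   replicate with [normalize_to_max()].
#' @param edges Abundance bin edges, as in [group_by_abundance()].
#' @param metric Metric for normalization. Default `"reads"`.
#' @return Data frame of class `fdr_table`: `bin`, `lo`, `hi`, `n_sites`
#'   (test-set sites summed over rotations), `n_false`, `fdr` (mean over
#'   occupied rotations; `NaN` for never-occupied bins).
#' @export
estimate_fdr <- function(replicates, edges = c(0, 1, 5, 12.5, 50, 100),
                         metric = "reads") {
  if (length(replicates) < 2L) {
    stop("at least two replicate profiles are required")
  }
  keys <- lapply(replicates, site_key)
  nbin <- length(edges) - 1L
  labels <- levels(cut(numeric(0), breaks = edges))
  fdr_mat <- matrix(NA_real_, nrow = length(replicates), ncol = nbin)
  n_sites <- n_false <- matrix(0L, nrow = length(replicates), ncol = nbin)
  for (r in seq_along(replicates)) {
    tp <- Reduce(intersect, keys[-r])
    test <- normalize_to_max(replicates[[r]], metric = metric,
                             by_class = FALSE)
    bin <- group_by_abundance(test$pct_of_max, edges)
    false <- !(keys[[r]] %in% tp)
    for (b in seq_len(nbin)) {
      in_bin <- as.integer(bin) == b
      n_sites[r, b] <- sum(in_bin)
      n_false[r, b] <- sum(false & in_bin)
      if (any(in_bin)) {
        fdr_mat[r, b] <- sum(false & in_bin) / sum(in_bin)
      }
    }
  }
  out <- data.frame(
    bin = labels,
    lo = edges[-length(edges)],
    hi = edges[-1],
    n_sites = colSums(n_sites),
    n_false = colSums(n_false),
    fdr = colMeans(fdr_mat, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fdr_table", "data.frame")
  out
}

#' Count unique ligation points per site
#'
#' In shearing-based LM-PCR every template molecule carries a shear-derived
#' ligation point; the number of distinct shear positions per insertion site
#' is an alternative abundance metric to raw read count (and is bounded above
#' by it).
#'
#' @param fragments Named list mapping site keys to integer vectors of shear
#'   positions (genomic coordinates), one entry per observed read.
#' @return Named integer vector of distinct-shear-position counts.
#' @examples
#' count_ligation_points(list(siteA = c(10, 10, 12), siteB = integer(0)))
#' @export
count_ligation_points <- function(fragments) {
  vapply(fragments, function(p) length(unique(p)), integer(1))
}

#' Clonal-expansion summary metrics of an insertion profile
#'
#' * `top5_read_fraction`: percentage of all mapped reads assigned to the
#'   five most abundant sites (all sites when fewer than five) — high in
#'   clonally expanded tumors, low in unselected tissue.
#' * `gene_fraction`: percentage of distinct sites falling within gene
#'   intervals (requires `annot`).
#'
#' @param profile Data frame with `seqname`, `pos`, `reads`.
#' @param annot Optional `annotation_set` for `gene_fraction`.
#' @param known_seqnames Passed to [classify_sites()].
#' @return Named numeric vector (percent scale); `gene_fraction` is `NA`
#'   without annotation.
#' @export
clonal_expansion_metrics <- function(profile, annot = NULL,
                                     known_seqnames = NULL) {
  if (nrow(profile) == 0L) stop("profile is empty")
  reads <- sort(profile$reads, decreasing = TRUE)
  top5 <- 100 * sum(reads[seq_len(min(5L, length(reads)))]) / sum(reads)
  gene_frac <- NA_real_
  if (!is.null(annot)) {
    cls <- classify_sites(profile$seqname, profile$pos, annot,
                          known_seqnames = known_seqnames)
    gene_frac <- 100 * mean(cls != "intergenic")
  }
  c(top5_read_fraction = top5, gene_fraction = gene_frac)
}
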