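# Forward simulator of SB transposition screens. Generates every input the
# analysis modules consume: mutated genomes with insertions and excision
# footprints, clonal tumors with tiered site abundances, spike-in standards,
# replicate LM-PCR read-count profiles, and footprint-library site tables
# with endogenous-motif background plus a hidden truth table.

FOOTPRINT_VARIANTS <- c("TACAGTA", "TACTGTA")

#' Integrate a transposon at a TA dinucleotide
#'
#' SB integration duplicates the TA target site: the product is
#' `prefix + TA + transposon + TA + suffix`, growing the sequence by
#' `nchar(transposon) + 2`.
#'
#' @param sequence Nucleotide string.
#' @param ta_pos 1-based position of the T of the target TA.
#' @param transposon Transposon sequence to integrate.
#' @return The mutated sequence.
#' @examples
#' apply_insertion("AATAGC", 3, "GGGG")  # "AATA GGGG TA GC"
#' @export
apply_insertion <- function(sequence, ta_pos, transposon) {
  if (substr(sequence, ta_pos, ta_pos + 1L) != "TA") {
    stop("position ", ta_pos, " is not a TA dinucleotide")
  }
  paste0(substr(sequence, 1L, ta_pos + 1L), transposon, "TA",
         substr(sequence, ta_pos + 2L, nchar(sequence)))
}

#' Excise an integrated transposon, leaving a footprint
#'
#' Cut-and-paste remobilization removes the transposon but leaves three ITR-
#' derived nucleotides between the duplicated TAs: the donor locus ends up
#' carrying a 7-mer footprint (`TACAGTA` or `TACTGTA`), a net gain of 5 bp
#' over the pre-insertion sequence.
#'
#' @param sequence Nucleotide string containing an integrated transposon (as
#'   produced by [apply_insertion()]).
#' @param ta_pos 1-based position of the original TA (the T of the left
#'   duplicated TA).
#' @param transposon The integrated transposon sequence (used to locate and
#'   verify the element).
#' @param variant Footprint 7-mer, `"TACAGTA"` or `"TACTGTA"`.
#' @return The post-excision sequence.
#' @examples
#' s <- apply_insertion("AATAGC", 3, "GGGG")
#' apply_excision(s, 3, "GGGG", "TACAGTA")  # "AATACAGTAGC"
#' @export
apply_excision <- function(sequence, ta_pos, transposon,
                           variant = c("TACAGTA", "TACTGTA")) {
  variant <- match.arg(variant)
  tn_len <- nchar(transposon)
  block <- substr(sequence, ta_pos, ta_pos + tn_len + 3L)
  if (block != paste0("TA", transposon, "TA")) {
    stop("no integrated transposon found at position ", ta_pos)
  }
  paste0(substr(sequence, 1L, ta_pos - 1L), variant,
         substr(sequence, ta_pos + tn_len + 4L, nchar(sequence)))
}

#' Concatemer specification
#'
#' The donor concatemer: a multi-copy transposon transgene array at a fixed
#' genomic location, the source of mobilized transposons and the anchor for
#' local hopping.
#'
#' @param seqname,position Location of the concatemer.
#' @param copy_number Number of transposon copies (>= 1).
#' @param transposon_length Length of one transposon copy in bp.
#' @return A list of class `concatemer_spec`.
#' @export
concatemer_spec <- function(seqname, position, copy_number = 25L,
                            transposon_length = 2000L) {
  stopifnot(copy_number >= 1L, position >= 1L, transposon_length >= 1L)
  structure(list(seqname = seqname, position = as.integer(position),
                 copy_number = as.integer(copy_number),
                 transposon_length = as.integer(transposon_length)),
            class = "concatemer_spec")
}

#' Simulate transposition events from a donor concatemer
#'
#' Each event picks a target TA: with probability `p_local` uniformly from the
#' TAs within `local_window` bp of the concatemer on its own chromosome
#' (local hopping), otherwise uniformly from all remaining TAs. With
#' probability `p_remobilize` the inserted transposon subsequently excises,
#' leaving a footprint whose 7-mer variant is chosen uniformly between the
#' two consensus forms (the two are mechanistically symmetric).
#'
#' Defaults follow the observed geometry of SB local hopping: most local
#' re-integration lands within ~6 Mb of the donor site, and roughly 85% of
#' enriched windows in unselected screens sit on donor chromosomes.
#'
#' @param genome A `ref_genome`.
#' @param concatemer A [concatemer_spec()].
#' @param n_events Number of transposition events.
#' @param p_local Probability an event is a local hop. Default 0.85.
#' @param local_window Half-width of the local-hopping window in bp. Default
#'   6e6.
#' @param p_remobilize Probability an inserted transposon later excises,
#'   leaving a footprint. Default 0 (no remobilization); the per-event rate
#'   is not a quantity with an established value, so it is a free parameter.
#' @param seed Integer seed; the event list is reproducible given it.
#' @return Data frame of events with columns `seqname`, `pos` (target TA, in
#'   the pre-event coordinate frame), `kind` (`insertion` or
#'   `excision_footprint`), `footprint_variant` (NA for insertions), `origin`
#'   (`concatemer`), `is_local`.
#' @export
simulate_transposition <- function(genome, concatemer, n_events,
                                   p_local = 0.85, local_window = 6e6,
                                   p_remobilize = 0, seed = NULL) {
  stopifnot(p_local >= 0, p_local <= 1, local_window > 0,
            p_remobilize >= 0, p_remobilize <= 1, n_events >= 1)
  genome <- as_ref_genome(genome)
  idx <- build_ta_index(genome)
  sites <- ta_sites(idx)
  is_local_site <- sites$seqname == concatemer$seqname &
    abs(sites$pos - concatemer$position) <= local_window
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  local_draw <- runif(n_events) < p_local
  if (any(local_draw) && !any(is_local_site)) {
    stop("no TA sites available in the local-hopping window")
  }
  if (any(!local_draw) && !any(!is_local_site)) {
    stop("no TA sites available outside the local-hopping window")
  }
  pick <- integer(n_events)
  local_pool <- which(is_local_site)
  distal_pool <- which(!is_local_site)
  n_loc <- sum(local_draw)
  if (n_loc > 0) {
    pick[local_draw] <- local_pool[sample.int(length(local_pool), n_loc,
                                              replace = TRUE)]
  }
  if (n_loc < n_events) {
    pick[!local_draw] <- distal_pool[sample.int(length(distal_pool),
                                                n_events - n_loc,
                                                replace = TRUE)]
  }
  remob <- runif(n_events) < p_remobilize
  variant <- rep(NA_character_, n_events)
  variant[remob] <- sample(FOOTPRINT_VARIANTS, sum(remob), replace = TRUE)
  data.frame(
    seqname = sites$seqname[pick],
    pos = sites$pos[pick],
    kind = ifelse(remob, "excision_footprint", "insertion"),
    footprint_variant = variant,
    origin = "concatemer",
    is_local = local_draw,
    stringsAsFactors = FALSE
  )
}

#' Apply transposition events to a genome
#'
#' Mutates the genome sequences: insertions integrate `transposon` at the
#' target TA; excision-footprint events integrate and immediately excise,
#' i.e. replace the TA with the footprint 7-mer (+5 bp net). Events are
#' applied per sequence in descending coordinate order so that every target,
#' drawn in the pre-event frame, remains a TA when its turn comes.
#'
#' @param genome A `ref_genome`.
#' @param events Event data frame from [simulate_transposition()]. Duplicate
#'   targets are dropped (one event per TA).
#' @param transposon Transposon sequence for surviving insertions.
#' @return A `ref_genome` with the mutations applied.
#' @export
apply_events <- function(genome, events, transposon) {
  genome <- as_ref_genome(genome)
  events <- events[!duplicated(events[, c("seqname", "pos")]), , drop = FALSE]
  seqs <- unclass(genome)
  for (nm in unique(events$seqname)) {
    ev <- events[events$seqname == nm, , drop = FALSE]
    ev <- ev[order(-ev$pos), , drop = FALSE]
    s <- seqs[[nm]]
    for (i in seq_len(nrow(ev))) {
      if (ev$kind[i] == "insertion") {
        s <- apply_insertion(s, ev$pos[i], transposon)
      } else {
        s <- apply_insertion(s, ev$pos[i], transposon)
        s <- apply_excision(s, ev$pos[i], transposon, ev$footprint_variant[i])
      }
    }
    seqs[[nm]] <- s
  }
  ref_genome(seqs)
}

#' Spike-in standards at tiered copy numbers
#'
#' Engineered LM-PCR templates mixed into tumor DNA at 1.0, 0.5 or 0.125
#' copies per genome to mimic mutations present in 100%, 50% or 12.5% of
#' tumor cells. Each standard is a physically linked pair of templates (left
#' and right ITR junction at two genomic loci) sharing one tier.
#'
#' @param ta_index A `ta_index` providing candidate loci.
#' @param n_standards Number of standards (pairs); default 9, split evenly
#'   across the three tiers.
#' @param tiers Copy-per-genome tiers. Default `c(1, 0.5, 0.125)`.
#' @param seed Integer seed.
#' @return Data frame with one row per template: `standard_id`, `side`
#'   (left/right), `seqname`, `pos`, `strand`, `tier`.
#' @export
spikein_standards <- function(ta_index, n_standards = 9L,
                              tiers = c(1, 0.5, 0.125), seed = NULL) {
  stopifnot(n_standards >= length(tiers))
  sites <- ta_sites(ta_index)
  if (nrow(sites) < 2L * n_standards) stop("not enough TA sites for standards")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  pick <- sample.int(nrow(sites), 2L * n_standards)
  tier <- rep_len(tiers, n_standards)
  data.frame(
    standard_id = rep(sprintf("std%02d", seq_len(n_standards)), each = 2L),
    side = rep(c("left", "right"), n_standards),
    seqname = sites$seqname[pick],
    pos = sites$pos[pick],
    strand = rep(c("+", "-"), n_standards),
    tier = rep(tier, each = 2L),
    stringsAsFactors = FALSE
  )
}

#' Simulate a clonal tumor's insertion-site population
#'
#' Builds the true site table of a heterogeneous tumor: clonally expanded
#' insertions at tiered clonality (the dominant clone defines clonality 1),
#' a background of low-abundance sites from ongoing transposition, and
#' optional spike-in standards.
#'
#' Default conditions mirror a high-copy SB screen calibrated with plasmid
#' standards: clonal tiers at 100%/50%/12.5% of tumor cells, and a few
#' hundred background sites whose per-site abundance is orders of magnitude
#' below the dominant clone, so that at typical depth they drop in and out of
#' individual replicate libraries.
#'
#' @param ta_index A `ta_index`.
#' @param tiers Clonality tiers of expanded clones. Default `c(1, 0.5,
#'   0.125)`.
#' @param sites_per_tier Clonal insertion sites per tier. Default 4.
#' @param n_background Background site count. Default 300.
#' @param background_range Clonality range for background sites (log-uniform
#'   draw). Default `c(5e-5, 5e-4)`.
#' @param standards Optional data frame from [spikein_standards()]; its
#'   templates are added as sites of class `standard` with clonality equal to
#'   their tier.
#' @param sample_id Sample label. Default `"tumor1"`.
#' @param seed Integer seed.
#' @return An object of class `tumor_sim`: list with `sites` (data frame:
#'   `site_id`, `seqname`, `pos`, `strand`, `clonality`, `class`,
#'   `standard_id`), `sample_id` and `seed`.
#' @export
simulate_tumor <- function(ta_index, tiers = c(1, 0.5, 0.125),
                           sites_per_tier = 4L, n_background = 300L,
                           background_range = c(5e-5, 5e-4),
                           standards = NULL, sample_id = "tumor1",
                           seed = NULL) {
  stopifnot(max(tiers) == 1, all(tiers > 0), sites_per_tier >= 1)
  sites <- ta_sites(ta_index)
  n_clonal <- length(tiers) * sites_per_tier
  need <- n_clonal + n_background
  if (nrow(sites) < need) stop("not enough TA sites in the index")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  taken <- if (!is.null(standards)) {
    paste(standards$seqname, standards$pos)
  } else character(0)
  avail <- which(!(paste(sites$seqname, sites$pos) %in% taken))
  pick <- sample(avail, need)
  strand <- sample(c("+", "-"), need, replace = TRUE)
  clon <- c(rep(tiers, each = sites_per_tier),
            exp(runif(n_background, log(background_range[1]),
                      log(background_range[2]))))
  cls <- c(rep("clonal", n_clonal), rep("background", n_background))
  tab <- data.frame(
    site_id = sprintf("site%04d", seq_len(need)),
    seqname = sites$seqname[pick],
    pos = sites$pos[pick],
    strand = strand,
    clonality = clon,
    class = cls,
    standard_id = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(standards)) {
    tab <- rbind(tab, data.frame(
      site_id = paste0(standards$standard_id, "_", standards$side),
      seqname = standards$seqname,
      pos = standards$pos,
      strand = standards$strand,
      clonality = standards$tier,
      class = "standard",
      standard_id = standards$standard_id,
      stringsAsFactors = FALSE
    ))
  }
  structure(list(sites = tab, sample_id = sample_id, seed = seed),
            class = "tumor_sim")
}

#' @export
print.tumor_sim <- function(x, ...) {
  cat("tumor_sim '", x$sample_id, "': ", nrow(x$sites), " sites (",
      paste(sprintf("%s=%d", names(table(x$sites$class)),
                    as.integer(table(x$sites$class))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Simulate replicate LM-PCR read-count profiles
#'
#' Each replicate library draws a read count per site with mean
#' `depth * clonality` — Poisson when `dispersion = 0`, negative binomial
#' (size `1/dispersion`) otherwise. Ligation points are modeled as the number
#' of distinct shear positions among the site's fragments, drawn uniformly
#' over `fragment_span` possible shear offsets and therefore capped both by
#' the read count and by `fragment_span`. Sites drawing zero reads are absent
#' from that replicate's profile, reproducing the drop-in/drop-out of
#' low-abundance sites across replicates.
#'
#' @param tumor A [simulate_tumor()] object.
#' @param n_replicates Number of replicate libraries. Default 3.
#' @param depth Expected read count of a clonality-1 site. Default 10000.
#' @param dispersion Negative-binomial dispersion; 0 gives pure Poisson.
#' @param fragment_span Number of distinct shear offsets available per site.
#'   Default 300 (the average sheared-fragment size in bp).
#' @param seed Integer seed.
#' @return Named list of data frames (one per replicate) with columns
#'   `site_id`, `seqname`, `pos`, `strand`, `reads`, `ligation_points`,
#'   `class`, `standard_id`, plus attributes `sample_id`, `replicate` and
#'   `total_reads`.
#' @export
simulate_replicates <- function(tumor, n_replicates = 3L, depth = 10000,
                                dispersion = 0, fragment_span = 300L,
                                seed = NULL) {
  stopifnot(inherits(tumor, "tumor_sim"), n_replicates >= 1L, depth > 0,
            dispersion >= 0)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  sites <- tumor$sites
  mu <- depth * sites$clonality
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    reads <- if (dispersion == 0) {
      rpois(nrow(sites), mu)
    } else {
      rnbinom(nrow(sites), size = 1 / dispersion, mu = mu)
    }
    lig <- vapply(reads, function(n) {
      if (n == 0L) 0L
      else length(unique(sample.int(fragment_span, n, replace = TRUE)))
    }, integer(1))
    prof <- cbind(sites[, c("site_id", "seqname", "pos", "strand")],
                  reads = reads, ligation_points = lig,
                  sites[, c("clonality", "class", "standard_id")])
    prof <- prof[prof$reads > 0L, , drop = FALSE]
    rownames(prof) <- NULL
    attr(prof, "sample_id") <- tumor$sample_id
    attr(prof, "replicate") <- r
    attr(prof, "total_reads") <- sum(prof$reads)
    out[[r]] <- prof
  }
  names(out) <- paste0("rep", seq_len(n_replicates))
  out
}

#' Simulate a footprint-library sequencing experiment
#'
#' Emulates the HpyCH4III-based footprint enrichment protocol: each tumor's
#' site table contains strand-resolved read counts at (i) its true excision
#' footprints, (ii) every endogenous TACWGTA locus of the reference (shared
#' with the matched normal sample), (iii) the ITR/genome junctions of its
#' surviving clonal insertions, and (iv) optional low-depth noise sites. The
#' normal sample contains exactly the endogenous loci. A truth table labels
#' every locus for downstream evaluation.
#'
#' @param genome A `ref_genome` (pre-event reference; all coordinates are in
#'   this frame).
#' @param tumors Named list, one element per tumor, each a list with numeric
#'   data frames `footprints` and `insertions` (columns `seqname`, `pos`).
#' @param depth Expected reads per strand at a fully clonal locus. Default
#'   1000.
#' @param noise_sites Number of spurious low-depth sites per tumor. Default 0.
#' @param noise_depth Expected reads per strand at a noise site. Default 0.7
#'   (so many noise sites lack one strand and are caught by the dual-strand
#'   rule; survivors have low total depth).
#' @param footprint_clonality Optional numeric vector/list parallel to each
#'   tumor's footprints giving per-footprint clonality in (0, 1]; default all
#'   1.
#' @param seed Integer seed.
#' @return List with `tumor_tables` (named list of site tables: `seqname`,
#'   `pos`, `strand`, `reads`), `normal_table`, `clonal_sites` (named list of
#'   data frames of each tumor's clonal insertion sites) and `truth` (data
#'   frame `sample`, `seqname`, `pos`, `truth_class` in
#'   footprint/endogenous/junction/noise).
#' @export
simulate_footprint_library <- function(genome, tumors, depth = 1000,
                                       noise_sites = 0L, noise_depth = 0.7,
                                       footprint_clonality = NULL,
                                       seed = NULL) {
  genome <- as_ref_genome(genome)
  if (is.null(names(tumors)) || any(!nzchar(names(tumors)))) {
    stop("tumors must be a named list")
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(seed)
  }
  endo <- scan_motif(genome, "TACWGTA", both_strands = FALSE)
  endo_sites <- unique(data.frame(seqname = endo$seqname, start = endo$start,
                                  stringsAsFactors = FALSE))
  ta_all <- ta_sites(build_ta_index(genome))
  draw_counts <- function(loci, mu) {
    # strand-resolved Poisson reads at each locus; zero-read strands dropped
    if (nrow(loci) == 0L) {
      return(data.frame(seqname = character(), pos = integer(),
                        strand = character(), reads = integer(),
                        stringsAsFactors = FALSE))
    }
    mu <- rep_len(mu, nrow(loci))
    out <- data.frame(
      seqname = rep(loci$seqname, 2L),
      pos = rep(loci$pos, 2L),
      strand = rep(c("+", "-"), each = nrow(loci)),
      reads = rpois(2L * nrow(loci), rep(mu, 2L)),
      stringsAsFactors = FALSE
    )
    out[out$reads > 0L, , drop = FALSE]
  }
  endo_loci <- data.frame(seqname = endo_sites$seqname, pos = endo_sites$start,
                          stringsAsFactors = FALSE)
  # noise loci are drawn from TAs not occupied by any labeled class, so every
  # locus in the truth table carries exactly one label
  used <- c(paste(endo_loci$seqname, endo_loci$pos),
            unlist(lapply(tumors, function(tu) {
              c(paste(tu$footprints$seqname, tu$footprints$pos),
                paste(tu$insertions$seqname, tu$insertions$pos))
            })))
  ta_pool <- ta_all[!(paste(ta_all$seqname, ta_all$pos) %in% used), ,
                    drop = FALSE]
  normal_table <- draw_counts(endo_loci, depth)
  tumor_tables <- list()
  clonal_sites <- list()
  truth <- list()
  for (nm in names(tumors)) {
    tu <- tumors[[nm]]
    fp <- tu$footprints
    ins <- tu$insertions
    fp_clon <- if (is.null(footprint_clonality)) 1 else
      rep_len(unlist(footprint_clonality[[nm]]), nrow(fp))
    noise <- if (noise_sites > 0L) {
      pick <- sample.int(nrow(ta_pool), noise_sites)
      data.frame(seqname = ta_pool$seqname[pick], pos = ta_pool$pos[pick],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(seqname = character(), pos = integer(),
                 stringsAsFactors = FALSE)
    }
    tab <- rbind(
      draw_counts(fp, depth * fp_clon),
      draw_counts(endo_loci, depth),
      draw_counts(ins, depth),
      draw_counts(noise, noise_depth)
    )
    tab <- tab[order(tab$seqname, tab$pos, tab$strand), , drop = FALSE]
    rownames(tab) <- NULL
    tumor_tables[[nm]] <- tab
    clonal_sites[[nm]] <- ins
    truth[[nm]] <- data.frame(
      sample = nm,
      seqname = c(fp$seqname, endo_loci$seqname, ins$seqname, noise$seqname),
      pos = c(fp$pos, endo_loci$pos, ins$pos, noise$pos),
      truth_class = c(rep("footprint", nrow(fp)),
                      rep("endogenous", nrow(endo_loci)),
                      rep("junction", nrow(ins)),
                      rep("noise", nrow(noise))),
      stringsAsFactors = FALSE
    )
  }
  list(
    tumor_tables = tumor_tables,
    normal_table = normal_table,
    clonal_sites = clonal_sites,
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE)))
  )
}
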