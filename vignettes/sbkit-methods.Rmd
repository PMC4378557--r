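---
title: "sbkit: models and methods for Sleeping Beauty screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sbkit: models and methods for Sleeping Beauty screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbkit)
```

# Background

*Sleeping Beauty* (SB) is a Tc1/mariner DNA transposon mobilized by SB
transposase. Two mechanistic facts anchor everything in this package:

1. **Integration is TA-restricted and duplicates the target.** An insertion
   at a TA dinucleotide produces `...TA-[transposon]-TA...`, so the set of
   potential insertion sites is exactly the set of TA dinucleotides, and a
   genome's TA landscape (indexed by `build_ta_index()`) is the natural null
   model for integration.
2. **Excision leaves a footprint.** Cut-and-paste remobilization removes the
   transposon but leaves three ITR-derived bases between the duplicated TAs:
   the donor locus gains exactly 5 bp and afterwards reads `TACAGTA` or
   `TACTGTA` (consensus `TACWGTA`). A footprint inside a coding exon is a
   frameshift — a mutation class invisible to junction sequencing.

Screens read out insertions by ligation-mediated PCR (LM-PCR) of
transposon/genome junctions; footprint libraries instead enrich for the
footprint 7-mer via the HpyCH4III restriction site (`ACNGT`) it contains.

# Genome model and motif scanning

Sequences are uppercase `A/C/G/T/N` strings; coordinates are **1-based
inclusive** throughout the package, matching the R/Bioconductor ecosystem
(IRanges, Biostrings, GenomicRanges) it builds on. BED input/output converts
to 0-based half-open at the file boundary only, and window report labels
(`chr11:3,180,001-3,200,000`) are rendered from the same internal frame.

`scan_motif()` supports the IUPAC codes the footprint and restriction motifs
need (`N` = any base, `W` = A/T). Two conventions are deliberate:

* an `N` in the genome (assembly gap) matches nothing, not even pattern `N`
  — conservative handling of gaps;
* overlapping matches are all reported, and a palindromic motif such as
  `TACWGTA` yields one hit per strand at the same coordinates; callers that
  want strandless loci deduplicate on position.

Site classification applies exon > intron > intergenic precedence on
overlap, reflecting the mutational-consequence emphasis on coding sequence;
a position inside a gene with no overlapping exon is intronic.
`ta_composition()` tallies the TA index through the same classifier, and is
the recommended source of the expected exonic fraction `p0` for the
enrichment test below — genome-composition percentages depend on the
annotation build and should not be hard-coded.

# The transposition simulator

The simulator is first-class, tested code: it generates every input the
analysis modules consume, with a labeled truth table where evaluation needs
one. Stochastic steps take an explicit seed and are exactly reproducible.

**Events.** `simulate_transposition()` draws each target TA either from the
local-hopping stratum (same chromosome, within `local_window` of the donor
concatemer) with probability `p_local`, or uniformly from all remaining TAs.
Defaults `local_window = 6e6` and `p_local = 0.85` follow the observed
geometry of SB local hopping — the large majority of local re-integration
falls within ~6 Mb of the donor site and local chromosomes dominate
enriched-window lists in unselected screens. The per-event remobilization
probability has no established value, so `p_remobilize` defaults to 0 and is
a free parameter. Footprint variants are chosen uniformly between the two
consensus forms, which are mechanistically symmetric.

**Tumors and replicates.** `simulate_tumor()` builds a heterogeneous tumor:
clonal tiers at 1 / 0.5 / 0.125 relative clonality (the tiers the spike-in
standards mimic: mutations in 100%, 50% and 12.5% of cells), four sites per
tier, and 300 background sites with clonality log-uniform in
[5e-5, 5e-4] — orders of magnitude below the dominant clone, so that at the
default depth of 10,000 expected reads per clonality-1 site they drop in and
out of individual libraries, which is precisely the behavior the replicate
FDR measures. `simulate_replicates()` draws read counts Poisson
(negative-binomial when `dispersion > 0`) with mean `depth * clonality`, and
models ligation points as the number of distinct shear positions among a
site's fragments (uniform over `fragment_span = 300` offsets, the average
sheared-fragment size), hence capped by both the read count and the span —
which is why ligation points saturate for abundant sites and separate tiers
poorly.

**Footprint libraries.** `simulate_footprint_library()` emits
strand-resolved Poisson read counts at true footprints, at every endogenous
`TACWGTA` locus (shared with the matched normal), at ITR/genome junctions of
surviving clonal insertions, and at optional low-depth noise loci
(`noise_depth = 0.7` per strand, so many noise sites lack one strand and the
rest survive only as low-depth candidates). Noise loci are drawn from TAs
not occupied by any labeled class so the truth table is single-labeled.

**What the simulator does not emulate:** base-level reads with quality
scores, PCR-cycle-explicit amplification bias (shearing-based LM-PCR was
designed to remove size bias, and paired spike-in templates showed no
significant depth difference), chromatin or expression effects on target
choice, and real repeat families. Tests passing on simulated data therefore
validate the statistical machinery, not robustness to those artifacts.

# Footprint calling

`call_candidates()` applies four filters in order: (1) normal-sample
subtraction (endogenous motif loci), (2) removal of the sample's clonal
insertion junctions (each contains an HpyCH4III site), (3) cross-tumor
redundancy removal — a site seen in more than one tumor is dropped from
*all* of them, since true footprints should be private to a sample — and
(4) the dual-strand rule, which guarantees an intact 7-mer across the locus.
Steps 1–3 are set subtractions computed from the original inputs, so their
order is immaterial (a property the test suite asserts by permutation); the
dual-strand rule is applied last, though commuting it earlier would not
change the result either, as it is a per-site predicate.

**Confidence tiers.** The method compares candidate depth to the depths of
simultaneously sequenced, previously known clonal insertion loci. The
comparison is the method; the exact cutoff is not pinned down by it, so
sbkit uses a percentile threshold — high confidence iff
`depth >= quantile(clonal_depths, q/100)` with linear interpolation
(`type = 7`) and default `q = 25` — exposed as configuration.

**True-footprint estimation.** `estimate_true_footprints()` computes
`ceiling(n_high * r_high + n_low * r_low)` from per-tier candidate counts
and validation rates. Rounding up (rather than to nearest) means a tumor
with any surviving fractional expectation is credited with the extra
footprint — the conservative direction for a burden estimate. On the
canonical worked example — tiered counts (149, 69), (2, 95), (133, 104)
with pooled rates 12/12 and 1/18 — the estimator yields 153, 8 and 139, the
values the test suite and acceptance script reproduce. It is monotone in
every argument.

**Exon enrichment.** `exon_enrichment_test()` uses the one-sample proportion
z-test `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)`; a two-proportion test
against a genome-wide TA reference of effectively infinite size reduces to
this form, which is why the one-sample form is the natural choice when `p0`
comes from exhaustively classifying every TA in the annotation. With
`k = 13`, `n = 552`, `p0 = 0.015` it gives p ≈ 0.098. Two-proportion
variants against a finite reference, with or without continuity correction,
give somewhat different p-values for the same counts; the formula used here
is stated exactly so results are reproducible. A warning is issued when
`n p0 < 5`, where the normal approximation is poor.

# Clonality stratification and replicate FDR

`normalize_to_max()` maps counts to percent-of-maximum (top site = 100%).
When a profile declares site classes (spike-in standards vs genomic sites),
normalization is per class, matching how standards are scored against the
most abundant standard; set `by_class = FALSE` for global normalization.

Default abundance bins are `(0,1], (1,5], (5,12.5], (12.5,50], (50,100]`:
only the 5% boundary is anchored by the method (sites at ≥ 5% of maximum
are reproducibly detected), the others follow the spike-in tiers; all are
configurable. Bins are half-open `(lo, hi]`, so a site exactly at 5% falls
in the lower bin.

`estimate_fdr()` implements the leave-one-out rotation: each replicate in
turn is the test set; sites present (count ≥ 1 — raw detection, no
normalized floor) in *both* remaining replicates form the true-positive set;
test-set sites outside it are false positives. Per-bin FDRs are averaged
over rotations (the per-rotation vs averaged choice is not dictated by the
method; averaging uses all three rotations symmetrically), and a bin
unoccupied in a rotation simply does not contribute to that bin's mean.

# The detection-bias scan (PRIM)

Windows are a non-overlapping `width = 20000` bp tiling of each sequence
(final partial window retained). Observed counts are **distinct insertion
sites**, not reads: sites are deduplicated to one per (sample, TA) —
collapsing the two ITR orientations — and then pooled across samples, so a
site recurring in several samples contributes once per sample.

The Poisson Regression Insertion Model is the log-linear GLM

```
log E[count_w] = b0 + b1 * log(ta_count_w) + chromosome_w
```

fitted by `stats::glm(family = poisson())`. Under unbiased integration
`b1 = 1` and chromosome effects are log rate ratios; the GLM score equations
guarantee fitted means sum to the observed total. Windows with zero TAs
cannot receive an insertion: they are reported with `p_raw = 1` and excluded
from both the fit and the Bonferroni family. With a single chromosome the
factor is dropped.

Note that `b1` is only well identified when TA density actually varies
across windows; on a homogeneous random sequence the covariate is nearly
constant and its coefficient has a large standard error. The test suite
therefore evaluates parameter recovery on GC-heterogeneous (isochore-like)
simulated genomes, at ~50,000 sites over 160 windows.

Each tested window's p-value is the exact Poisson upper tail
`P(X >= observed | expected)` at the PRIM-fitted mean — reproducible and
conservative at small means, where a regression-based asymptotic test would
be anti-conservative. Bonferroni correction multiplies by the number of
tested windows; the family-wise level `alpha` defaults to 0.05 and the
report always carries both raw and corrected values, since genome-scale
window lists are conventionally quoted by corrected thresholds (e.g.
p < 1e-7) whose implicit family size varies with the analysis.

`flag_windows()` marks donor chromosomes, ± 6 Mb local-hopping windows, and
repeat-track overlap (half-open interval intersection; one shared base pair
counts). The non-local report excludes donor chromosomes entirely.

# Mappability correction

For each TA and strand, `generate_mock_reads()` emits the genomic sequence
starting at the TA (reverse-complemented on the minus strand) at lengths
10–65 bp in 5-bp steps — screen reads begin at the ITR/genome junction
adjacent to the TA, so the anchor is the TA itself. Reads running past a
sequence end are skipped and the affected lengths simply untested.

The built-in aligner (`align_reads()`) enumerates all hits with at most two
substitutions on both strands (Biostrings pattern matching under the hood,
verified against a brute-force Hamming oracle in the tests) and scores
match +1 / mismatch −1, so a perfect L-mer scores L. At assembly scale an
external aligner can substitute, provided it emits the same per-read hit
table (position, strand, mismatches, score); scores from external tools live
on their own scale and the `score_min` threshold should be chosen for that
scale.

A length qualifies for a (TA, strand) when the originating-locus hit scores
strictly above `score_min = 10` **and** no other locus is hit with fewer
than `alt_mismatch_limit = 2` mismatches — i.e. uniqueness demands every
alternative carry at least two mismatches. The second clause is a
deliberately resolved ambiguity: "without mapping to any other genomic site
having two or more mismatches" can be parsed both ways, and the chosen
reading is the one under which a near-perfect alternative makes a read
ambiguous; both the limit and its direction are exposed as arguments.
Because a perfect 10-mer scores exactly 10, the smallest attainable minimum
on the default grid is 15. Qualification is *not* assumed monotone in
length: the record is the smallest qualifying tested length (scanning
ascending and stopping at the first success computes exactly that), and
`NA` marks unmappable sites. `filter_reads()` then discards experimental
reads shorter than their site's minimum, at unmappable sites, or at sites
without a record, and logs counts per reason.

The end-to-end effect is the package's headline correction: on a simulated
genome containing a multi-copy duplicated segment whose reads collapse onto
one copy, the bias scan reports a strongly enriched window; after
mappability filtering the enrichment disappears, and filtering never
increases the enriched-window count on repeat-free simulations.

# Numerical and design notes

* Percentile thresholds use `stats::quantile` type 7 (linear
  interpolation), R's default.
* Summary percentages in candidate reports are rounded to one decimal;
  all statistics are computed on unrounded values.
* `estimate_fdr` requires ≥ 2 replicates; the canonical design is 3.
* Degenerate inputs error early with informative messages: empty genomes,
  all-zero profiles, empty clonal-depth references, zero tested validation
  candidates, designs with no insertions.
* Problem sizes in the test suite — toy genomes of 50 kb–3.2 Mb, 20-run
  batteries for type-I/hotspot properties, ~50,000 sites for PRIM recovery —
  were chosen as the smallest scales at which the statistical properties
  under test are stable.

# Known limitations

* The genome container is an in-memory string set; assembly-scale indexing
  and alignment are out of scope (the external-aligner contract is the
  escape hatch).
* Clonality output is semi-quantitative by construction: sites are
  stratified into abundance groups, not assigned absolute copy numbers, and
  within-group ordering is not meaningful.
* The replicate FDR measures detection reproducibility, not biological
  truth: a reproducible artifact (e.g. a mapping error present in all
  replicates) is invisible to it — which is exactly why the bias scan and
  mappability correction exist.
* Annotation handling is a minimal BED-like interval model; full gene-model
  (GFF3) semantics are not implemented.
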