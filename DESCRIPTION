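Package: sbkit
Title: Analysis Toolkit for Sleeping Beauty Insertional Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Methods for interpreting high-throughput sequencing data from
    Sleeping Beauty (SB) transposon mutagenesis screens. Implements detection
    of transposon excision footprints (the 5-bp TACWGTA scar left at a donor
    TA dinucleotide after remobilization) from ligation-mediated PCR footprint
    libraries, with validation-scaled estimation of true footprint burden and
    an exon-enrichment test; semi-quantitative stratification of insertion
    sites by normalized read abundance with a replicate-based false discovery
    rate; a Poisson regression insertion model (PRIM) scan for genomic windows
    with biased insertion-site detection; and per-TA-site mappability
    correction based on the minimum read length needed for accurate, unique
    alignment. A forward transposition simulator generates toy genomes,
    clonal tumors with tiered site abundances, spike-in standards, and
    footprint libraries for testing and method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
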