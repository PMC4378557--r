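test_that("mock reads are anchored at the TA on both strands", {
  g <- ref_genome(c(chr = paste0(strrep("G", 100), "TA", strrep("C", 100))))
  reads <- generate_mock_reads(g, data.frame(seqname = "chr", pos = 101L))
  expect_equal(nrow(reads), 24L)  # 12 lengths x 2 strands, no truncation
  expect_true(all(substr(reads$read[reads$strand == "+"], 1, 2) == "TA"))
  expect_true(all(substr(reads$read[reads$strand == "-"], 1, 2) == "TA"))
  expect_equal(reads$read[reads$strand == "+" & reads$length == 10],
               "TACCCCCCCC")
  expect_equal(reads$read[reads$strand == "-" & reads$length == 10],
               "TACCCCCCCC")  # G-run upstream reverse-complements to Cs

  # a TA close to the sequence end loses the lengths that would run off
  edge <- ref_genome(c(chr = paste0(strrep("G", 100), "TAGGG")))
  r <- generate_mock_reads(edge, data.frame(seqname = "chr", pos = 101L))
  expect_equal(sum(r$strand == "+"), 0L)   # only 5 bp remain downstream
  expect_equal(sum(r$strand == "-"), 12L)  # upstream room for every length
})

test_that("built-in aligner equals the brute-force Hamming oracle", {
  g <- random_genome(c(chrA = 3000L, chrB = 1500L), seed = 91)
  set.seed(92)
  reads <- character(0)
  for (i in 1:8) {
    nm <- sample(names(g), 1)
    L <- sample(c(15L, 20L, 30L), 1)
    s <- sample(nchar(g[[nm]]) - L, 1)
    r <- substr(g[[nm]], s, s + L - 1L)
    # mutate up to two bases
    for (j in seq_len(sample(0:2, 1))) {
      k <- sample(L, 1)
      substr(r, k, k) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(r, k, k)), 1)
    }
    if (sample(c(TRUE, FALSE), 1)) r <- revcomp(r)
    reads <- c(reads, r)
  }
  got <- align_reads(reads, g, max_reported_hits = 10000L)
  for (qi in seq_along(reads)) {
    h <- got[got$query == as.character(qi),
             c("seqname", "start", "strand", "mismatches", "score")]
    h <- h[order(h$seqname, h$start, h$strand), ]
    want <- naive_align(reads[qi], unclass(g))
    expect_equal(unname(as.matrix(h)), unname(as.matrix(want)))
  }

  # a read from a duplicated block yields two perfect hits
  dup <- ref_genome(c(chr = paste0(strrep("A", 20), "GATTACAGATTACAGGCCGG",
                                   strrep("C", 20), "GATTACAGATTACAGGCCGG")))
  hits <- align_reads("GATTACAGATTACAGGCCGG", dup)
  perfect <- hits[hits$mismatches == 0 & hits$strand == "+", ]
  expect_equal(nrow(perfect), 2L)
  expect_equal(perfect$score, c(20L, 20L))

  # longer read than any sequence: no hits
  expect_equal(nrow(align_reads(strrep("A", 5000), g)), 0L)
})

test_that("minimum unique length reflects scoring and ambiguity rules", {
  g <- random_genome(c(chr = 4000L), seed = 93)
  idx <- build_ta_index(g)
  rec <- min_unique_length(g, ta_sites(idx)[5:8, ])
  # perfect 10-mers score exactly 10 and fail 'score > 10'; unique sequence
  # qualifies at the next tested length
  expect_true(all(rec$min_len == 15L))

  # a TA inside a 90-bp exact duplication: every tested read length from it
  # fits inside the repeated block, so a perfect alternative always exists
  block <- paste0("GGCCGGCC", "TA",
                  substr(random_genome(c(x = 200), seed = 95)[["x"]], 1, 80))
  dup <- ref_genome(c(chr = paste0(strrep("G", 40), block, strrep("C", 40),
                                   block, strrep("G", 40))))
  rec <- min_unique_length(dup, data.frame(seqname = "chr", pos = 49L),
                           strands = "+")  # TA at offset 9 of the first copy
  expect_true(is.na(rec$min_len))

  # copies diverging only beyond the short read window become resolvable once
  # the window covers >= 2 mismatches
  u <- "TACCGGTTAACCGGATCCGGTTAACCGGAT"
  v <- u
  substr(v, 18, 18) <- "A"; substr(v, 25, 25) <- "G"
  div <- ref_genome(c(chr = paste0(strrep("G", 30), u, strrep("C", 30), v,
                                   strrep("G", 30))))
  rec <- min_unique_length(div, data.frame(seqname = "chr", pos = 31L),
                           strands = "+")
  # L = 15/20 still see an alternative with < 2 mismatches; L = 25 covers both
  expect_equal(rec$min_len, 25L)
})

test_that("mappability is invariant under genome reverse complement", {
  g <- random_genome(c(chr = 1500L), seed = 94)
  idx <- build_ta_index(g)
  pick <- ta_sites(idx)[c(3, 9, 15), ]
  fwd <- min_unique_length(g, pick)
  n <- nchar(g[["chr"]])
  rc <- ref_genome(c(chr = revcomp(g[["chr"]])))
  # the T of a TA at pos p maps to position n - p on the reverse complement,
  # and plus/minus strands swap
  mirrored <- data.frame(seqname = "chr", pos = n - pick$pos)
  rev <- min_unique_length(rc, mirrored)
  key_fwd <- paste(fwd$ta_pos, fwd$strand)
  rev$orig_pos <- n - rev$ta_pos
  rev$orig_strand <- ifelse(rev$strand == "+", "-", "+")
  key_rev <- paste(rev$orig_pos, rev$orig_strand)
  expect_equal(fwd$min_len[order(key_fwd)], rev$min_len[order(key_rev)])
})

test_that("read filtering enforces the per-site minimum and logs discards", {
  map <- structure(data.frame(
    seqname = "chr", ta_pos = c(100L, 200L, 300L), strand = "+",
    min_len = c(25L, NA, 15L)), class = c("mappability", "data.frame"))
  reads <- data.frame(seqname = "chr", pos = c(100, 100, 200, 300, 999),
                      strand = "+", length = c(30L, 20L, 60L, 15L, 50L))
  out <- filter_reads(reads, map)
  expect_equal(out$retained$pos, c(100, 300))
  expect_equal(sort(out$discarded$reason),
               sort(c("too_short", "unmappable", "no_record")))
  expect_equal(unname(out$summary["retained"]) + nrow(out$discarded),
               nrow(reads))
})
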