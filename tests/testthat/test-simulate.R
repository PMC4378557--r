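test_that("integration duplicates the TA target and excision leaves +5 bp", {
  s <- apply_insertion("AATAGC", 3, "GGGG")
  expect_equal(s, "AATAGGGGTAGC")
  expect_equal(nchar(s) - nchar("AATAGC"), 4L + 2L)
  expect_error(apply_insertion("AATAGC", 2, "GGGG"), "not a TA")

  expect_equal(apply_excision(s, 3, "GGGG", "TACAGTA"), "AATACAGTAGC")
  expect_equal(apply_excision(s, 3, "GGGG", "TACTGTA"), "AATACTGTAGC")
  expect_error(apply_excision("AATAGC", 3, "GGGG", "TACAGTA"),
               "no integrated transposon")
})

test_that("insertion/excision round trip differs only by the 5-bp footprint", {
  g <- random_genome(c(chr = 2000L), seed = 3)
  s0 <- g[["chr"]]
  tn <- "GGTTACCGGTT"
  for (pos in sample(build_ta_index(g)$positions$chr, 10)) {
    for (v in c("TACAGTA", "TACTGTA")) {
      s1 <- apply_excision(apply_insertion(s0, pos, tn), pos, tn, v)
      expect_equal(nchar(s1), nchar(s0) + 5L)
      expect_equal(substr(s1, 1, pos - 1), substr(s0, 1, pos - 1))
      expect_equal(substr(s1, pos, pos + 6), v)
      expect_equal(substr(s1, pos + 7, nchar(s1)),
                   substr(s0, pos + 2, nchar(s0)))
    }
  }
})

test_that("transposition targeting respects the local-hopping stratification", {
  g <- random_genome(c(chr1 = 20000L, chr2 = 20000L), seed = 7)
  cc <- concatemer_spec("chr1", 10000L)

  ev <- simulate_transposition(g, cc, 500L, p_local = 1, local_window = 3000L,
                               seed = 1)
  expect_true(all(ev$seqname == "chr1"))
  expect_true(all(abs(ev$pos - cc$position) <= 3000L))

  # p_local = 0: no event may fall in the local window
  ev0 <- simulate_transposition(g, cc, 2000L, p_local = 0,
                                local_window = 3000L, seed = 2)
  expect_false(any(ev0$seqname == "chr1" &
                     abs(ev0$pos - cc$position) <= 3000L))

  # all targets are TA positions of the pre-event genome
  idx <- build_ta_index(g)
  ok <- mapply(function(nm, p) p %in% idx$positions[[nm]],
               ev0$seqname, ev0$pos)
  expect_true(all(ok))

  # determinism under a fixed seed
  expect_identical(
    simulate_transposition(g, cc, 100L, seed = 9, local_window = 3000L),
    simulate_transposition(g, cc, 100L, seed = 9, local_window = 3000L))
})

test_that("intermediate p_local recovers the stratum probability", {
  g <- random_genome(c(chr1 = 30000L), seed = 8)
  cc <- concatemer_spec("chr1", 15000L)
  idx <- build_ta_index(g)
  p_local <- 0.4
  n <- 10000L
  ev <- simulate_transposition(g, cc, n, p_local = p_local,
                               local_window = 5000L, seed = 4)
  frac <- mean(abs(ev$pos - cc$position) <= 5000L)
  se <- sqrt(p_local * (1 - p_local) / n)
  expect_lt(abs(frac - p_local), 3 * se + 1e-9)
})

test_that("applied events mutate the genome as specified", {
  g <- random_genome(c(chr = 5000L), seed = 12)
  cc <- concatemer_spec("chr", 2500L)
  ev <- simulate_transposition(g, cc, 5L, p_local = 0.5,
                               local_window = 1000L, p_remobilize = 0.5,
                               seed = 6)
  tn <- "GGCCAATTGGCC"
  mut <- apply_events(g, ev, tn)
  n_ins <- sum(ev$kind == "insertion" & !duplicated(ev$pos))
  n_fp <- sum(ev$kind == "excision_footprint" & !duplicated(ev$pos))
  expect_equal(nchar(mut[["chr"]]) - nchar(g[["chr"]]),
               n_ins * (nchar(tn) + 2L) + n_fp * 5L)
})

test_that("replicate read counts follow clonality with reproducible noise", {
  g <- random_genome(c(chr = 50000L), seed = 21)
  idx <- build_ta_index(g)
  tumor <- simulate_tumor(idx, sites_per_tier = 4L, n_background = 0L,
                          seed = 31)
  # mean normalized abundance over many independent libraries recovers the
  # clonality tiers within 10%
  tier_means <- c()
  for (seed in 1:100) {
    prof <- simulate_replicates(tumor, n_replicates = 1L, depth = 10000,
                                seed = seed)[[1]]
    prof <- normalize_to_max(prof)
    tier_means <- rbind(tier_means,
                        tapply(prof$pct_of_max, prof$clonality, mean))
  }
  avg <- colMeans(tier_means)
  expect_lt(abs(avg[["1"]] - 100) / 100, 0.10)
  expect_lt(abs(avg[["0.5"]] - 50) / 50, 0.10)
  expect_lt(abs(avg[["0.125"]] - 12.5) / 12.5, 0.10)

  # determinism and absence of zero-clonality sites
  r1 <- simulate_replicates(tumor, seed = 99)
  r2 <- simulate_replicates(tumor, seed = 99)
  expect_identical(lapply(r1, as.data.frame), lapply(r2, as.data.frame))

  dead <- structure(list(sites = data.frame(
    site_id = "s1", seqname = "chr", pos = idx$positions$chr[1],
    strand = "+", clonality = 0, class = "background",
    standard_id = NA_character_), sample_id = "t", seed = 1),
    class = "tumor_sim")
  prof <- simulate_replicates(dead, n_replicates = 3L, seed = 1)
  expect_true(all(vapply(prof, nrow, integer(1)) == 0L))

  # ligation points are bounded by reads and the fragment span
  prof <- simulate_replicates(tumor, n_replicates = 1L, depth = 500,
                              fragment_span = 50L, seed = 2)[[1]]
  expect_true(all(prof$ligation_points <= prof$reads))
  expect_true(all(prof$ligation_points <= 50L))
})

test_that("footprint library emits labeled footprint/endogenous/junction loci", {
  # genome with exactly two endogenous consensus motifs
  base <- gsub("TACAGTA|TACTGTA", "GGGGGGG",
               unclass(random_genome(c(chr = 4000L), seed = 41))[["chr"]])
  s <- paste0(base, "TACAGTA", strrep("CG", 25), "TACTGTA", strrep("GC", 25))
  g <- ref_genome(c(chr = s))
  idx <- build_ta_index(g)
  pool <- setdiff(idx$positions$chr,
                  scan_motif(g, "TACWGTA", both_strands = FALSE)$start)
  fp <- data.frame(seqname = "chr", pos = pool[5])
  ins <- data.frame(seqname = "chr", pos = pool[10])
  lib <- simulate_footprint_library(g, list(t1 = list(footprints = fp,
                                                      insertions = ins)),
                                    depth = 1000, seed = 13)
  truth1 <- lib$truth[lib$truth$sample == "t1", ]
  expect_setequal(truth1$truth_class,
                  c("footprint", "endogenous", "junction"))
  expect_equal(sum(truth1$truth_class == "endogenous"), 2L)
  expect_equal(nrow(unique(lib$tumor_tables$t1[, c("seqname", "pos")])), 4L)

  # the normal sample contains exactly the endogenous loci
  expect_setequal(unique(lib$normal_table$pos),
                  truth1$pos[truth1$truth_class == "endogenous"])

  # at high depth every true footprint is covered on both strands
  fp_rows <- lib$tumor_tables$t1[lib$tumor_tables$t1$pos == fp$pos, ]
  expect_setequal(fp_rows$strand, c("+", "-"))
})
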