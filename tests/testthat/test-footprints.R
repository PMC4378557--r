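mk_table <- function(pos, strands = c("+", "-"), reads = 10L,
                     seqname = "chr1") {
  expand.grid(pos = pos, strand = strands, stringsAsFactors = FALSE) |>
    (\(d) data.frame(seqname = seqname, pos = d$pos, strand = d$strand,
                     reads = reads, stringsAsFactors = FALSE))()
}

test_that("candidate calling applies the four filters in sequence", {
  tumor1 <- mk_table(c(10, 20, 30, 40))
  tumor2 <- mk_table(c(30, 99))
  normal <- mk_table(10)
  clonal <- list(t1 = data.frame(seqname = "chr1", pos = 20), t2 = NULL)
  out <- call_candidates(list(t1 = tumor1, t2 = tumor2), normal, clonal)
  # a: in normal; b: clonal; c: shared with t2; d survives
  expect_equal(out$t1$pos, 40)
  expect_equal(out$t2$pos, 99)
  expect_equal(out$t1$plus_reads, 10L)
  expect_equal(out$t1$minus_reads, 10L)

  # dual-strand rule: a site with reads on one strand only is dropped
  oneside <- rbind(mk_table(50), mk_table(60, strands = "+", reads = 5L))
  out <- call_candidates(list(t1 = oneside), normal = mk_table(999))
  expect_equal(out$t1$pos, 50)

  expect_error(call_candidates(list(t1 = tumor1), NULL), "normal")
})

test_that("set-subtraction filters commute", {
  set.seed(77)
  for (i in 1:5) {
    pool <- sample(1000, 60)
    t1 <- mk_table(sample(pool, 25))
    t2 <- mk_table(sample(pool, 25))
    normal <- mk_table(sample(pool, 15))
    clonal <- list(t1 = data.frame(seqname = "chr1",
                                   pos = sample(pool, 10)), t2 = NULL)
    out <- call_candidates(list(t1 = t1, t2 = t2), normal, clonal)
    # oracle: apply the subtractions in a different order (redundancy first)
    k1 <- unique(t1$pos); k2 <- unique(t2$pos)
    keep <- setdiff(setdiff(setdiff(k1, intersect(k1, k2)),
                            clonal$t1$pos), unique(normal$pos))
    expect_setequal(out$t1$pos, keep)
  }
})

test_that("confidence tiers compare depth to a clonal-site percentile", {
  cand <- data.frame(seqname = "chr1", pos = c(1, 2, 3),
                     plus_reads = c(90, 80, 10), minus_reads = c(90, 100, 10))
  depths <- c(100, 200, 300, 400)
  out <- assign_confidence(cand, depths, q = 25)  # threshold 175
  expect_equal(out$confidence, c("high", "high", "low"))

  # below the minimum clonal depth -> low for any q
  tiny <- data.frame(seqname = "c", pos = 1, plus_reads = 30, minus_reads = 30)
  for (q in c(0, 25, 50, 100)) {
    expect_equal(assign_confidence(tiny, depths, q = q)$confidence, "low")
  }
  # q = 0: anything at or above the minimum clonal depth is high
  att <- data.frame(seqname = "c", pos = 1, plus_reads = 50, minus_reads = 50)
  expect_equal(assign_confidence(att, depths, q = 0)$confidence, "high")
  expect_error(assign_confidence(cand, numeric(0)), "non-empty")
})

test_that("true-footprint estimator reproduces the validation-scaled counts", {
  val <- data.frame(tier = c("high", "low"),
                    n_tested = c(12, 18), n_confirmed = c(12, 1))
  expect_identical(estimate_true_footprints(c(high = 149, low = 69), val), 153L)
  expect_identical(estimate_true_footprints(c(high = 133, low = 104), val), 139L)
  expect_identical(estimate_true_footprints(c(high = 2, low = 95), val), 8L)

  expect_equal(unname(validation_rates(val)), c(1, 1 / 18))
  expect_error(estimate_true_footprints(
    c(high = 1, low = 1),
    data.frame(tier = c("high", "low"), n_tested = c(0, 5),
               n_confirmed = c(0, 1))), "zero candidates tested")

  # monotone non-decreasing in every count and every rate
  base <- estimate_true_footprints(c(high = 50, low = 40), val)
  expect_gte(estimate_true_footprints(c(high = 51, low = 40), val), base)
  expect_gte(estimate_true_footprints(c(high = 50, low = 41), val), base)
  val2 <- val; val2$n_confirmed <- c(12, 2)
  expect_gte(estimate_true_footprints(c(high = 50, low = 40), val2), base)
})

test_that("candidate summary reports intron/exon percentages to one decimal", {
  cand <- data.frame(
    seqname = "chr1", pos = seq_len(552), plus_reads = 1, minus_reads = 1,
    feature_class = c(rep("intron", 213), rep("exon", 13),
                      rep("intergenic", 326)))
  s <- footprint_summary(list(pooled = cand))
  tot <- s[s$sample == "total", ]
  expect_equal(tot$pct_intron, 38.6)
  expect_equal(tot$pct_exon, 2.4)

  empty <- cand[0, ]
  s0 <- footprint_summary(list(a = empty))
  expect_equal(s0$total, c(0L, 0L))
  expect_equal(s0$pct_exon, c(0, 0))
})

test_that("exon-enrichment z-test follows the one-sample proportion formula", {
  ht <- exon_enrichment_test(k = 52, n = 1000, p0 = 0.052)
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 1)

  # frozen from an independent normal-CDF computation of the same inputs
  ht <- exon_enrichment_test(k = 13, n = 552, p0 = 0.015)
  expect_equal(unname(ht$statistic), 1.6527559, tolerance = 1e-6)
  expect_equal(ht$p.value, 0.09838055, tolerance = 1e-6)

  # doubling n at fixed k/n scales |z| by sqrt(2)
  a <- exon_enrichment_test(20, 400, 0.03)
  b <- exon_enrichment_test(40, 800, 0.03)
  expect_equal(unname(b$statistic / a$statistic), sqrt(2), tolerance = 1e-12)

  expect_warning(exon_enrichment_test(1, 20, 0.015), "normal approximation")
  expect_error(exon_enrichment_test(1, 100, 1.2), "p0")
})

test_that("pipeline on simulated libraries recovers true footprints", {
  g <- random_genome(c(chr1 = 20000L, chr2 = 20000L), seed = 55)
  idx <- build_ta_index(g)
  endo <- scan_motif(g, "TACWGTA", both_strands = FALSE)$start
  sites <- ta_sites(idx)
  pool <- sites[!(sites$pos %in% endo), ]
  set.seed(56)
  pick <- sample(nrow(pool), 40)
  fp1 <- pool[pick[1:8], c("seqname", "pos")]
  fp2 <- pool[pick[9:16], c("seqname", "pos")]
  ins1 <- pool[pick[17:24], c("seqname", "pos")]
  ins2 <- pool[pick[25:32], c("seqname", "pos")]
  lib <- simulate_footprint_library(
    g, list(t1 = list(footprints = fp1, insertions = ins1),
            t2 = list(footprints = fp2, insertions = ins2)),
    depth = 1000, noise_sites = 40L, noise_depth = 0.7, seed = 57)
  cands <- call_candidates(lib$tumor_tables, lib$normal_table,
                           lib$clonal_sites)

  truth <- lib$truth
  for (nm in c("t1", "t2")) {
    fp_true <- truth$pos[truth$sample == nm & truth$truth_class == "footprint"]
    other <- truth$pos[truth$sample == nm &
                         truth$truth_class %in% c("endogenous", "junction")]
    expect_true(all(fp_true %in% cands[[nm]]$pos))      # full recall at depth
    expect_false(any(cands[[nm]]$pos %in% other))       # filters clean out
  }

  # high-confidence precision >= low-confidence precision
  cands <- lapply(cands, assign_confidence,
                  clonal_depths = lib$tumor_tables$t1$reads[
                    lib$tumor_tables$t1$pos %in% ins1$pos], q = 25)
  prec <- function(cand, nm, tier) {
    sub <- cand[cand$confidence == tier, ]
    if (nrow(sub) == 0L) return(NA_real_)
    fp_true <- truth$pos[truth$sample == nm & truth$truth_class == "footprint"]
    mean(sub$pos %in% fp_true)
  }
  p_hi <- mean(c(prec(cands$t1, "t1", "high"), prec(cands$t2, "t2", "high")),
               na.rm = TRUE)
  p_lo <- mean(c(prec(cands$t1, "t1", "low"), prec(cands$t2, "t2", "low")),
               na.rm = TRUE)
  expect_gte(p_hi, p_lo)
})
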