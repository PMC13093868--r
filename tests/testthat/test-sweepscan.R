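# Garud H statistics, EHH/XP-EHH, candidate regions, FST blocks and the
# annotation contingency test.

test_that("Garud H statistics match direct sums", {
  # two haplotypes at 0.5/0.5
  m <- cbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  g <- garudH(m)
  expect_equal(g$H1, 0.5)
  expect_equal(g$H12, 1.0)
  # frequencies (0.4, 0.3, 0.2, 0.1)
  m2 <- matrix(0L, 2, 10)
  m2[, 5:7] <- c(1L, 0L); m2[, 8:9] <- c(0L, 1L); m2[, 10] <- c(1L, 1L)
  g2 <- garudH(m2)
  expect_equal(g2$H1, 0.30, tolerance = 1e-12)
  expect_equal(g2$H12, 0.54, tolerance = 1e-12)
  expect_equal(g2$H2H1, 0.14 / 0.30, tolerance = 1e-12)
  # all identical
  g3 <- garudH(matrix(1L, 3, 5))
  expect_equal(g3$H1, 1); expect_equal(g3$H12, 1); expect_equal(g3$H2H1, 0)
  # invariance to column order
  g4 <- garudH(m2[, sample(10)])
  expect_equal(g4$H12, g2$H12)
  # H12 >= H1 always
  set.seed(41)
  for (i in 1:20) {
    mm <- matrix(sample(0:1, 30, TRUE), 3, 10)
    gh <- garudH(mm)
    expect_gte(gh$H12 + 1e-12, gh$H1)
    expect_true(gh$H2H1 >= 0 && gh$H2H1 <= 1)
  }
})

test_that("EHH equals 1 for identical haplotypes and decays by enumeration", {
  # all identical: EHH stays 1 across the span
  m <- matrix(0L, 5, 6); m[3, ] <- 1L
  e <- ehhDecay(m, core = 3, pos = c(100, 200, 300, 400, 500))
  expect_true(all(e$site$ehh_right == 1))
  expect_true(all(e$site$ehh_left == 1))
  expect_equal(e$ies, 400)   # full span integrates to the bp width
  # six haplotypes, derived group of 4 splits 2/2 at the adjacent site:
  # identical pairs among carriers = C(2,2)*2 = 2 of C(4,2) = 6
  m2 <- matrix(0L, 2, 6)
  m2[1, 1:4] <- 1L
  m2[2, c(1, 2, 5)] <- 1L
  e2 <- ehhDecay(m2, core = 1, pos = c(1000, 2000))
  der <- e2$alleles[[2]]
  expect_equal(der$allele, 1)
  expect_equal(der$ehh_right[2], 2 / 6, tolerance = 1e-12)
})

test_that("EHH truncates at gaps above maxgap", {
  m <- matrix(0L, 3, 4); m[2, ] <- 1L
  e <- ehhDecay(m, core = 2, pos = c(1000, 2000, 27500), maxgap = 20000)
  # right arm must stop before the 25.5-kb gap
  expect_equal(length(e$site$pos_right), 1)
})

test_that("XP-EHH is zero for identical populations and antisymmetric", {
  ne <- piecewiseNe(0, 1e5)
  reg <- simulateSweepRegion(sweepRegionSpec(class = "neutral"), ne,
                             n = 16, seed = 71)
  cd <- SummarizedExperiment::colData(reg)
  hA <- reg[, 1:16]; hB <- reg[, 17:32]
  same <- xpehhScan(hA, hA)
  expect_true(all(abs(same$xpehh_raw[!same$skipped]) < 1e-12))
  ab <- xpehhScan(hA, hB)
  ba <- xpehhScan(hB, hA)
  expect_equal(ab$xpehh_raw, -ba$xpehh_raw, tolerance = 1e-10)
  # standardized track has mean ~0, sd ~1
  expect_lt(abs(mean(ab$xpehh, na.rm = TRUE)), 1e-8)
  expect_equal(sd(ab$xpehh, na.rm = TRUE), 1, tolerance = 1e-6)
})

test_that("candidate region calling honours the marker minimum and merges", {
  tr <- data.frame(pos = c(1000, 2000, 3000,          # window 0: 3 sig
                           12000, 13000,              # window 1: 2 sig
                           21000, 22000, 23000,       # window 2: 3 sig
                           55000),
                   sig_p = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                             TRUE, TRUE, TRUE, TRUE),
                   xpehh = c(5, 4, 3, 2, 2, 6, 1, 1, 0.5))
  cr <- candidateRegions(tr, window = 1e4, min_n_extr_mrk = 3)
  # windows 0 and 2 qualify; window 1 (2 markers) breaks the chain only if
  # not adjacent -- here 0 and 2 are non-adjacent so two regions result
  expect_equal(nrow(cr), 2)
  expect_equal(cr$start, c(0, 20000))
  expect_equal(cr$n_sig, c(3, 3))
  expect_equal(cr$extreme[2], 6)
  # two adjacent qualifying windows merge with summed counts
  tr2 <- data.frame(pos = c(1000, 2000, 3000, 11000, 12000, 13000),
                    sig_p = TRUE, xpehh = 1)
  cr2 <- candidateRegions(tr2, window = 1e4)
  expect_equal(nrow(cr2), 1)
  expect_equal(cr2$n_sig, 6)
  expect_equal(c(cr2$start, cr2$end), c(0, 20000))
  # a window with only 2 significant markers yields nothing
  tr3 <- data.frame(pos = c(1000, 2000), sig_p = TRUE, xpehh = 1)
  expect_equal(nrow(candidateRegions(tr3, window = 1e4)), 0)
})

test_that("FST blocks partition SNPs and flag outliers", {
  set.seed(42)
  S <- 2000
  ac1 <- rbinom(S, 20, 0.3); ac2 <- rbinom(S, 20, 0.3)
  # plant a run of fixed differences inside the first block
  ac1[100:130] <- 20; ac2[100:130] <- 0
  fb <- fstBlocks(ac1, ac2, 20, 20, pos = seq_len(S) * 50, blockSize = 1000,
                  top_frac = 0.5)
  expect_equal(nrow(fb), 2)            # 2000 SNPs -> 2 blocks
  expect_equal(sum(fb$n_snps), S)
  expect_true(fb$top[1])               # the block holding the fixed differences
  # trailing partial block below 10% of the size merges into the previous
  fb2 <- fstBlocks(ac1[1:1050], ac2[1:1050], 20, 20,
                   pos = seq_len(1050) * 50, blockSize = 1000)
  expect_equal(nrow(fb2), 1)
  expect_equal(sum(fb2$n_snps), 1050)
  fb3 <- fstBlocks(ac1[1:1500], ac2[1:1500], 20, 20,
                   pos = seq_len(1500) * 50, blockSize = 1000)
  expect_equal(nrow(fb3), 2)           # 500-SNP tail stands alone
})

test_that("annotation chi-square matches hand computation", {
  # identical row profiles -> 0
  t0 <- annotationChisq(matrix(c(10, 10, 5, 5), 2))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # diagonal 2x2 (10,0 / 0,10) -> chi-square 20, df 1
  t1 <- annotationChisq(matrix(c(10, 0, 0, 10), 2))
  expect_equal(t1$statistic, 20, tolerance = 1e-12)
  expect_equal(t1$df, 1)
  # df = (r-1)(c-1)
  t2 <- annotationChisq(matrix(c(5, 3, 2, 8, 1, 4, 2, 2, 7, 1, 1, 2), 3))
  expect_equal(t2$df, (3 - 1) * (4 - 1))
  expect_warning(annotationChisq(matrix(c(5, 0, 3, 2, 0, 1, 4, 0, 7), 3)),
                 "zero-marginal")
})
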