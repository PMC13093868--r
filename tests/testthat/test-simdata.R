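# Distributional contracts of the synthetic-data generators.

test_that("fixed seeds reproduce simulations exactly", {
  ne <- piecewiseNe(0, 5000)
  a <- simulateSinglePop(ne, L = 5e4, n = 6, seed = 7)
  b <- simulateSinglePop(ne, L = 5e4, n = 6, seed = 7)
  expect_identical(haplotypeMatrix(a), haplotypeMatrix(b))
  expect_identical(sitePositions(a), sitePositions(b))
  d <- simulateSinglePop(ne, L = 5e4, n = 6, seed = 8)
  expect_false(identical(haplotypeMatrix(a), haplotypeMatrix(d)))
})

test_that("input validation rejects degenerate requests", {
  ne <- piecewiseNe(0, 5000)
  expect_error(simulateSinglePop(ne, L = 100, n = 6, seed = 1), "10 kb")
  expect_error(simulateSinglePop(ne, L = 5e4, n = 1, seed = 1), "2 diploids")
  expect_error(piecewiseNe(numeric(0), numeric(0)))
  expect_error(piecewiseNe(c(0, 10), c(100, -5)))
  cfg <- demographyConfig(N_ref = 1e4, N1 = 1e4, N2 = 1e4, T_split = 100)
  expect_error(simulateTwoPop(cfg, L = 100, n1 = 4, n2 = 4, seed = 1))
  expect_error(demographyConfig(N_ref = 1e4, N1 = 1e4, N2 = 1e4,
                                T_split = 10, T_contact = 20))
})

test_that("Watterson theta matches 4*Ne*mu under constant size", {
  ne <- piecewiseNe(0, 10000)
  a1 <- sum(1 / (1:11))
  th <- vapply(1:100, function(s)
    nrow(simulateSinglePop(ne, L = 1e6, n = 6, seed = 1000 + s,
                           chunk_len = 10000L)) / a1 / 1e6,
    numeric(1))
  expect_lt(abs(mean(th) / (4 * 1e4 * 3.5e-9) - 1), 0.05)
})

test_that("mean FST is monotone non-decreasing in the split time", {
  meanFst <- function(Tsplit_gen, reps = 100) {
    cfg <- demographyConfig(N_ref = 5000, N1 = 5000, N2 = 5000,
                            T_split = Tsplit_gen / 11)
    mean(vapply(seq_len(reps), function(r) {
      h <- simulateTwoPop(cfg, L = 5e4, n1 = 6, n2 = 6, seed = 400 + r)
      ab <- alleleCountsByPop(h)
      hudsonFst(ab[[1]]$ac, ab[[2]]$ac, 12, 12, blockSize = 1e9)$estimate
    }, numeric(1)))
  }
  f <- c(meanFst(500), meanFst(5000), meanFst(30000))
  expect_true(all(diff(f) > 0))
})

test_that("complete lineage sorting drives FST toward 1", {
  cfg <- demographyConfig(N_ref = 5000, N1 = 5000, N2 = 5000,
                          T_split = 3e5 / 11)
  f <- mean(vapply(1:10, function(r) {
    h <- simulateTwoPop(cfg, L = 1e5, n1 = 8, n2 = 8, seed = 40 + r)
    ab <- alleleCountsByPop(h)
    hudsonFst(ab[[1]]$ac, ab[[2]]$ac, 16, 16, blockSize = 1e9)$estimate
  }, numeric(1)))
  expect_gt(f, 0.85)
})

test_that("deme labels and migration rates can be swapped symmetrically", {
  mk <- function(m12, m21, seeds) {
    cfg <- demographyConfig(N_ref = 5000, N1 = 8000, N2 = 8000,
                            T_split = 4e4 / 11, T_contact = 2e4 / 11,
                            m12 = m12, m21 = m21)
    vapply(seeds, function(s) {
      h <- simulateTwoPop(cfg, L = 1e5, n1 = 6, n2 = 6, seed = s)
      ab <- alleleCountsByPop(h)
      c(fst = hudsonFst(ab[[1]]$ac, ab[[2]]$ac, 12, 12,
                        blockSize = 1e9)$estimate,
        s1 = sum(ab[[1]]$ac > 0 & ab[[1]]$ac < 12),
        s2 = sum(ab[[2]]$ac > 0 & ab[[2]]$ac < 12))
    }, numeric(3))
  }
  A <- mk(2e-4, 2e-5, 1:60)
  B <- mk(2e-5, 2e-4, 61:120)   # swapped rates, fresh seeds
  # swapping (m12, m21) and the deme labels leaves summaries unchanged
  expect_lt(abs(mean(A["fst", ]) - mean(B["fst", ])),
            3 * sqrt(sd(A["fst", ])^2 / 60 + sd(B["fst", ])^2 / 60) + 0.01)
  expect_lt(abs(mean(A["s1", ]) - mean(B["s2", ])),
            3 * sqrt(sd(A["s1", ])^2 / 60 + sd(B["s2", ])^2 / 60) + 2)
})

test_that("a recent bottleneck pushes Tajima's D positive on average", {
  ne <- piecewiseNe(c(0, 2000), c(1000, 10000))  # 10x recent contraction
  d <- vapply(1:200, function(s) {
    h <- simulateSinglePop(ne, L = 5e4, n = 10, seed = 2000 + s)
    w <- windowDiversity(h, window = 5e4, chromLen = 5e4)
    w$tajima_d[1]
  }, numeric(1))
  expect_gt(mean(d, na.rm = TRUE), 0)
})

test_that("hard sweeps cut diversity at the center relative to the edges", {
  ne <- piecewiseNe(0, 1e5)
  spec <- sweepRegionSpec(class = "hard", s = 5e-3, fix_offset = 0)
  ratio <- vapply(1:8, function(s) {
    reg <- simulateSweepRegion(spec, ne, n = 20, seed = 300 + s)
    w <- windowDiversity(reg, window = 10000, chromLen = 110000)
    mean(w$pi[6]) / mean(w$pi[c(1, 11)])
  }, numeric(1))
  expect_lt(mean(ratio), 0.5)
})

test_that("sweep truth logs record class, conditioning and rescaling", {
  ne <- piecewiseNe(0, 1e5)
  spec <- sweepRegionSpec(class = "soft", s = 2e-3, f0 = 0.1)
  reg <- simulateSweepRegion(spec, ne, n = 10, seed = 5)
  tr <- simTruth(reg)
  expect_equal(tr$class, "soft")
  expect_gte(tr$fix_gen, 0)
  expect_equal(tr$rescale, 200)
  expect_gte(tr$copies0, 2)
  expect_error(simulateSweepRegion(sweepRegionSpec(class = "hard", s = 0),
                                   ne, n = 10, seed = 1))
})
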