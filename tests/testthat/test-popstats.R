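# Diversity and differentiation statistics against hand-computed oracles.

test_that("Tajima's D matches the textbook formula on the singleton fixture", {
  # n = 4 haplotypes, 2 singleton sites: a1 = 11/6, a2 = 49/36
  h <- toyHap(matrix(c(1, 0, 0, 0,
                       0, 1, 0, 0), nrow = 2, byrow = TRUE),
              pos = c(10L, 20L))
  w <- windowDiversity(h, window = 100, chromLen = 100)
  expect_equal(w$S[1], 2)
  expect_equal(w$pi[1] * 100, 1.0)               # per-unit pairwise sum
  expect_equal(w$theta_w[1] * 100, 2 / (11 / 6), tolerance = 1e-12)
  expect_equal(w$tajima_d[1], tajimaOracle(4, 2, 1.0), tolerance = 1e-12)
  expect_equal(round(w$tajima_d[1], 3), -0.710)
})

test_that("per-site pi enumerates all pairs", {
  # derived count 2 of 4: 6 pairs, 4 discordant -> 2*2*2/(4*3) = 2/3
  h <- toyHap(matrix(c(1, 1, 0, 0), nrow = 1), pos = 5L)
  w <- windowDiversity(h, window = 10, chromLen = 10)
  expect_equal(w$pi[1] * 10, 2 / 3, tolerance = 1e-12)
})

test_that("monomorphic windows have pi = 0 and undefined D", {
  h <- toyHap(matrix(c(1, 0, 0, 0), nrow = 1), pos = 5L)
  w <- windowDiversity(h, window = 10, chromLen = 30)
  expect_equal(w$S, c(1, 0, 0))
  expect_true(all(is.na(w$tajima_d[2:3])))
  expect_equal(w$pi[2:3], c(0, 0))
})

test_that("SFS construction, folding and scaling follow the definitions", {
  s <- computeSfs(c(1), n = 4)
  expect_equal(sfsCounts(s), c(0, 1, 0, 0, 0))
  f <- computeSfs(c(3), n = 4, folded = TRUE)   # derived 3 of 4 -> minor 1
  expect_equal(sfsCounts(f), c(0, 1, 0))
  expect_error(computeSfs(c(5), n = 4))
  # scaling: k(n-k)/n for n = 4 gives 0.75 and 1.0
  f2 <- computeSfs(c(1, 2), n = 4, folded = TRUE)
  sc <- scaleFoldedSfs(f2)
  expect_equal(sfsCounts(sc), c(0, 0.75, 1.0))
  expect_error(scaleFoldedSfs(computeSfs(c(1), n = 4)))
  z <- computeSfs(integer(0), n = 4, folded = TRUE)
  expect_equal(sfsCounts(scaleFoldedSfs(z)), c(0, 0, 0))
})

test_that("hypergeometric projection uses the exact weights", {
  # k = 2 of n = 4 projected to m = 2: weights (1/6, 2/3, 1/6)
  s <- computeSfs(c(2), n = 4)
  p <- projectSfs(s, 2)
  expect_equal(sfsCounts(p), c(1 / 6, 2 / 3, 1 / 6), tolerance = 1e-12)
  # identity at m = n, and mass preservation
  expect_equal(sfsCounts(projectSfs(s, 4)), sfsCounts(s), tolerance = 1e-12)
  s2 <- computeSfs(c(1, 2, 3, 3), n = 4)
  expect_equal(sum(sfsCounts(projectSfs(s2, 3))), sum(sfsCounts(s2)),
               tolerance = 1e-12)
  expect_error(projectSfs(s, 6))
})

test_that("projection agrees with Monte-Carlo subsampling of haplotypes", {
  set.seed(1)
  ne <- piecewiseNe(0, 10000)
  h <- simulateSinglePop(ne, L = 2e5, n = 6, seed = 31)
  s12 <- computeSfs(h)                     # n = 12
  proj <- sfsCounts(projectSfs(s12, 6))
  H <- haplotypeMatrix(h)
  mc <- Reduce(`+`, lapply(1:400, function(i) {
    sub <- H[, sample.int(12, 6), drop = FALSE]
    ac <- rowSums(sub)
    tabulate(ac + 1L, nbins = 7L)
  })) / 400
  expect_lt(max(abs(mc[2:6] - proj[2:6]) / pmax(proj[2:6], 1)), 0.1)
})

test_that("Hudson FST reproduces hand-computed values and symmetry", {
  # counts 3/4 vs 1/4: numerator 0.125, denominator 0.625 -> 0.2
  f <- hudsonFst(3, 1, 4, 4, blockSize = 10)
  expect_equal(f$estimate, 0.2, tolerance = 1e-12)
  # fixed difference -> 1
  expect_equal(hudsonFst(4, 0, 4, 4)$estimate, 1, tolerance = 1e-12)
  # identical counts, equal sizes -> numerator <= 0
  f0 <- hudsonFst(c(2, 1), c(2, 1), 4, 4)
  expect_lte(f0$estimate, 0)
  # symmetry under population swap
  a1 <- c(3, 1, 2, 4, 0, 2); a2 <- c(1, 2, 2, 0, 1, 3)
  expect_equal(hudsonFst(a1, a2, 6, 6)$estimate,
               hudsonFst(a2, a1, 6, 6)$estimate, tolerance = 1e-12)
  # jackknife SE shrinks to zero when blocks are identical
  f1 <- hudsonFst(rep(c(3, 1), 50), rep(c(1, 0), 50), 4, 4, blockSize = 2)
  expect_lt(f1$se, 1e-12)
  expect_error(hudsonFst(0, 0, 4, 4))
})

test_that("LD decay returns r2 = 1 for identical SNPs and ~0 for independent ones", {
  set.seed(2)
  g1 <- sample(0:2, 200, replace = TRUE)
  gm <- toyGeno(rbind(g1, g1), pos = c(100L, 150L))
  ld <- ldDecay(gm, breaks = c(10, 100), nPairs = 50, seed = 1)
  expect_equal(ld$mean_r2[1], 1, tolerance = 1e-12)
  ne <- piecewiseNe(0, 10000)
  h <- simulateSinglePop(ne, L = 2e5, n = 30, seed = 77, chunk_len = 1000L)
  gm2 <- hapToGenotypes(h)
  # pairs >= 50 kb apart span many independent chunks
  ld2 <- ldDecay(gm2, breaks = c(5e4, 2e5), nPairs = 400, seed = 3)
  expect_lt(ld2$mean_r2[1], 3 / 30)
})

test_that("ROH detection finds planted homozygous tracts", {
  set.seed(4)
  S <- 2000
  pos <- sort(sample.int(2e6, S))
  g <- matrix(sample(0:2, S * 2, replace = TRUE, prob = c(.4, .3, .3)),
              ncol = 2)
  # sample 1: homozygous tract from 0.5 Mb to 1.5 Mb
  inTract <- pos >= 5e5 & pos < 15e5
  g[inTract, 1] <- sample(c(0L, 2L), sum(inTract), replace = TRUE)
  gm <- toyGeno(g, pos = pos)
  r <- rohScan(gm, chromLen = 2e6)
  seg <- r$segments[r$segments$sample == "S1" & r$segments$length >= 1e5, ]
  expect_gte(nrow(seg), 1)
  cover <- sum(pmin(seg$end, 15e5) - pmax(seg$start, 5e5))
  expect_gte(cover / 1e6, 0.9)
  expect_gt(r$froh["S1"], 0.4)
  # sample 2 is heterozygous throughout often enough to yield no long ROH
  expect_lt(r$froh["S2"], 0.2)
})

test_that("fully homozygous and fully heterozygous chromosomes are edge cases", {
  pos <- seq(1000L, 2e5, by = 1000L)
  gm <- toyGeno(cbind(rep(1L, length(pos)), rep(0L, length(pos))), pos = pos)
  r <- rohScan(gm, chromLen = 2e5)
  expect_equal(unname(r$froh["S1"]), 0)       # all het: no ROH
  expect_equal(unname(r$froh["S2"]), 1)       # all hom: one spanning segment
})

test_that("IBD tracts cover planted shared haplotypes and twins", {
  set.seed(5)
  ne <- piecewiseNe(0, 10000)
  h <- simulateSinglePop(ne, L = 2e6, n = 4, seed = 91)
  H <- haplotypeMatrix(h)
  pos <- sitePositions(h)
  # plant a shared 1-Mb haplotype between individuals 1 and 2
  shared <- pos >= 5e5 & pos < 15e5
  H[shared, 3] <- H[shared, 1]
  g <- H[, c(1, 3)] + H[, c(2, 4)]
  gm <- toyGeno(g, pos = pos)
  tr <- ibdSegments(gm, c(1, 2), chromLen = 2e6)
  expect_gte(nrow(tr), 1)
  cover <- sum(pmin(tr$end, 15e5) - pmax(tr$start, 5e5))
  expect_gte(cover / 1e6, 0.8)
  # identical twins: one tract spanning the chromosome
  gmTwin <- toyGeno(cbind(g[, 1], g[, 1]), pos = pos)
  tw <- ibdSegments(gmTwin, c(1, 2), chromLen = 2e6)
  expect_equal(nrow(tw), 1)
  expect_gte((tw$end - tw$start) / 2e6, 0.95)
})

test_that("statistics are invariant to sample relabelling", {
  ne <- piecewiseNe(0, 10000)
  h <- simulateSinglePop(ne, L = 5e4, n = 6, seed = 15)
  w1 <- windowDiversity(h, window = 1e4, chromLen = 5e4)
  perm <- c(5, 6, 3, 4, 9, 10, 1, 2, 11, 12, 7, 8)
  h2 <- toyHap(haplotypeMatrix(h)[, perm], pos = sitePositions(h))
  w2 <- windowDiversity(h2, window = 1e4, chromLen = 5e4)
  expect_equal(w1$pi, w2$pi)
  expect_equal(w1$tajima_d, w2$tajima_d)
})
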