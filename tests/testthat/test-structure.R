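# PCA, joint SFS construction and the panmixia permutation test.

test_that("PCA separates deeply diverged demes on PC1", {
  cfg <- demographyConfig(N_ref = 5000, N1 = 5000, N2 = 5000,
                          T_split = 1e5 / 11)
  h <- simulateTwoPop(cfg, L = 2e5, n1 = 10, n2 = 10, seed = 21)
  gm <- hapToGenotypes(h)
  pc <- pcaGenotypes(gm, nComponents = 3)
  side <- sign(pc$scores[, 1])
  pop <- SummarizedExperiment::colData(gm)$population
  acc <- max(mean((side > 0) == (pop == "pop1")),
             mean((side < 0) == (pop == "pop1")))
  expect_gte(acc, 0.95)
  expect_lte(sum(pc$explained), 1 + 1e-9)
})

test_that("duplicated samples land on identical PCA coordinates", {
  set.seed(31)
  G <- matrix(sample(0:2, 50 * 6, replace = TRUE), ncol = 6)
  G[, 6] <- G[, 5]
  gm <- toyGeno(G)
  pc <- pcaGenotypes(gm, nComponents = 3)
  expect_equal(pc$scores[5, ], pc$scores[6, ], tolerance = 1e-8)
})

test_that("requesting more components than samples reduces with a warning", {
  set.seed(32)
  gm <- toyGeno(matrix(sample(0:2, 40 * 4, replace = TRUE), ncol = 4))
  expect_warning(pc <- pcaGenotypes(gm, nComponents = 10), "fewer")
  expect_lte(ncol(pc$scores), 3)
})

test_that("joint SFS tabulates cells, masks corners and is transpose-equivariant", {
  H <- matrix(0L, 3, 8)
  H[1, 1] <- 1L                      # derived count (1, 0)
  H[2, c(1, 2, 5)] <- 1L             # derived count (2, 1)
  H[3, 5:8] <- 1L                    # derived count (0, 4): fixed in pop2
  h <- toyHap(H, population = c("A", "A", "B", "B"))
  js <- jointSfs(h, pops = c("A", "B"))
  C <- jsfsCounts(js)
  expect_equal(C[2, 1], 1)           # cell [1, 0]
  expect_equal(C[3, 2], 1)           # cell [2, 1]
  expect_equal(C[1, 5], 1)           # cell [0, 4]
  expect_equal(sum(C[!jsfsMask(js)]), 3)
  jt <- jointSfs(h, pops = c("B", "A"))
  expect_equal(jsfsCounts(jt), t(C))
})

test_that("unmasked jSFS mass equals the polarized complete segregating sites", {
  h <- cachedPanmictic()
  js <- jointSfs(h)
  H <- haplotypeMatrix(h)
  ac <- rowSums(H)
  expect_equal(sum(jsfsCounts(js)[!jsfsMask(js)]),
               sum(ac > 0 & ac < ncol(H)))
})

test_that("jSFS projection matches the hand-computed hypergeometric table", {
  # five sites with counts (1,0) (2,1) (3,3) (0,2) (4,4) at n = (4,4)
  C <- matrix(0, 5, 5)
  C[2, 1] <- 1; C[3, 2] <- 1; C[4, 4] <- 1; C[1, 3] <- 1; C[5, 5] <- 1
  js <- jointSfsFromMatrix(C, 4, 4)
  pr <- projectSfs(js, c(2, 2))
  W <- demosel:::.projWeights(4, 2)
  hand <- matrix(0, 3, 3)
  add <- function(k1, k2, wgt = 1) {
    hand <<- hand + wgt * outer(W[, k1 + 1], W[, k2 + 1])
  }
  add(1, 0); add(2, 1); add(3, 3); add(0, 2); add(4, 4)
  expect_equal(jsfsCounts(pr), hand, tolerance = 1e-12)
})

test_that("panmixia test does not reject scrambled labels of one population", {
  h <- cachedPanmictic()
  pm <- panmixiaTest(h, n_perm = 300, seed = 5)
  expect_gt(pm$p_value, 0.01)
  # permutation chi-squares bracket the observed one for null data
  expect_gt(mean(pm$null >= pm$chisq_obs), 0.01)
})

test_that("panmixia test rejects moderately diverged demes", {
  cfg <- demographyConfig(N_ref = 1e4, N1 = 1e4, N2 = 1e4,
                          T_split = 0.05 * 2e4 / 11)   # FST ~ 0.05
  h <- simulateTwoPop(cfg, L = 2e6, n1 = 10, n2 = 10, seed = 61)
  pm <- panmixiaTest(h, n_perm = 300, seed = 6)
  expect_lt(pm$p_value, 0.01)
})

test_that("panmixia p-value is invariant to allele-label flips in folded mode", {
  h <- cachedPanmictic()
  p1 <- panmixiaTest(h, n_perm = 100, seed = 7, folded = TRUE)
  flip <- toyHap(1L - haplotypeMatrix(h), pos = sitePositions(h),
                 population = SummarizedExperiment::colData(h)$population[
                   SummarizedExperiment::colData(h)$hapIndex == 1])
  p2 <- panmixiaTest(flip, n_perm = 100, seed = 7, folded = TRUE)
  expect_equal(p1$p_value, p2$p_value)
  expect_equal(p1$chisq_obs, p2$chisq_obs, tolerance = 1e-9)
})

test_that("groups below two samples are refused", {
  h <- cachedPanmictic()
  cd <- SummarizedExperiment::colData(h)
  expect_error(panmixiaTest(h[, cd$sample %in% c("P1_01", "P2_01", "P2_02")]),
               "at least 2")
})
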