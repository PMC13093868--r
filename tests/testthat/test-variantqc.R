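# VCF round-trips and the site/genotype/sample filter cascade.

test_that("haplotype VCF writing is canonical and round-trips losslessly", {
  h <- toyHap(matrix(c(0, 1, 1, 0,
                       1, 1, 1, 1,
                       0, 0, 1, 0), nrow = 3, byrow = TRUE),
              pos = c(11L, 25L, 40L))
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  writeVcfFile(h, f1)
  lines <- readLines(f1)
  body <- grep("^chr1", lines, value = TRUE)
  expect_length(body, 3)
  gt <- strsplit(body[1], "\t")[[1]][10:11]
  expect_equal(gt, c("0|1", "1|0"))
  # fixed-derived site written as 1|1 for every sample
  expect_equal(strsplit(body[2], "\t")[[1]][10:11], c("1|1", "1|1"))
  h2 <- readPhasedVcf(f1)
  expect_equal(unname(haplotypeMatrix(h2)), unname(haplotypeMatrix(h)))
  expect_equal(sitePositions(h2), sitePositions(h))
  writeVcfFile(h2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
})

test_that("simulated haplotypes survive a VCF round-trip", {
  ne <- piecewiseNe(0, 8000)
  h <- simulateSinglePop(ne, L = 2e4, n = 4, seed = 3)
  f <- tempfile(fileext = ".vcf")
  writeVcfFile(h, f)
  h2 <- readPhasedVcf(f)
  expect_equal(unname(haplotypeMatrix(h2)), unname(haplotypeMatrix(h)))
})

test_that("the filter cascade applies annotations, GQ and missingness in order", {
  f <- writeQcFixtureVcf(tempfile(fileext = ".vcf"))
  gm <- loadFilteredVcf(f)
  # 10 sites: 3 fail FS > 60 (FS = 60 itself is kept), 1 triallelic -> 6
  expect_equal(nrow(gm), 6)
  rep <- S4Vectors::metadata(gm)$qc_report
  expect_equal(rep$n_not_biallelic_snp, 1)
  expect_equal(rep$n_failed_annotation, 3)
  expect_equal(rep$n_retained_samples, 4)
})

test_that("QD threshold is a strict less-than and GQ strictly greater-than", {
  # QD = 4.9 dropped, QD = 5.0 kept; GQ = 20 masked, GQ = 21 kept
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"x\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"x\">",
           paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO",
                   "FORMAT","a","b"), collapse = "\t"))
  rows <- c(paste(c("chr1",100,".","A","T",".",".","QD=4.9","GT:GQ",
                    "0/1:99","0/0:99"), collapse = "\t"),
            paste(c("chr1",200,".","A","T",".",".","QD=5.0","GT:GQ",
                    "0/1:20","0/0:21"), collapse = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, rows), f)
  thr <- qcThresholds(); thr$site_miss <- 1.1; thr$sample_miss <- 1.1
  gm <- loadFilteredVcf(f, thresholds = thr)
  expect_equal(sitePositions(gm), 200L)
  G <- genotypeMatrix(gm)
  expect_true(is.na(G[1, 1]))     # GQ = 20 masked
  expect_equal(unname(G[1, 2]), 0L)       # GQ = 21 retained
})

test_that("accessibility masking and missingness thresholds drop rows/columns", {
  f <- writeQcFixtureVcf(tempfile(fileext = ".vcf"))
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 650))
  gm <- loadFilteredVcf(f, mask = mask)
  expect_true(all(sitePositions(gm) <= 650))
})

test_that("the retained site set ignores sample order", {
  f <- writeQcFixtureVcf(tempfile(fileext = ".vcf"))
  gm1 <- loadFilteredVcf(f)
  # rewrite with permuted sample columns
  lines <- readLines(f)
  hi <- grep("^#CHROM", lines)
  reorder <- function(l) {
    p <- strsplit(l, "\t")[[1]]
    paste(c(p[1:9], p[c(12, 10, 13, 11)]), collapse = "\t")
  }
  lines[hi:length(lines)] <- vapply(lines[hi:length(lines)], reorder, "")
  f2 <- tempfile(fileext = ".vcf")
  writeLines(lines, f2)
  gm2 <- loadFilteredVcf(f2)
  expect_equal(sitePositions(gm1), sitePositions(gm2))
})

test_that("polarization recodes, flags and is an involution on flipped sites", {
  g <- matrix(c(0L, 1L, 2L,
                2L, 1L, 0L,
                0L, 0L, 1L), nrow = 3, byrow = TRUE)
  gm <- toyGeno(g, siteInfo = data.frame(ref = c("A", "C", "G"),
                                         alt = c("T", "G", "A"),
                                         ancestral = NA_character_))
  out <- c("A", "G", "T")  # ref, alt, third allele
  p1 <- polarizeGenotypes(gm, out)
  G1 <- genotypeMatrix(p1)
  expect_equal(unname(G1[1, ]), g[1, ])     # outgroup = ref: unchanged
  expect_equal(unname(G1[2, ]), 2L - g[2, ])  # outgroup = alt: flipped
  mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(p1))
  expect_equal(mc$polarized, c(TRUE, TRUE, FALSE))
  rep <- S4Vectors::metadata(p1)$polarize_report
  expect_equal(rep$n_unpolarized, 1)
  # involution: applying the same outgroup twice restores the coding
  p2 <- polarizeGenotypes(p1, out)
  expect_equal(unname(genotypeMatrix(p2)[2, ]), g[2, ])
})

test_that("sexing calls follow the coverage ratio with an ambiguity band", {
  depth <- matrix(c(30, 30, 30, 0,     # autosomes
                    30, 15, 18, 0), ncol = 2,
                  dimnames = list(c("f", "m", "amb", "zero"), c("2", "X")))
  # X/genome ratios: 1.0 (XX), 0.667 (X0), exactly 0.75, undefined
  sx <- sexFromDepth(depth, xChrom = "X")
  expect_equal(sx$sex[1], "F")
  expect_equal(sx$sex[2], "M")
  expect_equal(unname(depth["amb", "X"] / mean(depth["amb", ])), 0.75)
  expect_equal(sx$sex[3], "ambiguous")
  expect_true(is.na(sx$sex[4]))
})

test_that("relatedness separates duplicates, parent-offspring and unrelated", {
  set.seed(8)
  ne <- piecewiseNe(0, 10000)
  h <- simulateSinglePop(ne, L = 1e6, n = 6, seed = 55)
  H <- haplotypeMatrix(h)
  g <- function(i, j) H[, i] + H[, j]
  # child shares haplotype 1 with parent (cols 1,2); unrelated pair from 5..8
  G <- cbind(dup1 = g(1, 2), dup2 = g(1, 2), parent = g(3, 4),
             child = g(3, 5), u1 = g(7, 8), u2 = g(9, 10))
  gm <- toyGeno(G, pos = sitePositions(h),
                samples = colnames(G))
  rel <- pairwiseRelatedness(gm)
  pick <- function(a, b) rel$pi_hat[rel$sample1 == a & rel$sample2 == b]
  expect_gt(pick("dup1", "dup2"), 0.9)
  expect_equal(pick("parent", "child"), 0.5, tolerance = 0.15)
  expect_lt(abs(pick("u1", "u2")), 0.15)
  expect_true(rel$flagged[rel$sample1 == "dup1" & rel$sample2 == "dup2"])
  expect_error(pairwiseRelatedness(gm[1:50, ]), "100")
})

test_that("LD pruning removes exactly the right SNPs", {
  set.seed(9)
  base <- sample(0:2, 60, replace = TRUE, prob = c(.25, .5, .25))
  noise <- function() sample(0:2, 60, replace = TRUE, prob = c(.25, .5, .25))
  # two perfectly correlated SNPs -> one survives
  gm <- toyGeno(rbind(base, base, noise()), pos = c(10L, 20L, 30L))
  pr <- ldPrune(gm, r2_max = 0.5, window = 10, step = 5, maf_min = 0.01)
  expect_equal(sitePositions(pr), c(10L, 30L))
  # mutually independent SNPs at a lenient threshold -> unchanged
  gm2 <- toyGeno(do.call(rbind, replicate(5, noise(), simplify = FALSE)),
                 pos = (1:5) * 10L)
  G2 <- genotypeMatrix(gm2)
  r2max <- max(demosel:::.rogersHuffR2(t(G2))[upper.tri(diag(5))])
  pr2 <- ldPrune(gm2, r2_max = r2max + 0.01, window = 10, step = 5)
  expect_equal(nrow(pr2), 5)
  expect_error(ldPrune(toyGeno(rbind(base, base), pos = c(20L, 10L))),
               "sorted")
})

test_that("pruning on a known 6-SNP structure matches brute-force enumeration", {
  set.seed(10)
  a <- sample(0:2, 80, replace = TRUE, prob = c(.3, .4, .3))
  b <- sample(0:2, 80, replace = TRUE, prob = c(.3, .4, .3))
  c2 <- sample(0:2, 80, replace = TRUE, prob = c(.3, .4, .3))
  G <- rbind(a, a, b, a, b, c2)   # duplicates of a at 1,2,4; b at 3,5
  gm <- toyGeno(G, pos = (1:6) * 10L)
  pr <- ldPrune(gm, r2_max = 0.8, window = 6, step = 3)
  # brute-force left-to-right scan oracle
  R2 <- demosel:::.rogersHuffR2(t(G))
  alive <- rep(TRUE, 6)
  for (i in 1:5) if (alive[i])
    for (j in (i + 1):6) if (alive[j] && R2[i, j] > 0.8) alive[j] <- FALSE
  expect_equal(sitePositions(pr), ((1:6) * 10L)[alive])
  # invariant: no surviving within-window pair above the threshold
  R2s <- demosel:::.rogersHuffR2(t(genotypeMatrix(pr)))
  expect_true(all(R2s[upper.tri(R2s)] <= 0.8))
})
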