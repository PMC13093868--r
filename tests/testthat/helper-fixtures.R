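# Shared fixtures, built in code. Small simulations reused across tests are
# cached here so each file stays fast.

# tiny deterministic haplotype container
toyHap <- function(mat, pos = NULL, ...) {
  if (is.null(pos)) pos <- seq_len(nrow(mat)) * 100L
  HaplotypeData(mat, pos, ...)
}

# diploid genotype container from a plain matrix
toyGeno <- function(mat, pos = NULL, ...) {
  if (is.null(pos)) pos <- seq_len(nrow(mat)) * 100L
  GenotypeData(mat, pos, ...)
}

# hand-written VCF fixture for the QC filters: 10 sites of which 3 fail
# FS > 60 and 1 is triallelic, leaving 6 to survive those two filters
writeQcFixtureVcf <- function(path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
    "##INFO=<ID=RPRS,Number=1,Type=Float,Description=\"RankSum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"))
  gt <- function(...) paste(..., sep = "\t")
  fs <- function(v) sprintf("AA=A;QD=20.0;FS=%s;RPRS=1.0", v)
  rows <- c(
    gt("chr1", 100, ".", "A", "T", ".", ".", fs("1.0"),  "GT:GQ",
       "0/0:99", "0/1:99", "0/0:99", "1/1:99"),
    gt("chr1", 200, ".", "A", "T", ".", ".", fs("70.0"), "GT:GQ",   # FS fail
       "0/0:99", "0/1:99", "0/0:99", "1/1:99"),
    gt("chr1", 300, ".", "A", "T,G", ".", ".", "AA=A;QD=20.0;FS=1.0;RPRS=1.0",
       "GT:GQ", "0/0:99", "0/1:99", "0/2:99", "1/1:99"),             # triallelic
    gt("chr1", 400, ".", "G", "C", ".", ".", fs("1.0"),  "GT:GQ",
       "0/1:99", "0/1:99", "0/0:99", "0/0:99"),
    gt("chr1", 500, ".", "A", "T", ".", ".", fs("80.5"), "GT:GQ",   # FS fail
       "0/0:99", "0/0:99", "0/1:99", "0/0:99"),
    gt("chr1", 600, ".", "A", "T", ".", ".", fs("1.0"),  "GT:GQ",
       "0/0:99", "0/1:99", "1/1:99", "0/0:99"),
    gt("chr1", 700, ".", "C", "G", ".", ".", fs("60.0"), "GT:GQ",   # FS == 60 kept
       "0/0:99", "0/1:99", "0/0:99", "0/0:99"),
    gt("chr1", 800, ".", "A", "T", ".", ".", fs("61.0"), "GT:GQ",   # FS fail
       "0/1:99", "0/1:99", "0/0:99", "0/0:99"),
    gt("chr1", 900, ".", "T", "A", ".", ".", fs("2.0"),  "GT:GQ",
       "0/0:99", "0/0:99", "0/1:99", "1/1:99"),
    gt("chr1", 1000, ".", "A", "G", ".", ".", fs("3.0"), "GT:GQ",
       "0/1:99", "0/0:99", "0/0:99", "0/1:99"))
  writeLines(c(hdr, rows), path)
  path
}

# independent Tajima's D oracle (direct textbook formula)
tajimaOracle <- function(n, S, piSum) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (piSum - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# cached neutral two-population sample used by several structure tests
cachedPanmictic <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- demographyConfig(N_ref = 1e4, N1 = 1e4, N2 = 1e4, T_split = 0)
      val <<- simulateTwoPop(cfg, L = 3e5, n1 = 10, n2 = 10, seed = 99)
    }
    val
  }
})

# merge two polarized samples onto their union site set, as a joint call
# set would: a site absent from one sample is ancestral-fixed there
unionHaps <- function(a, b) {
  pos <- sort(union(sitePositions(a), sitePositions(b)))
  fill <- function(x) {
    H <- matrix(0L, length(pos), ncol(haplotypeMatrix(x)))
    H[match(sitePositions(x), pos), ] <- haplotypeMatrix(x)
    toyHap(H, pos = pos)
  }
  list(A = fill(a), B = fill(b))
}
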