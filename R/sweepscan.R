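# Haplotype- and frequency-based selection scans: Garud H statistics,
# EHH decay and its integral, cross-population XP-EHH with FDR control and
# candidate-region calling, Hudson FST in SNP blocks, and a contingency
# test on annotation categories of outlier SNP sets.

#' Garud haplotype (or multilocus-genotype) homozygosity statistics
#'
#' Columns of \code{m} are treated as units (phased haplotypes for
#' H statistics, diploid multilocus genotypes for the J analogues):
#' with sorted frequencies p1 >= p2 >= ..., H1 = sum p_i^2,
#' H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2, H2 = H1 - p1^2.
#'
#' @param m sites x units matrix over one window
#' @return list: H1, H12, H2, H2H1, n_distinct
#' @export
garudH <- function(m) {
  if (is.null(dim(m)) || ncol(m) < 2) stop("need at least 2 columns")
  if (nrow(m) == 0)
    return(list(H1 = NA_real_, H12 = NA_real_, H2 = NA_real_,
                H2H1 = NA_real_, n_distinct = NA_integer_))
  key <- apply(m, 2, paste, collapse = ",")
  p <- sort(as.numeric(table(key)) / ncol(m), decreasing = TRUE)
  H1 <- sum(p^2)
  H12 <- if (length(p) >= 2) (p[1] + p[2])^2 + sum(p[-(1:2)]^2) else 1
  H2 <- H1 - p[1]^2
  list(H1 = H1, H12 = H12, H2 = H2,
       H2H1 = if (H1 > 0) H2 / H1 else NA_real_,
       n_distinct = length(p))
}

#' EHH decay around a core site
#'
#' Extended haplotype homozygosity: the probability that two randomly drawn
#' haplotypes carrying the same core allele are identical at every site from
#' the core out to a distance, traced in both directions until it falls
#' below \code{ehh_floor} or a gap exceeds \code{maxgap}. The integral over
#' bp (trapezoid rule, both arms, both-allele site version) is iES.
#'
#' @param hap a \linkS4class{HaplotypeData} or sites x haplotypes matrix
#' @param core core site index (1-based)
#' @param pos site positions (required when \code{hap} is a plain matrix)
#' @param maxgap maximum bp gap a haplotype may extend across
#' @param ehh_floor truncation level for the curve
#' @return list with per-allele curves (\code{alleles}: position/ehh arms
#'   and integrated ihh) and the site-level \code{ies}
#' @export
ehhDecay <- function(hap, core, pos = NULL, maxgap = 20000,
                     ehh_floor = 0.05) {
  if (is(hap, "HaplotypeData")) { pos <- sitePositions(hap); hap <- haplotypeMatrix(hap) }
  stopifnot(!is.null(pos), core >= 1, core <= nrow(hap))
  byA <- .ehh_site(hap, as.numeric(pos), as.integer(core - 1), maxgap,
                   ehh_floor, TRUE)
  site <- .ehh_site(hap, as.numeric(pos), as.integer(core - 1), maxgap,
                    ehh_floor, FALSE)
  list(alleles = byA, ies = site$ies, site = site)
}

#' Cross-population extended haplotype homozygosity scan
#'
#' Per shared site, XP-EHH is \code{log(iES_A / iES_B)}, standardised
#' genome-wide to mean 0 and unit variance; two-sided normal p-values are
#' Benjamini-Hochberg adjusted. Sites where either iES is zero are skipped
#' and flagged.
#'
#' @param hapA,hapB \linkS4class{HaplotypeData} on identical site sets
#' @param maxgap,ehh_floor as in \code{\link{ehhDecay}}
#' @param fdr q-value threshold for the \code{sig_q} flag
#' @param sig_p raw p-value threshold for the \code{sig_p} flag
#' @return data.frame: pos, ies_a, ies_b, xpehh_raw, xpehh (standardised),
#'   p, q, sig_q, sig_p, skipped
#' @importFrom stats p.adjust sd
#' @export
xpehhScan <- function(hapA, hapB, maxgap = 20000, ehh_floor = 0.05,
                      fdr = 0.05, sig_p = 1e-4) {
  posA <- sitePositions(hapA); posB <- sitePositions(hapB)
  if (!identical(as.integer(posA), as.integer(posB)))
    stop("populations must share the site set")
  iesA <- .ies_scan(haplotypeMatrix(hapA), as.numeric(posA), maxgap, ehh_floor)
  iesB <- .ies_scan(haplotypeMatrix(hapB), as.numeric(posB), maxgap, ehh_floor)
  skipped <- iesA <= 0 | iesB <= 0
  raw <- rep(NA_real_, length(posA))
  raw[!skipped] <- log(iesA[!skipped] / iesB[!skipped])
  z <- (raw - mean(raw, na.rm = TRUE)) / sd(raw, na.rm = TRUE)
  p <- 2 * pnorm(-abs(z))
  q <- p.adjust(p, method = "BH")
  data.frame(pos = posA, ies_a = iesA, ies_b = iesB, xpehh_raw = raw,
             xpehh = z, p = p, q = q,
             sig_q = !is.na(q) & q < fdr,
             sig_p = !is.na(p) & p < sig_p,
             skipped = skipped)
}

#' Candidate selection regions from a significance-annotated track
#'
#' Fixed windows (0-based half-open) holding at least \code{min_n_extr_mrk}
#' significant markers qualify; adjacent qualifying windows are merged into
#' regions with summed counts and the most extreme statistic retained.
#'
#' @param track data.frame with columns \code{pos}, a logical significance
#'   column (\code{sig}), and optionally a statistic column \code{stat}
#' @param window window size in bp
#' @param min_n_extr_mrk minimum significant markers per window
#' @param sig name of the significance column (default \code{"sig_p"})
#' @param stat name of the statistic column (default \code{"xpehh"})
#' @return data.frame: start, end, n_sig, extreme
#' @export
candidateRegions <- function(track, window = 1e4, min_n_extr_mrk = 3,
                             sig = "sig_p", stat = "xpehh") {
  s <- track[[sig]]
  if (is.null(s)) stop("missing significance column: ", sig)
  st <- if (!is.null(track[[stat]])) track[[stat]] else rep(NA_real_, nrow(track))
  pos <- track$pos
  widx <- (pos - 1) %/% window            # 0-based window id, half-open
  sigTab <- tapply(s, widx, sum)
  qual <- as.integer(names(sigTab))[sigTab >= min_n_extr_mrk]
  if (!length(qual))
    return(data.frame(start = numeric(), end = numeric(),
                      n_sig = integer(), extreme = numeric()))
  qual <- sort(qual)
  grp <- cumsum(c(1, diff(qual) > 1))
  out <- do.call(rbind, lapply(split(qual, grp), function(ws) {
    inReg <- widx %in% ws & s
    data.frame(start = min(ws) * window, end = (max(ws) + 1) * window,
               n_sig = sum(inReg),
               extreme = if (any(inReg)) st[inReg][which.max(abs(st[inReg]))]
                         else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Hudson FST in blocks of consecutive SNPs with top-fraction flags
#'
#' Ratio-of-averages Hudson FST per block of \code{blockSize} SNPs; a
#' trailing block shorter than 10 percent of the block size is merged into
#' the previous one. Blocks at or above the empirical \code{1 - top_frac}
#' quantile are flagged (an outlier ranking: the top fraction is flagged
#' whatever the absolute differentiation).
#'
#' @param ac1,ac2 per-site derived/alt allele counts
#' @param n1,n2 haploid called counts (scalar or vector)
#' @param pos site positions
#' @param blockSize SNPs per block
#' @param top_frac flagged fraction
#' @return data.frame: start, end (bp of block ends), n_snps, fst, top
#' @importFrom stats quantile
#' @export
fstBlocks <- function(ac1, ac2, n1, n2, pos, blockSize = 1000,
                      top_frac = 0.01) {
  S <- length(ac1)
  bidx <- ceiling(seq_len(S) / blockSize)
  nB <- max(bidx)
  if (nB > 1 && sum(bidx == nB) < 0.1 * blockSize)
    bidx[bidx == nB] <- nB - 1L
  n1 <- rep(n1, length.out = S); n2 <- rep(n2, length.out = S)
  p1 <- ac1 / n1; p2 <- ac2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- as.numeric(tapply(num, bidx, sum) / tapply(den, bidx, sum))
  out <- data.frame(
    start = as.numeric(tapply(pos, bidx, min)),
    end = as.numeric(tapply(pos, bidx, max)),
    n_snps = as.integer(table(bidx)),
    fst = fst)
  thr <- quantile(fst, 1 - top_frac, na.rm = TRUE, type = 7)
  out$top <- !is.na(fst) & fst >= thr
  out
}

#' Pearson chi-square test on a scan x annotation-category table
#'
#' @param counts contingency table (matrix or table) of SNP counts, scans in
#'   rows and annotation classes in columns; rows/columns with a zero
#'   marginal are dropped with a warning
#' @return list: statistic, df, p_value, table (as used)
#' @importFrom stats chisq.test
#' @export
annotationChisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  keepR <- rowSums(counts) > 0; keepC <- colSums(counts) > 0
  if (!all(keepR) || !all(keepC)) {
    warning("dropping zero-marginal rows/columns")
    counts <- counts[keepR, keepC, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2 x 2 table")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = counts)
}
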