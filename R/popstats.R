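# Windowed diversity and differentiation statistics: pi, Watterson's theta,
# Tajima's D, site frequency spectra (folded/unfolded, scaling, projection),
# LD decay, runs of homozygosity, IBD-like tracts and Hudson's FST with a
# block-jackknife.

.tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# derived/alt allele count and called haploid count per site
.acAn <- function(x) {
  if (is(x, "HaplotypeData")) {
    h <- haplotypeMatrix(x)
    list(ac = rowSums(h), an = rep(ncol(h), nrow(h)))
  } else if (is(x, "GenotypeData")) {
    g <- genotypeMatrix(x)
    list(ac = rowSums(g, na.rm = TRUE), an = 2 * rowSums(!is.na(g)))
  } else stop("need a HaplotypeData or GenotypeData")
}

#' Windowed nucleotide diversity, Watterson's theta and Tajima's D
#'
#' Statistics are computed in non-overlapping windows (0-based half-open bp
#' coordinates). \code{pi} is the mean pairwise difference per accessible bp,
#' \code{theta_w} the per-bp Watterson estimator \code{S / (a1 * bp)};
#' Tajima's D uses the standard variance normalisation and is \code{NA}
#' (undefined, never 0) in windows without segregating sites.
#'
#' @param x a \linkS4class{HaplotypeData} or \linkS4class{GenotypeData}
#' @param window window size in bp
#' @param chromLen chromosome length (default: last site position)
#' @param accessible optional \code{GRanges} accessibility mask; accessible
#'   bases per window are used as the per-bp denominator
#' @return a data.frame with one row per window: chrom, start, end,
#'   accessible_bp, S, pi, theta_w, tajima_d
#' @export
windowDiversity <- function(x, window = 10000, chromLen = NULL,
                            accessible = NULL) {
  pos <- sitePositions(x)
  if (is.unsorted(pos)) stop("site positions must be sorted")
  aa <- .acAn(x)
  n <- if (is(x, "HaplotypeData")) ncol(haplotypeMatrix(x)) else
    2L * ncol(genotypeMatrix(x))
  if (is.null(chromLen)) chromLen <- max(pos)
  brk <- seq(0, ceiling(chromLen / window) * window, by = window)
  widx <- findInterval(pos - 1L, brk)  # 1-based window index, half-open
  nw <- length(brk) - 1L
  chrom <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(x)))[1]
  if (is.na(chrom)) chrom <- "chr1"
  accBp <- rep(window, nw)
  if (!is.null(accessible)) {
    wr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = brk[-length(brk)] + 1L, end = brk[-1]))
    ov <- GenomicRanges::intersect(wr, GenomicRanges::reduce(accessible))
    hit <- GenomicRanges::findOverlaps(wr, ov)
    w <- rep(0, nw)
    iw <- S4Vectors::queryHits(hit)
    ww <- GenomicRanges::width(GenomicRanges::pintersect(
      wr[iw], ov[S4Vectors::subjectHits(hit)]))
    for (k in seq_along(iw)) w[iw[k]] <- w[iw[k]] + ww[k]
    accBp <- w
  }
  # per-site heterozygosity with per-site called count
  an <- aa$an; ac <- aa$ac
  seg <- ac > 0 & ac < an
  hets <- ifelse(an > 1, 2 * ac * (an - ac) / (an * (an - 1)), 0)
  tc <- .tajimaConstants(n)
  S <- tabulate(widx[seg], nbins = nw)
  piSum <- rep(0, nw)
  t <- tapply(hets[seg], factor(widx[seg], levels = seq_len(nw)), sum)
  piSum[!is.na(t)] <- t[!is.na(t)]
  D <- rep(NA_real_, nw)
  ok <- S > 0
  varD <- tc$e1 * S[ok] + tc$e2 * S[ok] * (S[ok] - 1)
  D[ok] <- (piSum[ok] - S[ok] / tc$a1) / sqrt(varD)
  data.frame(chrom = chrom, start = brk[-length(brk)], end = brk[-1],
             accessible_bp = accBp, S = S,
             pi = ifelse(accBp > 0, piSum / accBp, NA_real_),
             theta_w = ifelse(accBp > 0, S / tc$a1 / accBp, NA_real_),
             tajima_d = D)
}

#' Site frequency spectrum from allele counts
#'
#' @param x a \linkS4class{HaplotypeData}, \linkS4class{GenotypeData} or a
#'   numeric vector of per-site derived-allele counts
#' @param n haploid sample size (required when \code{x} is a plain vector)
#' @param folded return the minor-allele-frequency spectrum
#' @return an \linkS4class{SFS1D}; monomorphic classes are included in the
#'   counts but carry no information about segregating variation
#' @export
computeSfs <- function(x, n = NULL, folded = FALSE) {
  if (is.numeric(x)) {
    if (is.null(n)) stop("n is required with a plain count vector")
    ac <- x
  } else {
    aa <- .acAn(x)
    full <- aa$an == max(aa$an)
    ac <- aa$ac[full]
    n <- max(aa$an)
  }
  if (any(ac < 0 | ac > n)) stop("allele counts must lie in [0, n]")
  if (folded) ac <- pmin(ac, n - ac)
  k <- if (folded) floor(n / 2) else n
  counts <- tabulate(ac + 1L, nbins = k + 1L)
  new("SFS1D", counts = as.numeric(counts), n = as.integer(n),
      folded = folded, scaled = FALSE)
}

#' Scale a folded SFS to a flat constant-size expectation
#'
#' Each entry k is multiplied by \code{k * (n - k) / n}; under a
#' constant-size neutral history every scaled entry has expectation theta,
#' so departures from a flat profile expose size changes.
#'
#' @param s a folded \linkS4class{SFS1D}
#' @return the scaled \linkS4class{SFS1D}
#' @export
scaleFoldedSfs <- function(s) {
  stopifnot(is(s, "SFS1D"))
  if (!s@folded) stop("scaling is defined for the folded spectrum")
  k <- seq_along(s@counts) - 1
  out <- s
  out@counts <- s@counts * k * (s@n - k) / s@n
  out@scaled <- TRUE
  out
}

.projWeights <- function(n, m) {
  # W[j+1, k+1] = P(j of m | k of n), hypergeometric
  W <- matrix(0, m + 1, n + 1)
  for (k in 0:n) {
    j <- 0:m
    W[, k + 1] <- exp(lchoose(k, j) + lchoose(n - k, m - j) - lchoose(n, m))
  }
  W[is.na(W)] <- 0
  W
}

#' Project a spectrum to a smaller sample size
#'
#' Expected hypergeometric down-sampling: a site with derived count k of n
#' contributes \code{choose(k,j) choose(n-k,m-j) / choose(n,m)} to class j of
#' the projected spectrum. Total mass is preserved.
#'
#' @param s an unfolded \linkS4class{SFS1D} or a \linkS4class{JointSFS}
#' @param m target haploid size (one value, or two for a JointSFS)
#' @return the projected object
#' @export
projectSfs <- function(s, m) {
  if (is(s, "SFS1D")) {
    if (s@folded) stop("projection operates on the unfolded spectrum")
    if (m > s@n) stop("cannot project up")
    W <- .projWeights(s@n, m)
    return(new("SFS1D", counts = as.numeric(W %*% s@counts),
               n = as.integer(m), folded = FALSE, scaled = FALSE))
  }
  if (is(s, "JointSFS")) {
    m <- rep(m, length.out = 2)
    if (any(m > c(s@n1, s@n2))) stop("cannot project up")
    W1 <- .projWeights(s@n1, m[1]); W2 <- .projWeights(s@n2, m[2])
    cnt <- W1 %*% s@counts %*% t(W2)
    return(jointSfsFromMatrix(cnt, m[1], m[2], folded = s@folded))
  }
  stop("unsupported input")
}

#' Decay of genotype linkage disequilibrium with distance
#'
#' Rogers-Huff genotype correlation r^2 on randomly sampled SNP pairs,
#' binned by physical distance.
#'
#' @param gm a \linkS4class{GenotypeData}
#' @param breaks distance bin edges in bp
#' @param nPairs pairs sampled per bin
#' @param seed integer seed
#' @return data.frame: bin_lo, bin_hi, n_pairs, mean_r2 (NA for empty bins)
#' @importFrom stats cor complete.cases
#' @export
ldDecay <- function(gm, breaks = 10^seq(1, 7, by = 0.5), nPairs = 2000,
                    seed = 1) {
  g <- genotypeMatrix(gm)
  pos <- sitePositions(gm)
  if (nrow(g) < 2) stop("need at least 2 SNPs")
  set.seed(seed)
  nb <- length(breaks) - 1
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    n_pairs = 0L, mean_r2 = NA_real_)
  for (b in seq_len(nb)) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    r2 <- numeric(0)
    for (try in seq_len(nPairs)) {
      i <- sample.int(nrow(g), 1L)
      win <- which(pos >= pos[i] + lo & pos < pos[i] + hi)
      if (!length(win)) next
      j <- win[sample.int(length(win), 1L)]
      cc <- complete.cases(g[i, ], g[j, ])
      if (sum(cc) < 4) next
      v <- suppressWarnings(cor(g[i, cc], g[j, cc]))
      if (!is.na(v)) r2 <- c(r2, v^2)
    }
    out$n_pairs[b] <- length(r2)
    if (length(r2)) out$mean_r2[b] <- mean(r2)
  }
  out
}

#' Runs of homozygosity by a two-state HMM
#'
#' Heterozygote calls per fixed-size emission window are modelled as Poisson
#' with a high (outbred background) or a strongly reduced (ROH) rate; the
#' Viterbi path defines ROH segments and F_ROH is the fraction of the
#' genome in segments of at least \code{minLen} bp.
#'
#' @param gm a \linkS4class{GenotypeData}
#' @param window emission window size (bp)
#' @param transition per-window probability of switching state
#' @param rohRate heterozygosity in ROH as a fraction of the background rate
#' @param minLen minimum segment length contributing to F_ROH (bp)
#' @param chromLen genome span used for windows and the F_ROH denominator
#' @return list with \code{segments} (data.frame sample, chrom, start, end,
#'   length, n_windows) and \code{froh} (named per-sample vector)
#' @export
rohScan <- function(gm, window = 20000, transition = 1e-3, rohRate = 0.05,
                    minLen = 1e5, chromLen = NULL) {
  g <- genotypeMatrix(gm)
  pos <- sitePositions(gm)
  if (is.null(chromLen)) chromLen <- max(pos)
  brk <- seq(0, ceiling(chromLen / window) * window, by = window)
  nw <- length(brk) - 1L
  widx <- findInterval(pos - 1L, brk)
  chrom <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(gm)))[1]
  segs <- list(); froh <- numeric(ncol(g))
  names(froh) <- SummarizedExperiment::colData(gm)$sample
  # background emission rate from the cohort-wide heterozygosity, so that a
  # single unusually homozygous individual is measured against its peers
  hetW <- vapply(seq_len(ncol(g)), function(j)
    tabulate(widx[!is.na(g[, j]) & g[, j] == 1L], nbins = nw), integer(nw))
  lamBg <- max(mean(hetW), 1e-6)
  lamRoh <- max(lamBg * rohRate, 1e-6)
  for (j in seq_len(ncol(g))) {
    het <- hetW[, j]
    if (all(is.na(g[, j]))) { froh[j] <- NA_real_; next }
    # Viterbi over states 1 = background, 2 = ROH
    lp <- cbind(stats::dpois(het, lamBg, log = TRUE),
                stats::dpois(het, lamRoh, log = TRUE))
    lt <- log(matrix(c(1 - transition, transition,
                       transition, 1 - transition), 2, 2))
    V <- matrix(-Inf, nw, 2); ptr <- matrix(1L, nw, 2)
    V[1, ] <- log(c(0.9, 0.1)) + lp[1, ]
    for (w in 2:nw) {
      for (s in 1:2) {
        cand <- V[w - 1, ] + lt[, s]
        ptr[w, s] <- which.max(cand)
        V[w, s] <- max(cand) + lp[w, s]
      }
    }
    path <- integer(nw)
    path[nw] <- which.max(V[nw, ])
    for (w in (nw - 1):1) path[w] <- ptr[w + 1, path[w + 1]]
    r <- rle(path == 2L)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep)) {
      sg <- data.frame(sample = names(froh)[j], chrom = chrom,
                       start = brk[starts[keep]],
                       end = brk[ends[keep] + 1L])
      sg$length <- sg$end - sg$start
      sg$n_windows <- r$lengths[keep]
      segs[[length(segs) + 1L]] <- sg
      froh[j] <- sum(sg$length[sg$length >= minLen]) / chromLen
    } else froh[j] <- 0
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample = character(), chrom = character(), start = numeric(),
               end = numeric(), length = numeric(), n_windows = integer())
  list(segments = segments, froh = froh)
}

#' Identity-by-descent tracts between one pair of individuals
#'
#' A simplified IBD detector: fixed windows are scored by the count of
#' opposite homozygotes (one individual 0, the other 2 -- impossible inside a
#' shared haplotype without error); runs of windows at or below
#' \code{maxOpp} spanning at least \code{minLen} bp are reported.
#'
#' @param gm a \linkS4class{GenotypeData}
#' @param pair indices or sample names of the two individuals
#' @param window window size (bp)
#' @param maxOpp opposite-homozygote count tolerated per window
#' @param minLen minimum tract length (bp)
#' @param chromLen genome span
#' @return data.frame of tracts (chrom, start, end, length, n_windows)
#' @export
ibdSegments <- function(gm, pair, window = 10000, maxOpp = 0,
                        minLen = 3e5, chromLen = NULL) {
  g <- genotypeMatrix(gm)
  if (is.character(pair))
    pair <- match(pair, SummarizedExperiment::colData(gm)$sample)
  a <- g[, pair[1]]; b <- g[, pair[2]]
  shared <- !is.na(a) & !is.na(b)
  if (!any(shared))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric(),
                      n_windows = integer()))
  pos <- sitePositions(gm)
  if (is.null(chromLen)) chromLen <- max(pos)
  brk <- seq(0, ceiling(chromLen / window) * window, by = window)
  nw <- length(brk) - 1L
  opp <- (a == 0L & b == 2L) | (a == 2L & b == 0L)
  oppW <- tabulate(findInterval(pos[shared & opp] - 1L, brk), nbins = nw)
  ok <- oppW <= maxOpp
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths * window >= minLen)
  chrom <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(gm)))[1]
  out <- data.frame(chrom = rep(chrom, length(keep)),
                    start = brk[starts[keep]], end = brk[ends[keep] + 1L])
  out$length <- out$end - out$start
  out$n_windows <- r$lengths[keep]
  out
}

#' Hudson's FST with a block-jackknife
#'
#' Ratio-of-averages estimator: per-site numerator
#' \code{(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)} and denominator
#' \code{p1(1-p2) + p2(1-p1)}, averaged before the ratio. The standard error
#' comes from a delete-one block jackknife over blocks of consecutive SNPs,
#' giving a z-score and two-sided normal p-value.
#'
#' @param ac1,ac2 per-site derived/alt allele counts in each population
#' @param n1,n2 haploid called counts (scalar or per-site vector)
#' @param blockSize SNPs per jackknife block
#' @return list: estimate, se, z, p, n_blocks, per-block FST values
#' @importFrom stats pnorm
#' @export
hudsonFst <- function(ac1, ac2, n1, n2, blockSize = 1000) {
  n1 <- rep(n1, length.out = length(ac1))
  n2 <- rep(n2, length.out = length(ac2))
  ok <- n1 > 1 & n2 > 1
  p1 <- ac1[ok] / n1[ok]; p2 <- ac2[ok] / n2[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1[ok] - 1) - p2 * (1 - p2) / (n2[ok] - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(den) == 0) stop("FST undefined: no variation in either population")
  est <- sum(num) / sum(den)
  S <- length(num)
  bidx <- ceiling(seq_len(S) / blockSize)
  B <- max(bidx)
  bn <- tapply(num, bidx, sum); bd <- tapply(den, bidx, sum)
  blockFst <- as.numeric(bn / bd)
  se <- z <- p <- NA_real_
  if (B > 1) {
    loo <- (sum(num) - bn) / (sum(den) - bd)
    se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
    z <- est / se
    p <- 2 * pnorm(-abs(z))
  }
  list(estimate = est, se = se, z = z, p = p, n_blocks = B,
       block_fst = blockFst)
}

#' Per-population allele counts at shared sites
#'
#' @param x a \linkS4class{HaplotypeData} or \linkS4class{GenotypeData} with
#'   population labels in \code{colData}
#' @return list per population: \code{ac} (derived counts) and \code{an}
#'   (called haploid sizes), aligned on the full site set
#' @export
alleleCountsByPop <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  pops <- unique(cd$population)
  out <- list()
  for (p in pops) {
    sel <- cd$population == p
    if (is(x, "HaplotypeData")) {
      h <- haplotypeMatrix(x)[, sel, drop = FALSE]
      out[[p]] <- list(ac = rowSums(h), an = rep(ncol(h), nrow(h)))
    } else {
      g <- genotypeMatrix(x)[, sel, drop = FALSE]
      out[[p]] <- list(ac = rowSums(g, na.rm = TRUE),
                       an = 2 * rowSums(!is.na(g)))
    }
  }
  out
}
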