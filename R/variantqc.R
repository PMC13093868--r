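# Site, genotype and sample quality control: hard site filters on caller
# annotations, accessibility masking, genotype-quality masking, missingness
# filters (in that order), allele polarization against an outgroup,
# coverage-based molecular sexing, relatedness and LD pruning.

#' Default QC thresholds
#'
#' Sites failing \code{QD < qd_min}, \code{FS > fs_max} or
#' \code{ReadPosRankSum < rprs_min} are removed; genotypes are retained only
#' with \code{GQ > gq_min} (strictly greater); sites with missingness at or
#' above \code{site_miss}, then samples at or above \code{sample_miss}, are
#' dropped.
#'
#' @return a named list of thresholds
#' @export
qcThresholds <- function() {
  list(qd_min = 5, fs_max = 60, rprs_min = -8, gq_min = 20,
       site_miss = 0.05, sample_miss = 0.10)
}

#' Load a VCF and apply site, genotype and sample filters
#'
#' Retains biallelic SNPs inside the accessibility mask that pass the hard
#' annotation filters (absent annotations do not fail a site; they are
#' caller-specific and counted in the report), masks genotypes with
#' \code{GQ <= gq_min}, then drops sites with missingness >=
#' \code{site_miss} and finally samples with missingness >=
#' \code{sample_miss} -- in that order.
#'
#' @param path VCF file
#' @param mask accessibility mask: a \code{GRanges} or a BED file path
#'   (0-based half-open); \code{NULL} keeps all sites
#' @param thresholds list as produced by \code{\link{qcThresholds}}
#' @param populations optional named vector mapping sample id -> population
#' @return a \linkS4class{GenotypeData}; the filtering report is in
#'   \code{metadata()$qc_report}
#' @export
loadFilteredVcf <- function(path, mask = NULL, thresholds = qcThresholds(),
                            populations = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  report <- list(n_input = nrow(vcf))
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(altL)
  alt <- rep(NA_character_, nrow(vcf))
  alt[nalt == 1L] <- as.character(unlist(altL[nalt == 1L]))
  snv <- nalt == 1L & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
    ref != alt
  report$n_not_biallelic_snp <- sum(!snv)

  rr <- SummarizedExperiment::rowRanges(vcf)
  inMask <- rep(TRUE, nrow(vcf))
  if (!is.null(mask)) {
    if (is.character(mask)) mask <- rtracklayer::import(mask, format = "BED")
    inMask <- IRanges::overlapsAny(rr, mask)
  }
  report$n_outside_mask <- sum(snv & !inMask)

  info <- VariantAnnotation::info(vcf)
  getAnn <- function(tag) {
    if (tag %in% colnames(info)) as.numeric(info[[tag]])
    else rep(NA_real_, nrow(vcf))
  }
  qd <- getAnn("QD"); fs <- getAnn("FS")
  rprs <- getAnn("RPRS")
  if (all(is.na(rprs))) rprs <- getAnn("ReadPosRankSum")
  passAnn <- (is.na(qd) | qd >= thresholds$qd_min) &
    (is.na(fs) | fs <= thresholds$fs_max) &
    (is.na(rprs) | rprs >= thresholds$rprs_min)
  report$n_failed_annotation <- sum(snv & inMask & !passAnn)
  report$n_missing_annotation <- sum(snv & inMask &
                                       (is.na(qd) | is.na(fs) | is.na(rprs)))
  keep <- snv & inMask & passAnn

  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  G <- matrix(.gtToDosage(gt), nrow = nrow(gt),
              dimnames = dimnames(gt))
  gq <- NULL
  if ("GQ" %in% names(VariantAnnotation::geno(vcf))) {
    gq <- VariantAnnotation::geno(vcf)$GQ[keep, , drop = FALSE]
    G[!is.na(gq) & gq <= thresholds$gq_min] <- NA_integer_
    report$n_genotypes_masked_gq <-
      sum(!is.na(gq) & gq <= thresholds$gq_min)
  }
  siteMiss <- rowMeans(is.na(G))
  siteOk <- siteMiss < thresholds$site_miss
  report$n_high_missing_sites <- sum(!siteOk)
  G <- G[siteOk, , drop = FALSE]
  if (!is.null(gq)) gq <- gq[siteOk, , drop = FALSE]
  sampMiss <- colMeans(is.na(G))
  sampOk <- sampMiss < thresholds$sample_miss
  report$dropped_samples <- colnames(G)[!sampOk]
  G <- G[, sampOk, drop = FALSE]
  if (!is.null(gq)) gq <- gq[, sampOk, drop = FALSE]
  keepIdx <- which(keep)[siteOk]
  report$n_retained_sites <- nrow(G)
  report$n_retained_samples <- ncol(G)
  if (nrow(G) == 0L) warning("no sites survive the filters")

  aa <- rep(NA_character_, nrow(vcf))
  if ("AA" %in% colnames(info)) {
    aa <- as.character(info$AA)
    aa[aa == "."] <- NA_character_
  }
  si <- data.frame(ref = ref[keepIdx], alt = alt[keepIdx],
                   QD = qd[keepIdx], FS = fs[keepIdx],
                   ReadPosRankSum = rprs[keepIdx],
                   accessible = inMask[keepIdx],
                   ancestral = aa[keepIdx])
  samples <- colnames(G)
  pops <- if (!is.null(populations)) unname(populations[samples]) else
    rep("pop1", length(samples))
  out <- GenotypeData(G, BiocGenerics::start(rr)[keepIdx],
                      chrom = as.character(GenomicRanges::seqnames(rr))[1],
                      samples = samples, population = pops, gq = gq,
                      siteInfo = si)
  S4Vectors::metadata(out)$qc_report <- report
  out
}

#' Polarize genotypes against an outgroup consensus
#'
#' Sites where the outgroup allele matches the reference keep their coding
#' (0 = ancestral); where it matches the alternate the dosages are flipped
#' (0 <-> 2) so that 0 counts ancestral alleles. Sites with a third allele or
#' missing outgroup are flagged unpolarized and excluded from unfolded-SFS
#' analyses. Applying the operation twice with the same outgroup restores
#' the original coding of flipped sites.
#'
#' @param gm a \linkS4class{GenotypeData}
#' @param outgroup per-site outgroup consensus allele (character, NA allowed)
#' @return the recoded \linkS4class{GenotypeData}; polarization counts in
#'   \code{metadata()$polarize_report}
#' @export
polarizeGenotypes <- function(gm, outgroup) {
  rr <- SummarizedExperiment::rowRanges(gm)
  mc <- S4Vectors::mcols(rr)
  stopifnot(length(outgroup) == nrow(gm))
  isRef <- !is.na(outgroup) & outgroup == mc$ref
  isAlt <- !is.na(outgroup) & outgroup == mc$alt
  G <- genotypeMatrix(gm)
  G[isAlt, ] <- 2L - G[isAlt, , drop = FALSE]
  mc$ancestral <- ifelse(isRef, mc$ref, ifelse(isAlt, mc$alt, NA))
  mc$polarized <- isRef | isAlt
  S4Vectors::mcols(rr) <- mc
  out <- gm
  SummarizedExperiment::assay(out, "GT") <- G
  SummarizedExperiment::rowRanges(out) <- rr
  S4Vectors::metadata(out)$polarize_report <- list(
    n_ancestral_ref = sum(isRef), n_ancestral_alt = sum(isAlt),
    n_unpolarized = sum(!isRef & !isAlt))
  out
}

#' Molecular sexing from relative X-chromosome coverage
#'
#' The normalised coverage ratio (mean X depth over genome-wide mean depth)
#' is close to 1 in XX females and 0.5 in X0/XY males. Calls use a midpoint
#' threshold with an ambiguity band.
#'
#' @param depth matrix or data.frame of mean depths, samples x chromosomes
#' @param xChrom name of the X chromosome column
#' @param threshold midpoint ratio separating the sexes
#' @param band half-width of the ambiguity band around the threshold
#' @return data.frame: sample, ratio, sex ("F", "M", "ambiguous" or NA)
#' @export
sexFromDepth <- function(depth, xChrom = "X", threshold = 0.75,
                         band = 0.05) {
  depth <- as.matrix(depth)
  if (!xChrom %in% colnames(depth)) stop("X chromosome column not found")
  genome <- rowMeans(depth)
  ratio <- ifelse(genome > 0, depth[, xChrom] / genome, NA_real_)
  sex <- ifelse(is.na(ratio), NA_character_,
                ifelse(ratio > threshold + band, "F",
                       ifelse(ratio < threshold - band, "M", "ambiguous")))
  data.frame(sample = rownames(depth) %||% seq_len(nrow(depth)),
             ratio = ratio, sex = sex)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise relatedness by the method of moments
#'
#' A PLINK-style estimate of the IBD-sharing coefficients from identity-by-
#' state counts and allele frequencies, reported as
#' \code{PI_HAT = P(IBD=1)/2 + P(IBD=2)}. Pairs above the removal threshold
#' are flagged, suggesting removal of the member with more missing data.
#'
#' @param gm a \linkS4class{GenotypeData}
#' @param threshold PI_HAT above which a pair is flagged
#' @return data.frame: sample1, sample2, pi_hat, flagged, drop
#' @export
pairwiseRelatedness <- function(gm, threshold = 0.5) {
  G <- genotypeMatrix(gm)
  if (nrow(G) < 100) stop("need at least 100 informative sites")
  p <- rowMeans(G, na.rm = TRUE) / 2
  q <- 1 - p
  ids <- SummarizedExperiment::colData(gm)$sample
  miss <- colMeans(is.na(G))
  pairs <- utils::combn(ncol(G), 2)
  out <- data.frame(sample1 = ids[pairs[1, ]], sample2 = ids[pairs[2, ]],
                    pi_hat = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- G[, pairs[1, k]]; b <- G[, pairs[2, k]]
    cc <- !is.na(a) & !is.na(b) & p > 0 & p < 1
    ibs <- 2L - abs(a[cc] - b[cc])
    pp <- p[cc]; qq <- q[cc]
    # expected per-site IBS probabilities given the IBD state
    e0_ibd0 <- sum(2 * pp^2 * qq^2)
    e1_ibd0 <- sum(4 * pp^3 * qq + 4 * pp * qq^3)
    e2_ibd0 <- sum(pp^4 + qq^4 + 4 * pp^2 * qq^2)
    e1_ibd1 <- sum(2 * pp^2 * qq + 2 * pp * qq^2)
    e2_ibd1 <- sum(pp^3 + qq^3 + pp^2 * qq + pp * qq^2)
    S <- sum(cc)
    o0 <- sum(ibs == 0L); o1 <- sum(ibs == 1L); o2 <- sum(ibs == 2L)
    z0 <- if (e0_ibd0 > 0) o0 / e0_ibd0 else 0
    z1 <- if (e1_ibd1 > 0) (o1 - z0 * e1_ibd0) / e1_ibd1 else 0
    z2 <- (o2 - z0 * e2_ibd0 - z1 * e2_ibd1) / S
    z <- pmax(c(z0, z1, z2), 0)
    z <- z / sum(z)
    out$pi_hat[k] <- z[2] / 2 + z[3]
  }
  out$flagged <- out$pi_hat > threshold
  out$drop <- NA_character_
  f <- which(out$flagged)
  if (length(f)) {
    m1 <- miss[match(out$sample1[f], ids)]
    m2 <- miss[match(out$sample2[f], ids)]
    out$drop[f] <- ifelse(m1 >= m2, out$sample1[f], out$sample2[f])
  }
  out
}

.rogersHuffR2 <- function(G) {
  # genotype correlation r^2 with pairwise-complete observations
  suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))^2
}

#' Prune SNPs in linkage disequilibrium
#'
#' A minor-allele-frequency filter is applied first; then, within moving
#' windows of \code{window} SNPs advanced by \code{step}, the later SNP of
#' every pair with Rogers-Huff genotype r^2 above \code{r2_max} is removed
#' (keep-first tie-breaking), iterating until no pair remains or
#' \code{n_iter} passes have run.
#'
#' @param gm a \linkS4class{GenotypeData} with sorted positions
#' @param r2_max r^2 threshold
#' @param window window size in SNPs
#' @param step step size in SNPs
#' @param maf_min minimum minor allele frequency (strictly greater retained)
#' @param n_iter maximum pruning passes
#' @return the pruned \linkS4class{GenotypeData}
#' @export
ldPrune <- function(gm, r2_max = 0.01, window = 500, step = 250,
                    maf_min = 0.01, n_iter = 5) {
  if (is.unsorted(sitePositions(gm))) stop("positions must be sorted")
  G <- genotypeMatrix(gm)
  p <- rowMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(maf > maf_min)
  for (iter in seq_len(n_iter)) {
    removed <- FALSE
    starts <- seq(1, max(1, length(keep)), by = step)
    alive <- rep(TRUE, length(keep))
    for (s in starts) {
      idx <- s:min(s + window - 1, length(keep))
      idx <- idx[alive[idx]]
      if (length(idx) < 2) next
      R2 <- .rogersHuffR2(t(G[keep[idx], , drop = FALSE]))
      for (a in seq_along(idx)) {
        if (!alive[idx[a]]) next
        for (b in seq_along(idx)) {
          if (b <= a || !alive[idx[b]]) next
          if (!is.na(R2[a, b]) && R2[a, b] > r2_max) {
            alive[idx[b]] <- FALSE
            removed <- TRUE
          }
        }
      }
    }
    keep <- keep[alive]
    if (!removed) break
  }
  gm[keep, ]
}
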