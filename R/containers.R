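#' Construct a HaplotypeData object
#'
#' @param hap sites x haplotypes 0/1 matrix
#' @param pos 1-based site positions (bp)
#' @param chrom chromosome name
#' @param samples sample labels, one per diploid individual (haplotype columns
#'   \code{2i-1, 2i} belong to sample \code{i}); defaults to
#'   \code{S1, S2, ...}
#' @param population optional per-sample population labels
#' @param truth optional truth record stored in \code{metadata(x)$truth}
#' @return a \linkS4class{HaplotypeData}
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
#' @export
HaplotypeData <- function(hap, pos, chrom = "chr1", samples = NULL,
                          population = NULL, truth = NULL) {
  hap <- as.matrix(hap)
  dimnames(hap) <- NULL
  storage.mode(hap) <- "integer"
  nh <- ncol(hap)
  if (nh %% 2L != 0L) stop("haplotype count must be even")
  ns <- nh %/% 2L
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ns))
  if (length(samples) != ns) stop("need one sample label per diploid")
  if (anyDuplicated(samples)) stop("sample labels must be unique")
  if (is.null(population)) population <- rep("pop1", ns)
  rr <- GenomicRanges::GRanges(rep(chrom, length(pos)),
                               IRanges::IRanges(as.integer(pos), width = 1L))
  S4Vectors::mcols(rr)$ref <- rep("A", length(pos))
  S4Vectors::mcols(rr)$alt <- rep("T", length(pos))
  S4Vectors::mcols(rr)$ancestral <- rep("A", length(pos))
  cd <- S4Vectors::DataFrame(
    sample = rep(samples, each = 2L),
    population = rep(population, each = 2L),
    hapIndex = rep(1:2, ns),
    row.names = sprintf("%s_%d", rep(samples, each = 2L), rep(1:2, ns)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(HT = hap), rowRanges = rr, colData = cd)
  obj <- new("HaplotypeData", se)
  if (!is.null(truth)) S4Vectors::metadata(obj)$truth <- truth
  obj
}

#' Construct a GenotypeData object
#'
#' @param gt sites x samples matrix with values 0/1/2/NA
#' @param pos 1-based positions
#' @param chrom chromosome name
#' @param samples sample ids
#' @param population per-sample population labels
#' @param gq optional genotype-quality matrix
#' @param siteInfo optional data.frame of per-site columns (ref, alt, QD, FS,
#'   ReadPosRankSum, accessible, ancestral, ...)
#' @return a \linkS4class{GenotypeData}
#' @export
GenotypeData <- function(gt, pos, chrom = "chr1", samples = NULL,
                         population = NULL, gq = NULL, siteInfo = NULL) {
  gt <- as.matrix(gt)
  dimnames(gt) <- NULL
  storage.mode(gt) <- "integer"
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(gt)))
  if (is.null(population)) population <- rep("pop1", ncol(gt))
  rr <- GenomicRanges::GRanges(rep(chrom, length(pos)),
                               IRanges::IRanges(as.integer(pos), width = 1L))
  if (!is.null(siteInfo)) {
    for (nm in colnames(siteInfo)) S4Vectors::mcols(rr)[[nm]] <- siteInfo[[nm]]
  }
  need <- c("ref", "alt", "ancestral")
  for (nm in need) if (is.null(S4Vectors::mcols(rr)[[nm]]))
    S4Vectors::mcols(rr)[[nm]] <- if (nm == "alt") "T" else "A"
  if (is.null(S4Vectors::mcols(rr)$polarized))
    S4Vectors::mcols(rr)$polarized <- !is.na(S4Vectors::mcols(rr)$ancestral)
  assays <- list(GT = gt)
  if (!is.null(gq)) {
    gq <- as.matrix(gq); dimnames(gq) <- NULL
    storage.mode(gq) <- "double"; assays$GQ <- gq
  }
  cd <- S4Vectors::DataFrame(sample = samples, population = population,
                             row.names = samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = rr, colData = cd)
  new("GenotypeData", se)
}

#' @describeIn HaplotypeData-class the sites x haplotypes 0/1 matrix
#' @param x a HaplotypeData
#' @export
haplotypeMatrix <- function(x) SummarizedExperiment::assay(x, "HT")

#' @describeIn GenotypeData-class the sites x samples dosage matrix
#' @param x a GenotypeData
#' @export
genotypeMatrix <- function(x) SummarizedExperiment::assay(x, "GT")

#' 1-based site positions of a genotype or haplotype container
#' @param x a GenotypeData or HaplotypeData
#' @return integer vector of bp positions
#' @importFrom BiocGenerics start
#' @export
sitePositions <- function(x) BiocGenerics::start(SummarizedExperiment::rowRanges(x))

#' Collapse phased haplotypes to diploid genotypes
#'
#' Adjacent haplotype columns are summed into 0/1/2 derived-allele dosages.
#'
#' @param x a \linkS4class{HaplotypeData}
#' @return a \linkS4class{GenotypeData}
#' @export
hapToGenotypes <- function(x) {
  h <- haplotypeMatrix(x)
  ns <- ncol(h) %/% 2L
  gt <- h[, seq(1, 2 * ns, by = 2), drop = FALSE] +
    h[, seq(2, 2 * ns, by = 2), drop = FALSE]
  cd <- SummarizedExperiment::colData(x)
  GenotypeData(gt, sitePositions(x),
               chrom = as.character(GenomicRanges::seqnames(
                 SummarizedExperiment::rowRanges(x)))[1],
               samples = cd$sample[cd$hapIndex == 1L],
               population = cd$population[cd$hapIndex == 1L])
}

#' Truth record attached to simulated data
#' @param x an object produced by one of the simulators
#' @return the truth record (list or data.frame)
#' @export
simTruth <- function(x) S4Vectors::metadata(x)$truth

#' @describeIn SFS1D-class raw counts vector
#' @param x an SFS1D
#' @export
sfsCounts <- function(x) x@counts

#' @describeIn JointSFS-class counts matrix
#' @param x a JointSFS
#' @export
jsfsCounts <- function(x) x@counts

#' @describeIn JointSFS-class logical mask of excluded cells
#' @export
jsfsMask <- function(x) x@mask

#' @describeIn DivergenceModelFit-class named scaled parameter vector
#' @param x a DivergenceModelFit
#' @export
fitParams <- function(x) x@params

#' @describeIn DivergenceModelFit-class composite log-likelihood
#' @export
fitLoglik <- function(x) x@loglik

#' @describeIn DivergenceModelFit-class Akaike information criterion
#' @export
fitAIC <- function(x) x@aic

#' @describeIn DivergenceModelFit-class profiled theta multiplier
#' @export
fitTheta <- function(x) x@theta

#' Construct a JointSFS with masked monomorphic corners
#' @param counts (n1+1) x (n2+1) matrix
#' @param n1,n2 haploid sample sizes
#' @param folded logical
#' @return a \linkS4class{JointSFS}
#' @export
jointSfsFromMatrix <- function(counts, n1, n2, folded = FALSE) {
  mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
  mask[1L, 1L] <- TRUE
  mask[n1 + 1L, n2 + 1L] <- TRUE
  new("JointSFS", counts = unname(as.matrix(counts)), n1 = as.integer(n1),
      n2 = as.integer(n2), folded = folded, mask = mask)
}
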