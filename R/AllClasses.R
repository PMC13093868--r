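#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib demosel, .registration = TRUE
NULL

#' Two-population divergence history with secondary contact and growth
#'
#' Describes a history in which an ancestral population of diploid size
#' \code{N_ref} splits \code{T_split} years ago into two populations of sizes
#' \code{N1} and \code{N2} that change exponentially to \code{b1*N1} and
#' \code{b2*N2} at present, with migration active only during the most recent
#' \code{T_contact} years (secondary contact). \code{m12} is the fraction of
#' population 1 made up of migrants from population 2 each generation.
#'
#' @slot N_ref,N1,N2 diploid effective sizes (individuals)
#' @slot b1,b2 ratio of present size to size at the split
#' @slot T_split,T_contact times in years before present
#' @slot m12,m21 per-generation migrant fractions
#' @slot mu mutation rate per bp per generation
#' @slot r recombination rate per bp per generation
#' @slot gen_per_year generations per year
#' @export
setClass("DemographyConfig", representation(
  N_ref = "numeric", N1 = "numeric", N2 = "numeric",
  b1 = "numeric", b2 = "numeric",
  T_split = "numeric", T_contact = "numeric",
  m12 = "numeric", m21 = "numeric",
  mu = "numeric", r = "numeric", gen_per_year = "numeric"))

setValidity("DemographyConfig", function(object) {
  msg <- NULL
  if (any(c(object@N_ref, object@N1, object@N2, object@b1, object@b2) <= 0))
    msg <- c(msg, "all sizes and growth ratios must be > 0")
  if (object@T_contact < 0 || object@T_split < 0 ||
      object@T_contact > object@T_split)
    msg <- c(msg, "need 0 <= T_contact <= T_split")
  if (any(c(object@m12, object@m21) < 0) || any(c(object@m12, object@m21) >= 1))
    msg <- c(msg, "migrant fractions must be in [0, 1)")
  if (object@gen_per_year <= 0) msg <- c(msg, "gen_per_year must be > 0")
  if (object@mu <= 0) msg <- c(msg, "mu must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @param N_ref,N1,N2,b1,b2,T_split,T_contact,m12,m21,mu,r,gen_per_year see
#'   slot documentation of \linkS4class{DemographyConfig}
#' @return a validated \linkS4class{DemographyConfig}
#' @rdname DemographyConfig-class
#' @export
demographyConfig <- function(N_ref, N1, N2, b1 = 1, b2 = 1,
                             T_split, T_contact = 0, m12 = 0, m21 = 0,
                             mu = 3.5e-9, r = 1e-8, gen_per_year = 11) {
  new("DemographyConfig", N_ref = N_ref, N1 = N1, N2 = N2, b1 = b1, b2 = b2,
      T_split = T_split, T_contact = T_contact, m12 = m12, m21 = m21,
      mu = mu, r = r, gen_per_year = gen_per_year)
}

#' Piecewise-constant single-population size history
#'
#' @slot times epoch start times in generations before present, strictly
#'   increasing from 0
#' @slot sizes diploid effective size in each epoch
#' @slot label population label
#' @export
setClass("PiecewiseNe", representation(
  times = "numeric", sizes = "numeric", label = "character"))

setValidity("PiecewiseNe", function(object) {
  msg <- NULL
  if (length(object@times) == 0L) msg <- c(msg, "need at least one epoch")
  if (length(object@times) != length(object@sizes))
    msg <- c(msg, "times and sizes must have equal length")
  if (length(object@times) && object@times[1] != 0)
    msg <- c(msg, "first epoch must start at time 0")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "epoch times must be strictly increasing")
  if (any(object@sizes <= 0)) msg <- c(msg, "sizes must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @param times,sizes,label see slots of \linkS4class{PiecewiseNe}
#' @rdname PiecewiseNe-class
#' @export
piecewiseNe <- function(times, sizes, label = "pop") {
  new("PiecewiseNe", times = as.numeric(times), sizes = as.numeric(sizes),
      label = label)
}

#' Specification of one simulated 110-kb selection region
#'
#' A region is neutral, or carries a single beneficial mutation of selection
#' coefficient \code{s} that starts from initial frequency \code{f0} (a hard
#' sweep starts from a single copy, \code{f0 = 1/(2N)}; anything larger is a
#' soft sweep from standing variation) and is conditioned to have fixed
#' \code{fix_offset} generations before sampling.
#'
#' @slot length region length in bp
#' @slot sweepClass one of "neutral", "hard", "soft"
#' @slot s selection coefficient
#' @slot f0 initial frequency of the beneficial allele
#' @slot sweep_pos 1-based bp offset of the selected site
#' @slot fix_offset generations between fixation and sampling
#' @export
setClass("SweepRegionSpec", representation(
  length = "numeric", sweepClass = "character", s = "numeric", f0 = "numeric",
  sweep_pos = "numeric", fix_offset = "numeric"))

setValidity("SweepRegionSpec", function(object) {
  msg <- NULL
  if (!object@sweepClass %in% c("neutral", "hard", "soft"))
    msg <- c(msg, "class must be neutral, hard or soft")
  if (object@sweepClass != "neutral" && object@s <= 0)
    msg <- c(msg, "selected regions need s > 0")
  if (object@length < 1e4) msg <- c(msg, "region length must be >= 10 kb")
  if (object@sweep_pos < 1 || object@sweep_pos > object@length)
    msg <- c(msg, "sweep position must lie inside the region")
  if (is.null(msg)) TRUE else msg
})

#' @param length,class,s,f0,sweep_pos,fix_offset see slots of
#'   \linkS4class{SweepRegionSpec}; \code{f0 = NA} resolves to a single copy
#'   (hard) at simulation time
#' @rdname SweepRegionSpec-class
#' @export
sweepRegionSpec <- function(length = 110000, class = "neutral", s = 0,
                            f0 = NA_real_, sweep_pos = NULL,
                            fix_offset = 0) {
  if (is.null(sweep_pos)) sweep_pos <- floor(length / 2)
  new("SweepRegionSpec", length = length, sweepClass = class, s = s, f0 = f0,
      sweep_pos = sweep_pos, fix_offset = fix_offset)
}

#' Phased haplotypes over genomic sites
#'
#' A \linkS4class{RangedSummarizedExperiment} with one assay \code{"HT"}
#' holding a sites x haplotypes 0/1 matrix (0 = ancestral/reference,
#' 1 = derived/alternate), site ranges in \code{rowRanges} and the
#' haplotype-to-sample map in \code{colData}.
#'
#' @import SummarizedExperiment
#' @export
setClass("HaplotypeData", contains = "RangedSummarizedExperiment")

setValidity("HaplotypeData", function(object) {
  msg <- NULL
  if (!"HT" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'HT' is required")
  else {
    v <- SummarizedExperiment::assay(object, "HT")
    if (!all(v %in% c(0L, 1L))) msg <- c(msg, "haplotype values must be 0/1")
    if (ncol(v) %% 2L != 0L) msg <- c(msg, "haplotype count must be even")
  }
  if (!"sample" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry the haplotype -> sample map")
  if (is.null(msg)) TRUE else msg
})

#' Diploid genotypes over genomic sites
#'
#' A \linkS4class{RangedSummarizedExperiment} with assay \code{"GT"} (values
#' 0/1/2 copies of the alternate -- or derived, once polarized -- allele,
#' \code{NA} = missing) and optional assay \code{"GQ"}. Site metadata
#' (\code{ref}, \code{alt}, caller annotations, accessibility, ancestral
#' allele) lives on \code{rowRanges}; sample metadata (id, population, sex)
#' in \code{colData}.
#'
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'GT' is required")
  else {
    v <- SummarizedExperiment::assay(object, "GT")
    if (!all(v %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "genotype values must be 0, 1, 2 or NA")
  }
  if (is.null(msg)) TRUE else msg
})

#' One-dimensional site frequency spectrum
#'
#' @slot counts numeric vector of site counts, indexed 0..n (unfolded) or
#'   0..floor(n/2) (folded)
#' @slot n haploid sample size
#' @slot folded logical
#' @slot scaled logical; TRUE after \code{\link{scaleFoldedSfs}}
#' @export
setClass("SFS1D", representation(
  counts = "numeric", n = "integer", folded = "logical", scaled = "logical"))

setValidity("SFS1D", function(object) {
  msg <- NULL
  want <- if (object@folded) floor(object@n / 2) + 1L else object@n + 1L
  if (length(object@counts) != want)
    msg <- c(msg, sprintf("counts must have length %d", want))
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Joint site frequency spectrum of two populations
#'
#' Matrix of site counts with derived-allele count in population 1 on rows
#' (0..n1) and population 2 on columns (0..n2). The fixed-ancestral corner
#' [0, 0] and fixed-derived corner [n1, n2] carry no information about
#' segregating variation and are masked: excluded from all likelihood and
#' chi-square sums.
#'
#' @slot counts (n1+1) x (n2+1) matrix
#' @slot n1,n2 haploid sample sizes
#' @slot folded logical
#' @slot mask logical matrix, TRUE = excluded cell
#' @export
setClass("JointSFS", representation(
  counts = "matrix", n1 = "integer", n2 = "integer",
  folded = "logical", mask = "matrix"))

setValidity("JointSFS", function(object) {
  msg <- NULL
  d <- dim(object@counts)
  if (d[1] != object@n1 + 1L || d[2] != object@n2 + 1L)
    msg <- c(msg, "counts must be (n1+1) x (n2+1)")
  if (!identical(dim(object@mask), d))
    msg <- c(msg, "mask must match counts in shape")
  if (any(object@counts[!object@mask] < 0))
    msg <- c(msg, "unmasked counts must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Fit of a two-population divergence model to a joint SFS
#'
#' @slot model model id, e.g. "SC+G"
#' @slot params named vector of scaled parameters at the optimum
#' @slot loglik composite Poisson log-likelihood (constant terms dropped)
#' @slot theta profiled theta multiplier
#' @slot k number of optimised parameters (theta included)
#' @slot aic 2k - 2 lnL
#' @slot n1,n2 haploid sizes of the fitted spectrum
#' @slot restarts data.frame of per-restart best log-likelihoods
#' @slot boundary TRUE when most restarts ended on a parameter bound
#' @slot control engine settings used (grid points, time step)
#' @export
setClass("DivergenceModelFit", representation(
  model = "character", params = "numeric", loglik = "numeric",
  theta = "numeric", k = "integer", aic = "numeric",
  n1 = "integer", n2 = "integer", restarts = "data.frame",
  boundary = "logical", control = "list"))

setMethod("show", "DemographyConfig", function(object) {
  cat("DemographyConfig: split", object@T_split, "ya; contact",
      object@T_contact, "ya\n")
  cat(sprintf("  N_ref=%g N1=%g (b1=%g) N2=%g (b2=%g)\n",
              object@N_ref, object@N1, object@b1, object@N2, object@b2))
  cat(sprintf("  m12=%g m21=%g mu=%g r=%g gen/yr=%g\n", object@m12,
              object@m21, object@mu, object@r, object@gen_per_year))
})

setMethod("show", "PiecewiseNe", function(object) {
  cat("PiecewiseNe [", object@label, "]:", length(object@times), "epochs\n")
  print(data.frame(t_start_gen = object@times, Ne = object@sizes))
})

setMethod("show", "SFS1D", function(object) {
  cat(sprintf("SFS1D: n=%d %s%s, %g segregating sites\n", object@n,
              if (object@folded) "folded" else "unfolded",
              if (object@scaled) " (scaled)" else "",
              sum(object@counts[-1])))
})

setMethod("show", "JointSFS", function(object) {
  cat(sprintf("JointSFS: n1=%d n2=%d, %g sites in unmasked cells\n",
              object@n1, object@n2, sum(object@counts[!object@mask])))
})

setMethod("show", "DivergenceModelFit", function(object) {
  cat(sprintf("DivergenceModelFit [%s]: lnL=%.3f  AIC=%.3f  k=%d  theta=%.4g\n",
              object@model, object@loglik, object@aic, object@k,
              object@theta))
  print(round(object@params, 5))
})
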