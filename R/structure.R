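# Population structure: PCA on pruned genotypes, joint site frequency
# spectra, and a permutation test of panmixia comparing the observed jSFS
# with the mean spectrum under scrambled population labels.

#' PCA of a genotype matrix
#'
#' Patterson-style PCA: genotypes are centred by twice the allele frequency
#' and scaled by \code{sqrt(p(1-p))}; missing genotypes are mean-imputed.
#' Intended for LD-pruned, MAF-filtered matrices.
#'
#' @param gm a \linkS4class{GenotypeData}
#' @param nComponents number of axes to return
#' @return list: \code{scores} (samples x components),
#'   \code{explained} (variance fractions, all axes)
#' @export
pcaGenotypes <- function(gm, nComponents = 10) {
  G <- genotypeMatrix(gm)
  p <- rowMeans(G, na.rm = TRUE) / 2
  use <- p > 0 & p < 1
  G <- G[use, , drop = FALSE]; p <- p[use]
  X <- (G - 2 * p) / sqrt(p * (1 - p))
  X[is.na(X)] <- 0
  M <- t(X)  # samples x sites
  nc <- min(nComponents, nrow(M) - 1L, ncol(M))
  if (nc < nComponents)
    warning("fewer samples than requested components; returning ", nc)
  sv <- svd(scale(M, center = TRUE, scale = FALSE), nu = nc, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(nc)], nc, nc)
  rownames(scores) <- SummarizedExperiment::colData(gm)$sample
  colnames(scores) <- sprintf("PC%d", seq_len(nc))
  list(scores = scores, explained = sv$d^2 / sum(sv$d^2))
}

.jsfsTabulate <- function(ac1, ac2, n1, n2) {
  idx <- ac1 * (n2 + 1) + ac2 + 1
  matrix(tabulate(idx, nbins = (n1 + 1) * (n2 + 1)),
         nrow = n1 + 1, byrow = TRUE)
}

#' Joint site frequency spectrum of two populations
#'
#' Built from sites that are fully called in every sample (no missing data)
#' and, in unfolded mode, successfully polarized. The fixed corners are
#' masked. Optional hypergeometric projection to smaller sample sizes.
#'
#' @param x a \linkS4class{HaplotypeData} or \linkS4class{GenotypeData}
#'   carrying exactly two population labels
#' @param projection \code{NULL}, or haploid target sizes (length 1 or 2)
#' @param pops optional: the two population labels, in order
#' @return a \linkS4class{JointSFS}
#' @export
jointSfs <- function(x, projection = NULL, pops = NULL) {
  cd <- SummarizedExperiment::colData(x)
  if (is.null(pops)) pops <- unique(cd$population)
  if (length(pops) != 2) stop("need exactly two populations")
  if (is(x, "GenotypeData")) {
    G <- genotypeMatrix(x)
    full <- rowSums(is.na(G)) == 0L
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(x))
    pol <- if (!is.null(mc$polarized)) mc$polarized else rep(TRUE, nrow(G))
    use <- full & pol
    ac1 <- rowSums(G[use, cd$population == pops[1], drop = FALSE])
    ac2 <- rowSums(G[use, cd$population == pops[2], drop = FALSE])
    n1 <- 2L * sum(cd$population == pops[1])
    n2 <- 2L * sum(cd$population == pops[2])
  } else {
    H <- haplotypeMatrix(x)
    ac1 <- rowSums(H[, cd$population == pops[1], drop = FALSE])
    ac2 <- rowSums(H[, cd$population == pops[2], drop = FALSE])
    n1 <- sum(cd$population == pops[1])
    n2 <- sum(cd$population == pops[2])
  }
  out <- jointSfsFromMatrix(.jsfsTabulate(ac1, ac2, n1, n2), n1, n2)
  if (!is.null(projection)) out <- projectSfs(out, projection)
  out
}

.chisqPooled <- function(O, E, mask, poolBelow = 1) {
  keep <- !mask & E > 0
  o <- O[keep]; e <- E[keep]
  small <- e < poolBelow
  if (any(small)) {
    o <- c(o[!small], sum(o[small]))
    e <- c(e[!small], sum(e[small]))
  }
  ok <- e > 0
  sum((o[ok] - e[ok])^2 / e[ok])
}

#' Permutation test of panmixia on the joint SFS
#'
#' The observed jSFS between two labelled groups is compared with the mean
#' jSFS over random permutations of the sample labels (the expectation under
#' panmixia) using a chi-square statistic over unmasked cells; cells with
#' expectation below 1 are pooled. Significance is empirical: the fraction
#' of permuted spectra whose own chi-square against the permutation mean
#' reaches the observed one.
#'
#' @param x a \linkS4class{HaplotypeData} or \linkS4class{GenotypeData} with
#'   two population labels
#' @param n_perm number of permutations
#' @param seed integer seed
#' @param folded compare label-flip-symmetrised spectra
#' @param pops optional: the two population labels, in order
#' @return list: p_value, chisq_obs, null (permutation chi-squares),
#'   n1, n2
#' @export
panmixiaTest <- function(x, n_perm = 1000, seed = 1, folded = FALSE,
                         pops = NULL) {
  cd <- SummarizedExperiment::colData(x)
  if (is.null(pops)) pops <- unique(cd$population)
  if (length(pops) != 2) stop("need exactly two populations")
  if (is(x, "HaplotypeData")) {
    H <- haplotypeMatrix(x)
    sampOf <- cd$sample[cd$hapIndex == 1L]
    popOf <- cd$population[cd$hapIndex == 1L]
  } else {
    G <- genotypeMatrix(x)
    G <- G[rowSums(is.na(G)) == 0L, , drop = FALSE]
    H <- matrix(0L, nrow(G), 2 * ncol(G))
    # split dosages into pseudo-haplotypes (only counts matter here)
    H[, seq(1, ncol(H), 2)] <- (G >= 1L) + 0L
    H[, seq(2, ncol(H), 2)] <- (G == 2L) + 0L
    sampOf <- cd$sample
    popOf <- cd$population
  }
  ns <- length(sampOf)
  if (min(table(popOf)) < 2) stop("each group needs at least 2 samples")
  n1s <- sum(popOf == pops[1])
  n1 <- 2L * n1s; n2 <- 2L * (ns - n1s)
  set.seed(seed)
  sampleCols <- function(sIdx) sort(c(2L * sIdx - 1L, 2L * sIdx))
  jsfsOf <- function(sIdx) {
    c1 <- sampleCols(sIdx)
    ac1 <- rowSums(H[, c1, drop = FALSE])
    acT <- rowSums(H)
    .jsfsTabulate(ac1, acT - ac1, n1, n2)
  }
  obs <- jsfsOf(which(popOf == pops[1]))
  perms <- vector("list", n_perm)
  for (b in seq_len(n_perm))
    perms[[b]] <- jsfsOf(sample.int(ns, n1s))
  E <- Reduce(`+`, perms) / n_perm
  mask <- matrix(FALSE, n1 + 1, n2 + 1)
  mask[1, 1] <- TRUE; mask[n1 + 1, n2 + 1] <- TRUE
  foldIt <- function(M) M + M[rev(seq_len(nrow(M))), rev(seq_len(ncol(M)))]
  if (folded) {
    obs <- foldIt(obs); E <- foldIt(E) }
  chisqObs <- .chisqPooled(obs, E, mask)
  null <- vapply(perms, function(P) {
    if (folded) P <- foldIt(P)
    .chisqPooled(P, E, mask)
  }, numeric(1))
  p <- (1 + sum(null >= chisqObs)) / (1 + n_perm)
  list(p_value = p, chisq_obs = chisqObs, null = null, n1 = n1, n2 = n2)
}
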