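# Demography-aware selective-sweep classification. A 110-kb region is split
# into 11 subwindows of 10 kb and summarised by 12 statistics per subwindow
# (row-normalised across subwindows so only the spatial shape remains);
# a gradient-boosted-tree classifier trained on simulated regions assigns
# one of five classes: hard, hard-linked, soft, soft-linked, neutral.

.sweepClasses <- function() c("hard", "hardLinked", "soft", "softLinked",
                              "neutral")

.momentStats <- function(v) {
  # variance, skew, kurtosis; zeros when degenerate
  if (length(v) < 2) return(c(0, 0, 0))
  m <- mean(v); d <- v - m
  m2 <- mean(d^2)
  if (m2 < 1e-12) return(c(0, 0, 0))
  c(stats::var(v), mean(d^3) / m2^1.5, mean(d^4) / m2^2)
}

.subwindowR2 <- function(G, maxSnps = 120) {
  if (nrow(G) > maxSnps) G <- G[round(seq(1, nrow(G), length.out = maxSnps)), ,
                                drop = FALSE]
  if (nrow(G) < 2) return(NULL)
  suppressWarnings(stats::cor(t(G)))^2
}

.omegaMax <- function(R2) {
  if (is.null(R2)) return(0)
  S <- nrow(R2)
  if (S < 4) return(0)
  R2[is.na(R2)] <- 0
  diag(R2) <- 0
  # prefix sums: within-left, total row sums, hence between-side sums, all
  # split points in one O(S^2) pass
  sL <- rowSums(R2 * lower.tri(R2))       # sum over j < i of r2[i, j]
  wLeft <- cumsum(sL)                     # sum over i < j <= l
  Tall <- wLeft[S]
  Rcum <- cumsum(rowSums(R2))
  best <- 0
  for (l in 2:(S - 2)) {
    between <- Rcum[l] - 2 * wLeft[l]
    wl <- wLeft[l]
    wr <- Tall - wl - between
    nw <- choose(l, 2) + choose(S - l, 2)
    if (nw == 0 || between <= 0) next
    om <- ((wl + wr) / nw) / (between / (l * (S - l)))
    if (is.finite(om) && om > best) best <- om
  }
  best
}

#' Feature vector of a 110-kb region for sweep classification
#'
#' Splits the region into \code{nSub} equal subwindows and computes, per
#' subwindow on diploid genotypes: nucleotide diversity (pi), Watterson's
#' theta, Tajima's D, the variance/skew/kurtosis of the pairwise Manhattan
#' genotype distance g_kl, the number of distinct multilocus genotypes, the
#' Garud genotype statistics J1, J12 and J2/J1, the mean pairwise genotype
#' r^2 (Zns) and the Kim-Nielsen omega maximum. Each statistic's values are
#' then normalised to sum to 1 across subwindows; rows with (near-)zero sum
#' are encoded as the uniform profile and flagged degenerate.
#'
#' @param x a \linkS4class{HaplotypeData} or \linkS4class{GenotypeData}
#'   spanning the region
#' @param regionLength region length in bp
#' @param nSub number of subwindows
#' @return a 12 x nSub matrix (statistics in rows) with attribute
#'   \code{degenerate} (logical per row)
#' @export
featureVector <- function(x, regionLength = 110000, nSub = 11) {
  if (is(x, "HaplotypeData")) {
    h <- haplotypeMatrix(x)
    ns <- ncol(h) %/% 2L
    G <- h[, seq(1, 2 * ns, 2), drop = FALSE] +
      h[, seq(2, 2 * ns, 2), drop = FALSE]
    pos <- sitePositions(x)
  } else {
    G <- genotypeMatrix(x)
    pos <- sitePositions(x)
  }
  w <- regionLength / nSub
  stats <- c("pi", "theta_w", "tajima_d", "var_gkl", "skew_gkl", "kurt_gkl",
             "n_diplos", "J1", "J12", "J2J1", "Zns", "omega_max")
  M <- matrix(0, length(stats), nSub, dimnames = list(stats, NULL))
  n <- 2L * ncol(G)
  tc <- .tajimaConstants(n)
  for (k in seq_len(nSub)) {
    inW <- pos > (k - 1) * w & pos <= k * w
    Gk <- G[inW, , drop = FALSE]
    S <- 0L
    if (nrow(Gk)) {
      ac <- rowSums(Gk); an <- n
      seg <- ac > 0 & ac < an
      S <- sum(seg)
      piSum <- sum(2 * ac[seg] * (an - ac[seg]) / (an * (an - 1)))
      M["pi", k] <- piSum
      M["theta_w", k] <- S / tc$a1
      if (S > 0)
        M["tajima_d", k] <- (piSum - S / tc$a1) /
          sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
      gd <- as.numeric(stats::dist(t(Gk), method = "manhattan"))
      M[c("var_gkl", "skew_gkl", "kurt_gkl"), k] <- .momentStats(gd)
      gh <- garudH(Gk)
      M["n_diplos", k] <- gh$n_distinct
      M["J1", k] <- gh$H1
      M["J12", k] <- gh$H12
      M["J2J1", k] <- ifelse(is.na(gh$H2H1), 0, gh$H2H1)
      R2 <- .subwindowR2(Gk[rowSums(Gk) > 0 & rowSums(Gk) < n, , drop = FALSE])
      if (!is.null(R2)) {
        off <- R2[upper.tri(R2)]
        M["Zns", k] <- mean(off, na.rm = TRUE)
        M["omega_max", k] <- .omegaMax(R2)
      }
    }
  }
  M[!is.finite(M)] <- 0
  rs <- rowSums(M)
  degenerate <- abs(rs) < 1e-9
  out <- M / ifelse(abs(rs) < 1e-9, 1, rs)
  out[degenerate, ] <- 1 / nSub
  attr(out, "degenerate") <- degenerate
  out
}

#' Simulate a labelled training/testing set for sweep classification
#'
#' For each of the five classes, regions are simulated under the supplied
#' demography: neutral draws, and hard/soft sweeps conditioned on fixation
#' with the selected site in the central subwindow (focal classes) or in a
#' flanking subwindow ("linked" classes). Selection is drawn uniformly on
#' the population-scaled strength alpha = 2*Ne*s, the initial frequency of
#' soft sweeps uniformly up to \code{f0_max}, and the time since fixation
#' uniformly up to \code{age_frac * 4 Ne} generations.
#'
#' @param ne a \linkS4class{PiecewiseNe} (the population's history)
#' @param n_train,n_test regions per class
#' @param n diploid sample size per region
#' @param seed integer seed
#' @param alphaRange range of alpha = 2*Ne*s
#' @param f0_max maximum initial frequency for soft sweeps
#' @param age_frac maximum fixation age as a fraction of 4*Ne generations
#' @param forward_N forward-population size passed to the simulator
#' @param regionLength,nSub feature-vector geometry
#' @return list: \code{train}, \code{test} (each with matrix \code{X} of
#'   flattened feature vectors and factor \code{y}), and \code{truth}
#' @export
buildTrainingSet <- function(ne, n_train = 2000, n_test = 1000, n = 20,
                             seed = 1, alphaRange = c(100, 1000),
                             f0_max = 0.2, age_frac = 0.05,
                             forward_N = 500L, regionLength = 110000,
                             nSub = 11) {
  classes <- .sweepClasses()
  Ne0 <- ne@sizes[1]
  w <- regionLength / nSub
  central <- c(floor(nSub / 2) * w + 1, (floor(nSub / 2) + 1) * w)
  set.seed(seed)
  makeOne <- function(cls, rseed) {
    alpha <- runif(1, alphaRange[1], alphaRange[2])
    s <- alpha / (2 * Ne0)
    age <- runif(1, 0, age_frac * 4 * Ne0)
    linked <- grepl("Linked", cls)
    posn <- if (cls == "neutral") central[1]
      else if (!linked) runif(1, central[1], central[2])
      else {
        repeat {
          p <- runif(1, 1, regionLength)
          if (p < central[1] || p > central[2]) break
        }
        p
      }
    base <- sub("Linked", "", cls)
    f0 <- if (base == "soft") runif(1, 1 / (2 * forward_N) + 1e-6, f0_max)
          else NA_real_
    spec <- sweepRegionSpec(length = regionLength,
                            class = if (base == "neutral") "neutral" else base,
                            s = if (base == "neutral") 0 else s,
                            f0 = f0, sweep_pos = round(posn),
                            fix_offset = age)
    reg <- simulateSweepRegion(spec, ne, n, seed = rseed,
                               forward_N = forward_N)
    tr <- simTruth(reg)
    list(x = as.numeric(featureVector(reg, regionLength, nSub)),
         truth = data.frame(class = cls, s = spec@s,
                            f0 = ifelse(is.na(f0), 1 / (2 * forward_N), f0),
                            sweep_pos = spec@sweep_pos, age = age,
                            rescale = tr$rescale, seed = rseed))
  }
  build <- function(nPer, offset) {
    X <- matrix(NA_real_, nPer * length(classes), 12 * nSub)
    y <- character(nrow(X)); truths <- vector("list", nrow(X))
    i <- 0L
    for (cls in classes) {
      for (r in seq_len(nPer)) {
        i <- i + 1L
        one <- makeOne(cls, rseed = offset + i)
        X[i, ] <- one$x
        y[i] <- cls
        truths[[i]] <- one$truth
      }
    }
    list(X = X, y = factor(y, levels = classes),
         truth = do.call(rbind, truths))
  }
  train <- build(n_train, offset = seed * 1e6)
  test <- build(n_test, offset = seed * 1e6 + 5e5)
  list(train = train, test = test,
       truth = rbind(cbind(train$truth, set = "train"),
                     cbind(test$truth, set = "test")))
}

#' Train the sweep classifier and report held-out performance
#'
#' Gradient-boosted trees (xgboost, multiclass softprob) over the flattened
#' 12 x 11 feature vectors.
#'
#' @param train list with \code{X} and factor \code{y} (all five classes
#'   present)
#' @param test held-out set of the same form
#' @param seed integer seed
#' @param nrounds boosting rounds
#' @param max_depth,eta tree depth and learning rate
#' @return list: model, classes, confusion (rows = truth, cols = call),
#'   accuracy
#' @export
trainSweepClassifier <- function(train, test = NULL, seed = 1,
                                 nrounds = 200, max_depth = 4, eta = 0.1) {
  classes <- .sweepClasses()
  if (!all(classes %in% levels(droplevels(train$y))) ||
      any(table(train$y) == 0))
    stop("every class must be present in the training set")
  yNum <- as.integer(train$y) - 1L
  dtrain <- xgboost::xgb.DMatrix(train$X, label = yNum)
  set.seed(seed)
  model <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(classes),
                  max_depth = max_depth, eta = eta, subsample = 0.8,
                  colsample_bytree = 0.8, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  out <- list(model = model, classes = classes)
  if (!is.null(test)) {
    pr <- predictSweepClass(out, test$X)
    call <- factor(classes[max.col(pr)], levels = classes)
    out$confusion <- table(truth = test$y, call = call)
    out$accuracy <- mean(call == test$y)
  }
  out
}

#' Class probabilities for feature vectors
#'
#' @param classifier result of \code{\link{trainSweepClassifier}}
#' @param X matrix of flattened feature vectors (one row per window)
#' @return matrix windows x classes of probabilities
#' @export
predictSweepClass <- function(classifier, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  p <- predict(classifier$model, xgboost::xgb.DMatrix(X))
  m <- if (is.matrix(p)) p
       else matrix(p, ncol = length(classifier$classes), byrow = TRUE)
  colnames(m) <- classifier$classes
  m
}

#' Consensus sweep calls over replicated classifier runs
#'
#' Implements the replicated-run protocol: a window is retained as a sweep
#' call when its probability of being neutral is at most
#' \code{p_neutral_max} in at least a fraction \code{consensus} of the runs;
#' the consensus label is the modal non-neutral class among the qualifying
#' runs, with ties resolved toward the less specific "linked" variant.
#'
#' @param probList list of per-run probability matrices (windows x classes,
#'   as from \code{\link{predictSweepClass}})
#' @param p_neutral_max neutrality-probability cutoff per run
#' @param consensus fraction of runs that must qualify
#' @return data.frame: window, n_runs, n_qualifying, retained, consensus
#'   (label), plus mean per-class probabilities
#' @export
classifyWindows <- function(probList, p_neutral_max = 0.01,
                            consensus = 0.5) {
  classes <- colnames(probList[[1]])
  nR <- length(probList)
  if (nR < 10) warning("fewer than 10 runs: consensus is provisional")
  nW <- nrow(probList[[1]])
  pneut <- sapply(probList, function(P) P[, "neutral"])
  if (is.null(dim(pneut))) pneut <- matrix(pneut, nrow = nW)
  qual <- pneut <= p_neutral_max
  nQual <- rowSums(qual)
  retained <- nQual >= consensus * nR
  lab <- character(nW)
  linkedPref <- grepl("Linked", classes)
  for (wdx in seq_len(nW)) {
    if (nQual[wdx] == 0) { lab[wdx] <- "neutral"; next }
    calls <- vapply(which(qual[wdx, ]), function(r) {
      P <- probList[[r]][wdx, ]
      nn <- P[setdiff(classes, "neutral")]
      names(nn)[which.max(nn)]
    }, character(1))
    tab <- table(calls)
    winners <- names(tab)[tab == max(tab)]
    lab[wdx] <- if (length(winners) == 1) winners else {
      lk <- winners[grepl("Linked", winners)]
      if (length(lk)) lk[1] else winners[1]
    }
  }
  meanP <- Reduce(`+`, probList) / nR
  colnames(meanP) <- paste0("mean_p_", classes)
  data.frame(window = seq_len(nW), n_runs = nR, n_qualifying = nQual,
             retained = retained, consensus = lab, meanP)
}
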