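# Two-population divergence-model inference on the joint SFS.
#
# Eight nested models built from four gene-flow histories -- strict
# isolation (SI), continuous migration (IM), ancient migration (AM),
# secondary contact (SC) -- each with or without exponential size change
# (+G). Expected spectra come from a Wright-Fisher diffusion solved on a
# boundary-refined grid and extrapolated over three grid sizes; the
# composite Poisson likelihood profiles the theta multiplier analytically.
# Scaled units: sizes nu = N/N_ref, times in 2*N_ref generations, migration
# M = 2*N_ref*m, ancestral-state misorientation O.

.modelParamNames <- function(model) {
  base <- sub("\\+G$", "", model)
  g <- grepl("\\+G$", model)
  p <- switch(base,
    SI = c("nu1", "nu2", "Ts", "O"),
    IM = c("nu1", "nu2", "m12", "m21", "Ts", "O"),
    AM = c("nu1", "nu2", "m12", "m21", "Ts", "Tc", "O"),
    SC = c("nu1", "nu2", "m12", "m21", "Ts", "Tc", "O"),
    stop("unknown model: ", model))
  if (g) p <- c(p, "b1", "b2")
  p
}

#' The eight divergence models
#' @return character vector of model identifiers
#' @export
divergenceModels <- function() {
  c("SI", "SI+G", "IM", "IM+G", "AM", "AM+G", "SC", "SC+G")
}

.paramBounds <- function(names) {
  lo <- c(nu1 = 0.01, nu2 = 0.01, b1 = 0.01, b2 = 0.01,
          m12 = 0, m21 = 0, Ts = 1e-6, Tc = 0, O = 0.01)
  hi <- c(nu1 = 100, nu2 = 100, b1 = 100, b2 = 100,
          m12 = 50, m21 = 50, Ts = 10, Tc = 10, O = 0.99)
  list(lo = lo[names], hi = hi[names])
}

.diffGrid <- function(pts, crwd = 5) {
  u <- seq(-1, 1, length.out = pts)
  g <- 1 / (1 + exp(-crwd * u))
  (g - g[1]) / (g[length(g)] - g[1])
}

.cellWidths <- function(xx) {
  G <- length(xx)
  c((xx[2] - xx[1]) / 2,
    (xx[3:G] - xx[1:(G - 2)]) / 2,
    (xx[G] - xx[G - 1]) / 2)
}

.phi1Dto2D <- function(phi, xx) {
  cw <- .cellWidths(xx)
  diag(phi / cw)
}

# expected spectrum on one grid, unit theta, before misorientation
.expectedJsfsGrid <- function(model, par, n1, n2, pts, dt) {
  xx <- .diffGrid(pts)
  phi1 <- 1 / pmax(xx, xx[2])
  Phi <- .phi1Dto2D(phi1, xx)
  base <- sub("\\+G$", "", model)
  b1 <- if ("b1" %in% names(par)) par[["b1"]] else 1
  b2 <- if ("b2" %in% names(par)) par[["b2"]] else 1
  Ts <- par[["Ts"]]
  Tc <- if ("Tc" %in% names(par)) min(par[["Tc"]], Ts) else 0
  m12 <- if ("m12" %in% names(par)) par[["m12"]] else 0
  m21 <- if ("m21" %in% names(par)) par[["m21"]] else 0
  g1 <- log(b1) / Ts; g2 <- log(b2) / Ts
  nu1 <- par[["nu1"]]; nu2 <- par[["nu2"]]
  # epoch 1: from the split, duration Ts - Tc
  d1 <- Ts - Tc
  mE1 <- if (base == "IM") c(m12, m21) else if (base == "AM") c(m12, m21)
         else c(0, 0)
  if (base == "IM") { d1 <- Ts; d2 <- 0 } else d2 <- Tc
  mE2 <- if (base == "SC") c(m12, m21) else c(0, 0)
  if (base == "SI") { mE1 <- c(0, 0); d1 <- Ts; d2 <- 0 }
  if (d1 > 0)
    Phi <- .integrate_two_pop(Phi, xx, d1, nu1, g1, nu2, g2,
                              mE1[1], mE1[2], 1, dt)
  if (d2 > 0)
    Phi <- .integrate_two_pop(Phi, xx, d2, nu1 * exp(g1 * d1), g1,
                              nu2 * exp(g2 * d1), g2,
                              mE2[1], mE2[2], 1, dt)
  .sample_sfs2d(Phi, xx, n1, n2)
}

#' Expected joint SFS under a divergence model
#'
#' Solves the two-population diffusion at each of the grid sizes in
#' \code{pts} and extrapolates the sampled spectrum to zero grid spacing
#' (quadratic Richardson extrapolation when three grids are given). The
#' result is in units of theta = 1; multiply by a theta to match data, or
#' let \code{\link{compositeLoglik}} profile it. Misorientation \code{O}
#' mixes the spectrum with its reversal.
#'
#' @param model one of \code{divergenceModels()}
#' @param par named parameter vector (see \code{.modelParamNames});
#'   times \code{Ts}/\code{Tc} in 2 N_ref generations
#' @param n1,n2 haploid sample sizes
#' @param pts diffusion grid sizes; default \code{max(n1,n2) + c(0,10,20)}
#' @param dt target diffusion time step
#' @return a \linkS4class{JointSFS} (expected, unit theta)
#' @export
expectedJsfs <- function(model, par, n1, n2, pts = NULL, dt = 0.004) {
  model <- match.arg(model, divergenceModels())
  need <- .modelParamNames(model)
  if (!all(need %in% names(par)))
    stop("missing parameters: ", paste(setdiff(need, names(par)), collapse = ", "))
  par <- par[need]
  b <- .paramBounds(need)
  if (any(par < b$lo - 1e-12) || any(par > b$hi + 1e-12))
    stop("parameters out of bounds")
  if ("Tc" %in% need && par[["Tc"]] > par[["Ts"]] + 1e-12)
    stop("Tc cannot exceed Ts")
  if (is.null(pts)) pts <- max(n1, n2) + c(0, 10, 20)
  mats <- lapply(pts, function(p) .expectedJsfsGrid(model, par, n1, n2, p, dt))
  if (length(pts) == 1) {
    S <- mats[[1]]
  } else {
    hs <- vapply(pts, function(p) .diffGrid(p)[2], numeric(1))
    w <- vapply(seq_along(hs), function(g) {
      prod((0 - hs[-g]) / (hs[g] - hs[-g]))
    }, numeric(1))
    S <- Reduce(`+`, Map(`*`, mats, w))
  }
  S <- pmax(S, 0)
  out <- jointSfsFromMatrix(S, n1, n2)
  if ("O" %in% need) out <- applyMisorientation(out, par[["O"]])
  out
}

#' Mix a spectrum with its reversal to model ancestral-state error
#'
#' With probability \code{1 - O} a site's ancestral state is mis-assigned,
#' which reverses both axes of the unfolded spectrum:
#' \code{O * M + (1 - O) * rev(M)}.
#'
#' @param M a \linkS4class{JointSFS} (unfolded) or plain matrix
#' @param O probability that the assigned orientation is correct
#' @return object of the same type
#' @export
applyMisorientation <- function(M, O) {
  revM <- function(x) x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))), drop = FALSE]
  if (is(M, "JointSFS")) {
    if (M@folded) stop("misorientation applies to unfolded spectra")
    out <- M
    out@counts <- O * M@counts + (1 - O) * revM(M@counts)
    return(out)
  }
  O * M + (1 - O) * revM(M)
}

#' Composite Poisson log-likelihood with profiled theta
#'
#' Over unmasked cells, \code{theta_hat = sum(obs) / sum(model)} maximises
#' the Poisson composite likelihood analytically, and
#' \code{lnL = sum(obs * log(theta_hat * model) - theta_hat * model)}
#' (constant terms in the data are dropped). Model cells below 1e-12 are
#' floored.
#'
#' @param obs observed \linkS4class{JointSFS}
#' @param model expected \linkS4class{JointSFS} at unit theta
#' @return list: loglik, theta
#' @export
compositeLoglik <- function(obs, model) {
  stopifnot(is(obs, "JointSFS"), is(model, "JointSFS"))
  if (!all(dim(obs@counts) == dim(model@counts)))
    stop("spectra differ in shape")
  keep <- !(obs@mask | model@mask)
  o <- obs@counts[keep]
  m <- pmax(model@counts[keep], 1e-12)
  th <- sum(o) / sum(m)
  list(loglik = sum(o * log(th * m) - th * m), theta = th)
}

.toOpt <- function(par, lo, hi, names) {
  # log for positive parameters, logit for O; Tc as a fraction of Ts
  x <- par
  if ("Tc" %in% names) x[["Tc"]] <- par[["Tc"]] / par[["Ts"]]
  out <- numeric(length(names))
  for (i in seq_along(names)) {
    nm <- names[i]
    out[i] <- if (nm == "O") stats::qlogis((x[[nm]] - lo[nm]) / (hi[nm] - lo[nm]))
    else if (nm == "Tc") stats::qlogis(min(max(x[[nm]], 1e-6), 1 - 1e-6))
    else log(max(x[[nm]], 1e-8))
  }
  out
}

.fromOpt <- function(x, lo, hi, names) {
  par <- numeric(length(names)); names(par) <- names
  for (i in seq_along(names)) {
    nm <- names[i]
    par[nm] <- if (nm == "O") lo[nm] + (hi[nm] - lo[nm]) * stats::plogis(x[i])
    else if (nm == "Tc") stats::plogis(x[i])     # fraction, resolved below
    else exp(x[i])
  }
  if ("Tc" %in% names) par["Tc"] <- par["Tc"] * par["Ts"]
  par
}

#' Fit one divergence model to an observed joint SFS
#'
#' Global-then-local optimisation: random starts drawn log-uniformly within
#' the bounds are screened on a single coarse diffusion grid, the best are
#' refined by Nelder-Mead and the winner polished by Nelder-Mead plus
#' bounded BFGS on the full three-grid engine. Every restart's achieved
#' log-likelihood is kept for convergence assessment.
#'
#' @param obs observed \linkS4class{JointSFS} (projected, corners masked)
#' @param model one of \code{divergenceModels()}
#' @param n_restarts random starts
#' @param seed integer seed
#' @param pts engine grid sizes (default \code{max(n1,n2) + c(0,10,20)})
#' @param dt diffusion time step
#' @param refine how many screened starts get Nelder-Mead refinement
#' @param starts optional matrix/list of extra (named) starting points
#' @param cycles polish cycles on the full grid
#' @param use_bfgs follow each polish cycle with a bounded BFGS step
#' @param tries repeat the whole procedure this many times with shifted
#'   internal seeds and keep the best likelihood (a cheap insurance against
#'   an unlucky draw of random starts)
#' @param scheme \code{"cascade"} (default) first fits the nested simpler
#'   models -- strict isolation, then the constant-size variant -- and uses
#'   their optima as warm starts, mirroring the usual hot/cold fitting
#'   protocol for these model suites; \code{"random"} uses random starts
#'   only
#' @return a \linkS4class{DivergenceModelFit}
#' @importFrom stats optim runif
#' @export
fitModel <- function(obs, model, n_restarts = 20, seed = 1, pts = NULL,
                     dt = 0.004, refine = 4, starts = NULL,
                     scheme = c("cascade", "random"), cycles = 2,
                     use_bfgs = TRUE, tries = 1) {
  scheme <- match.arg(scheme)
  if (tries > 1) {
    fits <- lapply(seq_len(tries) - 1L, function(k)
      fitModel(obs, model, n_restarts = n_restarts, seed = seed + 7919L * k,
               pts = pts, dt = dt, refine = refine, starts = starts,
               scheme = scheme, cycles = cycles, use_bfgs = use_bfgs,
               tries = 1))
    return(fits[[which.max(vapply(fits, function(f) f@loglik, numeric(1)))]])
  }
  if (scheme == "cascade") {
    casc <- .cascadeStarts(obs, model, seed = seed, pts = pts, dt = dt)
    starts <- c(starts, casc)
  }
  stopifnot(is(obs, "JointSFS"))
  model <- match.arg(model, divergenceModels())
  names <- .modelParamNames(model)
  b <- .paramBounds(names)
  n1 <- obs@n1; n2 <- obs@n2
  if (is.null(pts)) pts <- max(n1, n2) + c(0, 10, 20)
  ptsCoarse <- pts[1]
  # flat objective: grid solves, Richardson extrapolation, misorientation
  # and the profiled Poisson log-likelihood on plain matrices
  keep <- !obs@mask
  oCnt <- obs@counts[keep]
  oSum <- sum(oCnt)
  hasO <- "O" %in% names
  exWeights <- function(p) {
    if (length(p) == 1) return(1)
    hs <- vapply(p, function(q) .diffGrid(q)[2], numeric(1))
    vapply(seq_along(hs), function(g)
      prod((0 - hs[-g]) / (hs[g] - hs[-g])), numeric(1))
  }
  wFull <- exWeights(pts); wCoarse <- exWeights(ptsCoarse)
  negll <- function(x, usePts) {
    par <- .fromOpt(x, b$lo, b$hi, names)
    if (any(!is.finite(par)) ||
        any(par < b$lo - 1e-12) || any(par > b$hi + 1e-12) ||
        ("Tc" %in% names && par[["Tc"]] > par[["Ts"]])) return(1e12)
    wts <- if (identical(usePts, pts)) wFull else wCoarse
    S <- 0
    for (g in seq_along(usePts))
      S <- S + wts[g] * .expectedJsfsGrid(model, par, n1, n2, usePts[g], dt)
    if (hasO) {
      O <- par[["O"]]
      S <- O * S + (1 - O) * S[rev(seq_len(nrow(S))), rev(seq_len(ncol(S)))]
    }
    m <- pmax(S[keep], 1e-12)
    th <- oSum / sum(m)
    -sum(oCnt * log(th * m) - th * m)
  }
  set.seed(seed)
  sLo <- pmax(b$lo, c(nu1 = 0.01, nu2 = 0.01, b1 = 0.01, b2 = 0.01,
                      m12 = 1e-3, m21 = 1e-3, Ts = 1e-3, Tc = 1e-6,
                      O = 0.01)[names])
  randStart <- function() {
    par <- exp(runif(length(names), log(sLo), log(pmin(b$hi, 60))))
    names(par) <- names
    par["O"] <- runif(1, 0.5, 0.99)
    if ("Tc" %in% names) par["Tc"] <- par["Ts"] * runif(1, 0.05, 0.95)
    par["Ts"] <- exp(runif(1, log(0.01), log(5)))
    if ("Tc" %in% names) par["Tc"] <- min(par["Tc"], par["Ts"] * 0.95)
    par
  }
  cand <- lapply(seq_len(n_restarts), function(i) randStart())
  nProvided <- 0L
  if (!is.null(starts)) {
    if (is.numeric(starts)) starts <- list(starts)
    provided <- Filter(Negate(is.null), lapply(starts, function(s) {
      s <- s[names]
      if (anyNA(s)) return(NULL)
      pmin(pmax(s, b$lo + 1e-9), b$hi - 1e-9)
    }))
    nProvided <- length(provided)
    cand <- c(provided, cand)
  }
  X <- lapply(cand, .toOpt, lo = b$lo, hi = b$hi, names = names)
  scr <- vapply(X, negll, numeric(1), usePts = ptsCoarse)
  ord <- order(scr)
  # every provided (purposeful) start is refined -- screening by raw
  # coarse-grid value would discard ladder starts that need a few
  # Nelder-Mead steps before their basin shows -- plus the best-screened
  # of the random restarts
  refIdx <- union(seq_len(nProvided),
                  ord[seq_len(min(max(refine, 1), length(ord)))])
  if (length(ord) <= 4) refIdx <- seq_along(ord)
  restartLL <- rep(NA_real_, length(cand))
  restartPar <- vector("list", length(cand))
  for (i in refIdx) {
    o1 <- optim(X[[i]], negll, usePts = ptsCoarse, method = "Nelder-Mead",
                control = list(maxit = 350, reltol = 1e-9))
    restartLL[i] <- -o1$value
    restartPar[[i]] <- o1$par
    X[[i]] <- o1$par
  }
  nRef <- length(refIdx)
  # polish the best few refined candidates on the full engine before the
  # final cycles: the coarse ranking can near-tie distinct basins
  topIdx <- refIdx[order(-restartLL[refIdx])]
  topIdx <- topIdx[seq_len(min(3, length(topIdx)))]
  if (length(topIdx) > 1) {
    pol <- lapply(topIdx, function(i)
      optim(X[[i]], negll, usePts = pts, method = "Nelder-Mead",
            control = list(maxit = 300, reltol = 1e-9)))
    polishFrom <- pol[[which.min(vapply(pol, `[[`, numeric(1), "value"))]]$par
  } else {
    polishFrom <- X[[topIdx[1]]]
  }
  best <- list(par = polishFrom, value = Inf)
  cur <- polishFrom
  for (cycle in seq_len(cycles)) {
    o2 <- optim(cur, negll, usePts = pts, method = "Nelder-Mead",
                control = list(maxit = 400, reltol = 1e-10))
    step <- o2
    if (use_bfgs) {
      o3 <- try(optim(o2$par, negll, usePts = pts, method = "BFGS",
                      control = list(maxit = 30)), silent = TRUE)
      if (!inherits(o3, "try-error") && o3$value < o2$value) step <- o3
    }
    if (step$value < best$value) best <- step
    cur <- step$par
  }
  par <- .fromOpt(best$par, b$lo, b$hi, names)
  mfit <- expectedJsfs(model, par, n1, n2, pts = pts, dt = dt)
  cl <- compositeLoglik(obs, mfit)
  # boundary diagnostic on the refined restarts
  onBound <- vapply(which(!is.na(restartLL)), function(i) {
    p <- .fromOpt(restartPar[[i]], b$lo, b$hi, names)
    any(p / b$lo < 1.05 | p / b$hi > 0.95, na.rm = TRUE)
  }, logical(1))
  k <- length(names) + 1L  # theta is profiled but optimised
  new("DivergenceModelFit", model = model, params = par,
      loglik = cl$loglik, theta = cl$theta, k = k,
      aic = 2 * k - 2 * cl$loglik, n1 = n1, n2 = n2,
      restarts = data.frame(loglik = restartLL),
      boundary = length(onBound) > 0 && mean(onBound) > 0.5,
      control = list(pts = pts, dt = dt, seed = seed,
                     obs_sum = sum(obs@counts)))
}

# Warm starts for the optimiser from fits of the nested simpler models:
# strict isolation first (a well-behaved 4-parameter problem), then the
# constant-size variant of the requested gene-flow history.
.cascadeStarts <- function(obs, model, seed, pts, dt) {
  base <- sub("\\+G$", "", model)
  hasG <- grepl("\\+G$", model)
  if (model == "SI") return(list())
  fitSI <- fitModel(obs, "SI", n_restarts = 10, seed = seed + 101,
                    pts = pts, dt = dt, refine = 3, scheme = "random")
  pSI <- fitSI@params
  addMig <- function(p, m, tcf) {
    c(p[c("nu1", "nu2")], m12 = unname(m), m21 = unname(m),
      Ts = unname(p["Ts"]), Tc = unname(p["Ts"] * tcf), O = unname(p["O"]))
  }
  # growth starts from a constant-size fit must rescale the split sizes so
  # the geometric-mean size (which sets the coalescent intensity) is kept:
  # nu' = nu / sqrt(b)
  bGrid <- function(p) lapply(c(1, 0.1, 0.3, 10), function(b) {
    q <- p
    q[["nu1"]] <- p[["nu1"]] / sqrt(b)
    q[["nu2"]] <- p[["nu2"]] / sqrt(b)
    c(q, b1 = b, b2 = b)
  })
  if (base == "SI") return(bGrid(pSI))
  # systematic coverage of the weakly identified contact-time fraction
  mids <- c(lapply(c(0.15, 0.35, 0.6, 0.85), function(f) addMig(pSI, 0.25, f)),
            lapply(c(0.15, 0.35, 0.6, 0.85), function(f) addMig(pSI, 2, f)))
  if (!hasG) return(mids)
  fitBase <- fitModel(obs, base, n_restarts = 8, seed = seed + 202,
                      pts = pts, dt = dt, refine = 3, scheme = "random",
                      starts = mids)
  gs <- bGrid(fitBase@params)
  if ("Tc" %in% names(fitBase@params)) {
    gs <- c(gs, lapply(gs, function(q) {
      q[["Tc"]] <- 0.35 * q[["Ts"]]
      q
    }))
  }
  gs
}

#' Fit all eight divergence models as a tournament
#'
#' Shares the warm-start cascade: strict isolation is fitted first, the
#' three gene-flow histories start from it, and each growth variant starts
#' from its constant-size fit -- each with its own random restarts on top.
#'
#' @param obs observed \linkS4class{JointSFS}
#' @param n_restarts random restarts per model
#' @param seed integer seed
#' @param pts,dt engine settings (see \code{\link{expectedJsfs}})
#' @param refine starts refined per model
#' @param cycles,use_bfgs polish settings passed to \code{\link{fitModel}}
#' @param ref_starts optional named list of per-model parameter vectors
#'   (e.g. fits of the same models to a reference spectrum) added as warm
#'   starts -- the continuation strategy used for bootstrap-style replicate
#'   refits
#' @return named list of \linkS4class{DivergenceModelFit}
#' @export
fitAllModels <- function(obs, n_restarts = 8, seed = 1, pts = NULL,
                         dt = 0.004, refine = 3, cycles = 1,
                         use_bfgs = FALSE, ref_starts = NULL) {
  # embed a parent model's optimum into a child model's parameter space
  embed <- function(p, parent, child) {
    pb <- sub("\\+G$", "", parent); cb <- sub("\\+G$", "", child)
    need <- .modelParamNames(child)
    out <- stats::setNames(rep(NA_real_, length(need)), need)
    shared <- intersect(names(p), need)
    out[shared] <- p[shared]
    if ("b1" %in% need && is.na(out["b1"])) out[c("b1", "b2")] <- 1
    if ("m12" %in% need && is.na(out["m12"])) out[c("m12", "m21")] <- 1e-3
    if ("Tc" %in% need && is.na(out["Tc"])) {
      out["Tc"] <- if (pb == "IM" && cb == "SC") 0.999 * out[["Ts"]]
        else if (pb == "IM" && cb == "AM") 1e-3 * out[["Ts"]]
        else 0.5 * out[["Ts"]]
    }
    out
  }
  parents <- list("SI" = character(0),
                  "IM" = "SI", "AM" = c("SI", "IM"), "SC" = c("SI", "IM"),
                  "SI+G" = "SI", "IM+G" = c("IM", "SI+G"),
                  "AM+G" = c("AM", "IM+G", "SI+G"),
                  "SC+G" = c("SC", "IM+G", "SI+G"))
  order <- c("SI", "IM", "AM", "SC", "SI+G", "IM+G", "AM+G", "SC+G")
  fits <- list()
  fitOne <- function(model, extraSeed, starts, nr = n_restarts,
                     thorough = FALSE) {
    fitModel(obs, model, n_restarts = nr, seed = seed + extraSeed,
             pts = pts, dt = dt, refine = if (thorough) max(refine, 2) else refine,
             scheme = "random",
             cycles = if (thorough) 2 else cycles,
             use_bfgs = use_bfgs, starts = starts)
  }
  for (i in seq_along(order)) {
    model <- order[i]
    starts <- lapply(parents[[model]], function(pm)
      embed(fits[[pm]]@params, pm, model))
    if (grepl("\\+G$", model)) {
      pB <- fits[[sub("\\+G$", "", model)]]@params
      starts <- c(starts, lapply(c(0.1, 0.3), function(b) {
        q <- pB
        q[["nu1"]] <- pB[["nu1"]] / sqrt(b)
        q[["nu2"]] <- pB[["nu2"]] / sqrt(b)
        if ("Tc" %in% names(q)) q[["Tc"]] <- 0.35 * q[["Ts"]]
        c(q, b1 = b, b2 = b)
      }))
    }
    if (!is.null(ref_starts[[model]]))
      starts <- c(list(ref_starts[[model]]), starts)
    fits[[model]] <- fitOne(model, i, starts)
  }
  # Two correction passes, interleaved until stable:
  # (a) nesting rescue -- a child model can never score below a nested
  #     parent; where the optimiser fell short the child is refit from the
  #     embedded parent optimum;
  # (b) competition polish -- models near the current leader get a thorough
  #     warm-started refit from the leader's embedded solution, so the
  #     final ranking reflects the models rather than uneven optimiser luck.
  for (pass in 1:3) {
    changed <- FALSE
    for (model in order) {
      for (pm in parents[[model]]) {
        if (fits[[model]]@loglik < fits[[pm]]@loglik - 1e-6) {
          ref <- fitOne(model, 50 + 10 * pass + match(model, order),
                        list(embed(fits[[pm]]@params, pm, model),
                             fits[[model]]@params), nr = 1, thorough = TRUE)
          if (ref@loglik > fits[[model]]@loglik) {
            fits[[model]] <- ref
            changed <- TRUE
          }
        }
      }
    }
    aics <- vapply(fits, function(f) f@aic, numeric(1))
    bestM <- names(which.min(aics))
    nearest <- names(sort(aics))[seq_len(min(5, length(aics)))]
    for (model in order) {
      if (model == bestM ||
          (aics[model] - min(aics) >= 60 && !model %in% nearest)) next
      ref <- fitOne(model, 100 + 10 * pass + match(model, order),
                    list(embed(fits[[bestM]]@params, bestM, model),
                         fits[[model]]@params), nr = 0, thorough = TRUE)
      if (ref@loglik > fits[[model]]@loglik + 1e-9) {
        fits[[model]] <- ref
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fits[divergenceModels()]
}

#' Rank model fits by AIC and retain the supported set
#'
#' @param fits list of \linkS4class{DivergenceModelFit} on the same spectrum
#' @param daicMax retention threshold on the AIC difference to the best
#' @return data.frame: model, k, loglik, AIC, dAIC, retained -- ordered by
#'   AIC
#' @export
modelSelection <- function(fits, daicMax = 10) {
  if (length(fits) < 1) stop("need at least one fit")
  sums <- vapply(fits, function(f) f@control$obs_sum, numeric(1))
  ns <- vapply(fits, function(f) c(f@n1, f@n2), numeric(2))
  if (length(unique(sums)) > 1 || any(apply(ns, 1, function(v) length(unique(v)) > 1)))
    stop("fits are not on the same observed spectrum")
  tab <- data.frame(
    model = vapply(fits, function(f) f@model, character(1)),
    k = vapply(fits, function(f) f@k, integer(1)),
    loglik = vapply(fits, function(f) f@loglik, numeric(1)),
    AIC = vapply(fits, function(f) f@aic, numeric(1)))
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  tab$retained <- tab$dAIC < daicMax
  rownames(tab) <- NULL
  tab
}

#' Convert a fitted model to natural units
#'
#' \code{N_ref = theta / (4 mu L)}; population sizes \code{Ne_i = nu_i *
#' N_ref}; times \code{T * 2 N_ref} generations converted to years with the
#' generation time; migrant fractions \code{m_ij = M_ij / (2 N_ref)} and
#' effective migrant numbers \code{Ne_i * m_ij}.
#'
#' @param fit a \linkS4class{DivergenceModelFit}
#' @param mu mutation rate per bp per generation
#' @param L analysed sequence length (bp)
#' @param gen_time generation time in years
#' @return named list of natural-unit estimates
#' @export
toNaturalUnits <- function(fit, mu = 3.5e-9, L = 39359290, gen_time = 0.09) {
  th <- fit@theta
  if (!is.finite(th) || th <= 0) stop("non-positive theta")
  p <- fit@params
  Nref <- th / (4 * mu * L)
  out <- list(N_ref = Nref,
              N1 = unname(p["nu1"] * Nref),
              N2 = unname(p["nu2"] * Nref),
              b1 = unname(if ("b1" %in% names(p)) p["b1"] else 1),
              b2 = unname(if ("b2" %in% names(p)) p["b2"] else 1),
              T_split = unname(p["Ts"] * 2 * Nref * gen_time),
              T_contact = unname(if ("Tc" %in% names(p))
                p["Tc"] * 2 * Nref * gen_time else 0))
  m12 <- unname(if ("m12" %in% names(p)) p["m12"] / (2 * Nref) else 0)
  m21 <- unname(if ("m21" %in% names(p)) p["m21"] / (2 * Nref) else 0)
  out$m12 <- m12; out$m21 <- m21
  out$nb_m12 <- out$N1 * m12
  out$nb_m21 <- out$N2 * m21
  out$O <- unname(if ("O" %in% names(p)) p["O"] else NA_real_)
  out
}

#' Scaled model parameters from natural-unit values
#'
#' The inverse of \code{\link{toNaturalUnits}}: translates sizes in
#' individuals, times in years and effective migrant numbers into the
#' scaled units the diffusion engine uses, together with the implied theta.
#'
#' @param N_ref,N1,N2 diploid sizes (individuals)
#' @param T_split,T_contact years before present
#' @param nb_m12,nb_m21 effective migrants per generation (Ne_i * m_ij)
#' @param b1,b2 present/split size ratios
#' @param O orientation probability
#' @param mu,L,gen_time as in \code{\link{toNaturalUnits}}
#' @return list: \code{par} (named scaled vector) and \code{theta}
#' @export
scaledFromNatural <- function(N_ref, N1, N2, T_split, T_contact,
                              nb_m12, nb_m21, b1 = 1, b2 = 1, O = 0.98,
                              mu = 3.5e-9, L = 39359290, gen_time = 0.09) {
  theta <- 4 * mu * L * N_ref
  par <- c(nu1 = N1 / N_ref, nu2 = N2 / N_ref,
           m12 = (nb_m12 / N1) * 2 * N_ref,
           m21 = (nb_m21 / N2) * 2 * N_ref,
           Ts = T_split / (2 * N_ref * gen_time),
           Tc = T_contact / (2 * N_ref * gen_time),
           O = O, b1 = b1, b2 = b2)
  list(par = par, theta = theta)
}

#' Parametric bootstrap confidence intervals for a model fit
#'
#' Unmasked cells of the observed spectrum are resampled as independent
#' Poisson draws and the model refitted to each replicate (warm-started at
#' the point estimate plus a reduced set of random restarts); percentile
#' intervals are reported per parameter and for theta.
#'
#' @param obs observed \linkS4class{JointSFS}
#' @param fit the \linkS4class{DivergenceModelFit} being assessed
#' @param n_boot bootstrap replicates (below 50 triggers a wide-CI warning)
#' @param seed integer seed
#' @param n_restarts random restarts per replicate (on top of the warm start)
#' @param level confidence level
#' @param method \code{"se"} (normal interval around the point estimate
#'   using the bootstrap standard error; default) or \code{"percentile"}
#' @return matrix with one row per parameter (and theta), columns
#'   \code{lower}, \code{upper}; attribute \code{wide_ci_flag}
#' @importFrom stats rpois quantile qnorm
#' @export
bootstrapCi <- function(obs, fit, n_boot = 100, seed = 1, n_restarts = 2,
                        level = 0.95, method = c("se", "percentile")) {
  method <- match.arg(method)
  wide <- n_boot < 50
  if (wide) warning("n_boot < 50: intervals will be unstable (wide-CI flag)")
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, length(fit@params) + 1,
                  dimnames = list(NULL, c(names(fit@params), "theta")))
  for (bi in seq_len(n_boot)) {
    rep <- obs
    keep <- !obs@mask
    rep@counts[keep] <- rpois(sum(keep), obs@counts[keep])
    f <- fitModel(rep, fit@model, n_restarts = n_restarts,
                  seed = seed + bi, pts = fit@control$pts,
                  dt = fit@control$dt, refine = 2,
                  starts = list(fit@params))
    draws[bi, ] <- c(f@params, f@theta)
  }
  a <- (1 - level) / 2
  if (method == "percentile") {
    ci <- t(apply(draws, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  } else {
    centre <- c(fit@params, theta = fit@theta)
    se <- apply(draws, 2, sd, na.rm = TRUE)
    ci <- cbind(centre - qnorm(1 - a) * se, centre + qnorm(1 - a) * se)
  }
  colnames(ci) <- c("lower", "upper")
  attr(ci, "wide_ci_flag") <- wide
  attr(ci, "draws") <- draws
  ci
}
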