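# Divergence-model engine, likelihood, fitting, unit conversion.

test_that("model nesting identities hold exactly in the engine", {
  par <- c(nu1 = 2, nu2 = 0.5, m12 = 1, m21 = 2, Ts = 0.3, Tc = 0.12,
           O = 0.98, b1 = 1, b2 = 1)
  pts <- c(20, 30, 40)
  relDev <- function(a, b) {
    k <- !jsfsMask(b) & jsfsCounts(b) > 1e-8
    max(abs(jsfsCounts(a)[k] / jsfsCounts(b)[k] - 1))
  }
  # SC with Tc -> Ts equals IM
  pSC <- par; pSC["Tc"] <- pSC["Ts"]
  expect_lt(relDev(
    expectedJsfs("SC", pSC[c("nu1","nu2","m12","m21","Ts","Tc","O")], 20, 20, pts),
    expectedJsfs("IM", par[c("nu1","nu2","m12","m21","Ts","O")], 20, 20, pts)),
    0.02)
  # IM with m = 0 equals SI
  p0 <- par; p0["m12"] <- 0; p0["m21"] <- 0
  expect_lt(relDev(
    expectedJsfs("IM", p0[c("nu1","nu2","m12","m21","Ts","O")], 20, 20, pts),
    expectedJsfs("SI", par[c("nu1","nu2","Ts","O")], 20, 20, pts)),
    0.02)
  # growth with b = 1 equals the constant-size variant
  expect_lt(relDev(
    expectedJsfs("SC+G", par, 20, 20, pts),
    expectedJsfs("SC", par[c("nu1","nu2","m12","m21","Ts","Tc","O")], 20, 20, pts)),
    0.02)
})

test_that("the expected spectrum is label-equivariant", {
  par <- c(nu1 = 3, nu2 = 0.4, m12 = 2, m21 = 0.5, Ts = 0.3, Tc = 0.1,
           O = 0.95, b1 = 0.3, b2 = 2)
  sw <- c(nu1 = 0.4, nu2 = 3, m12 = 0.5, m21 = 2, Ts = 0.3, Tc = 0.1,
          O = 0.95, b1 = 2, b2 = 0.3)
  A <- jsfsCounts(expectedJsfs("SC+G", par, 16, 16, pts = c(20, 30)))
  B <- jsfsCounts(expectedJsfs("SC+G", sw, 16, 16, pts = c(20, 30)))
  # the alternating-direction solver orders its sweeps, so equivariance is
  # exact only up to the splitting error of the scheme
  k <- A > 1e-6
  expect_lt(max(abs(A[k] / t(B)[k] - 1)), 0.02)
})

test_that("misorientation mixing is linear, symmetric and involutive", {
  M <- matrix(runif(25), 5, 5)
  js <- jointSfsFromMatrix(M, 4, 4)
  expect_equal(jsfsCounts(applyMisorientation(js, 1)), M)
  half <- jsfsCounts(applyMisorientation(js, 0.5))
  expect_equal(half, half[5:1, 5:1], tolerance = 1e-12)   # rev-invariant
  revM <- M[5:1, 5:1]
  expect_equal(revM[5:1, 5:1], M)                         # involution
  expect_error(applyMisorientation(
    new("JointSFS", counts = M, n1 = 4L, n2 = 4L, folded = TRUE,
        mask = matrix(FALSE, 5, 5)), 0.9), "unfolded")
})

test_that("composite likelihood profiles theta and matches a hand Poisson sum", {
  obs <- jointSfsFromMatrix(matrix(c(0, 4, 2, 6), 2), 1, 1)
  mod <- jointSfsFromMatrix(matrix(c(9, 2, 1, 9), 2), 1, 1)
  cl <- compositeLoglik(obs, mod)
  # unmasked cells are [1,0] and [0,1]: obs (4, 2), model (2, 1)
  thHand <- (4 + 2) / (2 + 1)
  lnlHand <- 4 * log(thHand * 2) - thHand * 2 + 2 * log(thHand * 1) - thHand * 1
  expect_equal(cl$theta, thHand, tolerance = 1e-12)
  expect_equal(cl$loglik, lnlHand, tolerance = 1e-12)
  # doubling the observation doubles the profiled theta
  obs2 <- obs; obs2@counts <- obs2@counts * 2
  expect_equal(compositeLoglik(obs2, mod)$theta, 2 * thHand,
               tolerance = 1e-12)
  # saturated case: obs = theta * model gives the zero-deviance optimum
  obs3 <- mod; obs3@counts <- mod@counts * 7
  cl3 <- compositeLoglik(obs3, mod)
  o <- obs3@counts[!obs3@mask]
  expect_equal(cl3$loglik, sum(o * log(o) - o), tolerance = 1e-9)
})

test_that("AIC ranking and the retention rule are arithmetic", {
  mk <- function(model, k, lnl) new("DivergenceModelFit", model = model,
    params = c(nu1 = 1), loglik = lnl, theta = 1, k = as.integer(k),
    aic = 2 * k - 2 * lnl, n1 = 4L, n2 = 4L,
    restarts = data.frame(loglik = lnl), boundary = FALSE,
    control = list(obs_sum = 10))
  tab <- modelSelection(list(mk("SI", 5, -100), mk("SC", 7, -100)))
  expect_equal(tab$AIC, c(210, 214))
  expect_equal(tab$model[1], "SI")
  expect_equal(tab$dAIC, c(0, 4))
  expect_true(all(tab$retained))
  tab2 <- modelSelection(list(mk("SI", 5, -100), mk("SC", 7, -110)))
  expect_false(tab2$retained[2])       # dAIC = 24
  one <- modelSelection(list(mk("SI", 5, -1)))
  expect_true(one$retained)
  bad <- mk("SC", 7, -100); bad@control$obs_sum <- 99
  expect_error(modelSelection(list(mk("SI", 5, -100), bad)), "same observed")
})

test_that("natural-unit conversion round-trips the published point estimates", {
  sc <- scaledFromNatural(142332.55, 865159.02, 292460.51, 12056.12,
                          4431.69, 25.10, 4.80, b1 = 0.10, b2 = 0.31)
  # theta = 4 mu L N_ref ~ 7.84e4
  expect_equal(sc$theta, 78429.5, tolerance = 1e-4)
  fit <- new("DivergenceModelFit", model = "SC+G", params = sc$par,
             loglik = 0, theta = sc$theta, k = 10L, aic = 0, n1 = 40L,
             n2 = 40L, restarts = data.frame(), boundary = FALSE,
             control = list())
  nat <- toNaturalUnits(fit)
  expect_equal(nat$N_ref, 142332.55, tolerance = 1e-9)
  expect_equal(nat$N1, 865159.02, tolerance = 1e-9)
  expect_equal(nat$T_split, 12056.12, tolerance = 1e-9)
  expect_equal(nat$T_contact, 4431.69, tolerance = 1e-9)
  expect_equal(nat$nb_m12, 25.10, tolerance = 1e-9)
  expect_equal(nat$nb_m21, 4.80, tolerance = 1e-9)
  # implied per-generation migrant fraction ~ 2.9e-5, i.e. ~0.003%
  expect_equal(nat$m12, 25.10 / 865159.02, tolerance = 1e-12)
  expect_equal(round(100 * nat$m12, 3), 0.003)
  # zero scaled time converts to zero years
  p0 <- sc$par; p0["Ts"] <- 1e-6; p0["Tc"] <- 0
  fit0 <- fit; fit0@params <- p0
  expect_lt(toNaturalUnits(fit0)$T_split, 1)
  expect_equal(toNaturalUnits(fit0)$T_contact, 0)
})

test_that("fitting a model to its own expected spectrum recovers the truth", {
  truth <- c(nu1 = 3, nu2 = 0.6, Ts = 0.35, O = 0.95)
  pts <- c(20, 30, 40)
  obs <- expectedJsfs("SI", truth, 20, 20, pts = pts)
  obs@counts <- obs@counts * 5e4
  fit <- fitModel(obs, "SI", n_restarts = 8, seed = 3, pts = pts,
                  refine = 3, scheme = "random")
  expect_lt(max(abs(fit@params[c("nu1", "nu2", "Ts")] /
                      truth[c("nu1", "nu2", "Ts")] - 1)), 0.05)
  expect_equal(fit@theta, 5e4, tolerance = 0.05)
  # a different seed reaches the same optimum (composite lnL within 0.5)
  fit2 <- fitModel(obs, "SI", n_restarts = 8, seed = 11, pts = pts,
                   refine = 3, scheme = "random")
  expect_lt(abs(fit@loglik - fit2@loglik), 0.5)
})

test_that("parametric bootstrap brackets the point estimate reproducibly", {
  truth <- c(nu1 = 2, nu2 = 0.8, Ts = 0.25, O = 0.95)
  pts <- c(20, 30)
  obs <- expectedJsfs("SI", truth, 16, 16, pts = pts)
  obs@counts <- obs@counts * 2e4
  fit <- fitModel(obs, "SI", n_restarts = 4, seed = 5, pts = pts,
                  refine = 2, scheme = "random")
  expect_warning(
    ci <- bootstrapCi(obs, fit, n_boot = 4, seed = 9, n_restarts = 1),
    "wide-CI")
  expect_true(all(ci[names(fit@params), "lower"] <=
                    fit@params + 1e-6))
  expect_true(all(ci[names(fit@params), "upper"] >=
                    fit@params - 1e-6))
  expect_warning(ci2 <- bootstrapCi(obs, fit, n_boot = 4, seed = 9,
                                    n_restarts = 1), "wide-CI")
  expect_identical(ci, ci2)            # fixed seed, identical intervals
})

test_that("out-of-bounds parameters are refused by the engine", {
  expect_error(expectedJsfs("SI", c(nu1 = 200, nu2 = 1, Ts = 0.3, O = 0.9),
                            10, 10, pts = 20), "bounds")
  expect_error(expectedJsfs("SC", c(nu1 = 1, nu2 = 1, m12 = 1, m21 = 1,
                                    Ts = 0.2, Tc = 0.3, O = 0.9),
                            10, 10, pts = 20), "Tc")
  expect_error(expectedJsfs("SI", c(nu1 = 1, nu2 = 1, O = 0.9), 10, 10),
               "missing")
})
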