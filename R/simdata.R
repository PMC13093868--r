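# Synthetic data generators: structured-coalescent samples under one- and
# two-population histories, and forward-in-time sweep regions.
#
# The backward engine simulates independent non-recombining chunks
# (`chunk_len` bp each) and concatenates them, which reproduces the marginal
# genealogical process exactly and approximates recombination by free
# recombination between chunks; see the methods vignette for what this does
# and does not emulate.

.epochsTwoPop <- function(cfg) {
  Ts <- cfg@T_split * cfg@gen_per_year
  Tc <- cfg@T_contact * cfg@gen_per_year
  noMig <- matrix(0, 2, 2)
  mig <- matrix(c(0, cfg@m21, cfg@m12, 0), 2, 2)  # mig[i,j]: backward i -> j
  anc <- list(t0 = Ts, N0 = cfg@N_ref, g = 0,
              mig = matrix(0, 1, 1), relabel = c(0L, 0L))
  if (Ts <= 0) {
    return(list(list(t0 = 0, N0 = cfg@N_ref, g = 0,
                     mig = matrix(0, 1, 1), relabel = c(0L, 0L))))
  }
  # backward growth rate: present size b*N shrinks/grows to N at the split
  g1 <- -log(cfg@b1) / Ts
  g2 <- -log(cfg@b2) / Ts
  Npres <- c(cfg@b1 * cfg@N1, cfg@b2 * cfg@N2)
  e1 <- list(t0 = 0, N0 = Npres, g = c(g1, g2), mig = mig,
             relabel = c(0L, 1L))
  if (Tc <= 0) {
    e1$mig <- noMig
    return(list(e1, anc))
  }
  if (Tc >= Ts) return(list(e1, anc))
  Nc <- Npres * exp(c(g1, g2) * Tc)
  e2 <- list(t0 = Tc, N0 = Nc, g = c(g1, g2), mig = noMig,
             relabel = c(0L, 1L))
  list(e1, e2, anc)
}

.epochsPiecewise <- function(ne) {
  lapply(seq_along(ne@times), function(i) {
    list(t0 = ne@times[i], N0 = ne@sizes[i], g = 0,
         mig = matrix(0, 1, 1), relabel = 0L)
  })
}

#' Simulate two populations under a secondary-contact-with-growth history
#'
#' Draws phased haplotypes for \code{n1 + n2} diploid individuals under the
#' divergence history in \code{cfg}: an ancestral population of size
#' \code{N_ref} splits \code{T_split} years ago; each daughter changes size
#' exponentially from \code{N_i} at the split to \code{b_i * N_i} at present;
#' migration runs only during the most recent \code{T_contact} years.
#'
#' @param cfg a \linkS4class{DemographyConfig}
#' @param L sequence length in bp (>= 10 kb)
#' @param n1,n2 diploid sample sizes per population (>= 2)
#' @param seed integer seed; fixed seed gives identical output
#' @param chunk_len length of the independent non-recombining chunks (bp)
#' @return a \linkS4class{HaplotypeData} with population labels
#'   \code{"pop1"}/\code{"pop2"} and the truth record in
#'   \code{metadata()$truth}
#' @export
simulateTwoPop <- function(cfg, L, n1, n2, seed, chunk_len = 5000L) {
  stopifnot(is(cfg, "DemographyConfig"))
  validObject(cfg)
  if (L < 1e4) stop("L must be at least 10 kb")
  if (n1 < 2 || n2 < 2) stop("need at least 2 diploids per population")
  nChunks <- as.integer(ceiling(L / chunk_len))
  res <- .sim_coalescent(c(2L * n1, 2L * n2), .epochsTwoPop(cfg),
                         cfg@mu, as.integer(chunk_len), nChunks,
                         as.numeric(seed))
  HaplotypeData(res$hap, res$pos,
                samples = sprintf("P%d_%02d", rep(1:2, c(n1, n2)),
                                  c(seq_len(n1), seq_len(n2))),
                population = rep(c("pop1", "pop2"), c(n1, n2)),
                truth = list(kind = "two_pop", cfg = cfg, L = L,
                             n1 = n1, n2 = n2, seed = seed,
                             chunk_len = chunk_len))
}

#' Simulate one population under a piecewise-constant size history
#'
#' @param ne a \linkS4class{PiecewiseNe}
#' @param L sequence length (bp)
#' @param n diploid sample size
#' @param seed integer seed
#' @param mu mutation rate per bp per generation
#' @param chunk_len independent chunk length (bp)
#' @return a \linkS4class{HaplotypeData}
#' @export
simulateSinglePop <- function(ne, L, n, seed, mu = 3.5e-9,
                              chunk_len = 5000L) {
  stopifnot(is(ne, "PiecewiseNe"))
  validObject(ne)
  if (L < 1e4) stop("L must be at least 10 kb")
  if (n < 2) stop("need at least 2 diploids")
  nChunks <- as.integer(ceiling(L / chunk_len))
  res <- .sim_coalescent(2L * n, .epochsPiecewise(ne), mu,
                         as.integer(chunk_len), nChunks, as.numeric(seed))
  HaplotypeData(res$hap, res$pos,
                samples = sprintf("S%02d", seq_len(n)),
                population = rep(ne@label, n),
                truth = list(kind = "single_pop", ne = ne, L = L, n = n,
                             seed = seed, mu = mu, chunk_len = chunk_len))
}

#' Simulate a selection region under a supplied demography
#'
#' Neutral regions are drawn directly from the structured coalescent. Sweep
#' regions use a forward-in-time Wright-Fisher population with recombination,
#' initialised from a coalescent draw of the whole (rescaled) population at
#' mutation-drift equilibrium; the beneficial allele is injected at its
#' initial frequency and the simulation is conditioned on fixation, with lost
#' runs restarted. The demography is rescaled so that the forward population
#' holds \code{forward_N} diploids; mutation and recombination rates and the
#' selection coefficient are multiplied, and times divided, by the rescaling
#' factor, preserving the population-scaled parameters theta = 4*Ne*mu,
#' rho = 4*Ne*r and alpha = 2*Ne*s. The factor used is recorded in the truth
#' record.
#'
#' @param spec a \linkS4class{SweepRegionSpec}; \code{spec@s} is the
#'   unrescaled (biological) selection coefficient
#' @param ne a \linkS4class{PiecewiseNe} (unrescaled history)
#' @param n diploid sample size
#' @param seed integer seed
#' @param mu,r unrescaled per-bp per-generation rates
#' @param forward_N target diploid size of the forward population
#' @param chunk_len coalescent chunk length for the initial standing
#'   variation (bp)
#' @param max_restarts restarts allowed when the beneficial allele is lost
#' @return a \linkS4class{HaplotypeData} for \code{n} diploids over the
#'   region, truth record in \code{metadata()$truth}
#' @export
simulateSweepRegion <- function(spec, ne, n, seed, mu = 3.5e-9, r = 1e-8,
                                forward_N = 500L, chunk_len = 5000L,
                                max_restarts = 200L) {
  stopifnot(is(spec, "SweepRegionSpec"), is(ne, "PiecewiseNe"))
  validObject(spec); validObject(ne)
  if (spec@sweepClass != "neutral" && spec@s <= 0)
    stop("selected regions need s > 0")
  L <- as.integer(spec@length)
  Q <- max(1, ne@sizes[1] / forward_N)
  neR <- piecewiseNe(ne@times / Q, pmax(2, round(ne@sizes / Q)), ne@label)
  muR <- mu * Q
  rR <- r * Q
  sR <- spec@s * Q
  if (sR >= 2) stop("rescaled selection coefficient too large; raise forward_N")
  N <- as.integer(neR@sizes[1])
  nChunks <- as.integer(ceiling(L / chunk_len))

  if (spec@sweepClass == "neutral") {
    res <- .sim_coalescent(2L * n, .epochsPiecewise(neR), muR,
                           as.integer(chunk_len), nChunks, as.numeric(seed))
    truth <- list(kind = "sweep_region", class = "neutral", spec = spec,
                  rescale = Q, seed = seed)
    return(HaplotypeData(res$hap, res$pos,
                         samples = sprintf("S%02d", seq_len(n)),
                         population = rep(ne@label, n), truth = truth))
  }

  init <- .sim_coalescent(2L * N, .epochsPiecewise(neR), muR,
                          as.integer(chunk_len), nChunks, as.numeric(seed))
  f0 <- spec@f0
  copies <- if (spec@sweepClass == "hard" || is.na(f0)) 1L else
    max(2L, as.integer(round(f0 * 2 * N)))
  if (spec@sweepClass == "soft" && !is.na(f0) && f0 <= 1 / (2 * N))
    stop("soft sweeps need f0 > 1/(2N)")
  tau <- as.integer(round(spec@fix_offset / Q))
  fw <- .sim_sweep_forward(init$hap, init$pos, L, N, muR, rR, sR, 0.5,
                           copies, as.integer(spec@sweep_pos), tau,
                           as.integer(n), as.integer(max_restarts),
                           500000L, as.numeric(seed) + 7e9)
  truth <- list(kind = "sweep_region", class = spec@sweepClass, spec = spec,
                rescale = Q, s_rescaled = sR, copies0 = copies,
                restarts = fw$restarts, generations = fw$generations,
                fix_gen = fw$fix_gen, seed = seed)
  HaplotypeData(fw$hap, fw$pos, samples = sprintf("S%02d", seq_len(n)),
                population = rep(ne@label, n), truth = truth)
}
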