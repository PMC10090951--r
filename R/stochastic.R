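#' @useDynLib coupledGTPase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct an Ornstein-Uhlenbeck noise configuration
#'
#' Builds a validated [NoiseConfig-class] with the standard channel
#' amplitudes: stimulus amplitude 0.02 with relaxation time 1 min; species
#' amplitudes 0.02 for the five GTPase variables and tGAP, reduced to 2e-5
#' for secretion and 2e-6 for cell number (whose reaction rates are small,
#' keeping noise from overwhelming the deterministic drift); connection
#' amplitudes 0.02 for every activation-function and rate channel except the
#' cell-number channel at 0.002.
#'
#' @param mode noise source: \code{"stimulus_only"},
#'   \code{"stimulus_and_species"} or \code{"stimulus_and_connections"}.
#' @param sigmaSti stimulus-channel OU amplitude.
#' @param tauNoise OU relaxation time (min).
#' @param sigmaSpe optional named numeric overriding per-species amplitudes
#'   (names among mGEF, mGAP, mGstar, tGEF, tGstar, S, X, tGAP).
#' @param sigmaLink optional named numeric overriding per-connection
#'   amplitudes (names among fact1..fact9, S2, X).
#' @param dt fixed Euler step (min).
#' @param nRuns ensemble size.
#' @param seed base RNG seed.
#' @param scheme OU update scheme: \code{"as_printed"} keeps the
#'   \eqn{\tfrac12\sigma^2(\delta W^2-dt)} correction term;
#'   \code{"euler_maruyama"} drops it. For additive OU noise the two have
#'   identical stationary statistics.
#' @return a [NoiseConfig-class] object.
#' @export
noiseConfig <- function(mode = c("stimulus_only", "stimulus_and_species",
                                 "stimulus_and_connections"),
                        sigmaSti = 0.02, tauNoise = 1,
                        sigmaSpe = NULL, sigmaLink = NULL,
                        dt = 0.01, nRuns = 1000L, seed = 1L,
                        scheme = c("as_printed", "euler_maruyama")) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  spe <- setNames(rep(0.02, 8L), c(.STATE_VARS, "tGAP"))
  spe[["S"]] <- 2e-5
  spe[["X"]] <- 2e-6
  if (!is.null(sigmaSpe)) {
    bad <- setdiff(names(sigmaSpe), names(spe))
    if (length(bad)) stop("unknown species channels: ", paste(bad, collapse = ","))
    spe[names(sigmaSpe)] <- sigmaSpe
  }
  lnk <- setNames(rep(0.02, 11L), c(paste0("fact", 1:9), "S2", "X"))
  lnk[["X"]] <- 0.002
  if (!is.null(sigmaLink)) {
    bad <- setdiff(names(sigmaLink), names(lnk))
    if (length(bad)) stop("unknown link channels: ", paste(bad, collapse = ","))
    lnk[names(sigmaLink)] <- sigmaLink
  }
  new("NoiseConfig", mode = mode, sigmaSti = sigmaSti, tauNoise = tauNoise,
      sigmaSpe = spe, sigmaLink = lnk, dt = dt, nRuns = as.integer(nRuns),
      seed = as.integer(seed), scheme = scheme)
}

#' @describeIn NoiseConfig-class compact display
#' @param object a \code{NoiseConfig} object.
#' @export
setMethod("show", "NoiseConfig", function(object) {
  cat("NoiseConfig:", object@mode, "| sigmaSti =", object@sigmaSti,
      "tauNoise =", object@tauNoise, "dt =", object@dt,
      "nRuns =", object@nRuns, "seed =", object@seed,
      "scheme =", object@scheme, "\n")
  invisible(NULL)
})

#' One update step of an Ornstein-Uhlenbeck noise channel
#'
#' Advances \eqn{\tau\,d\eta = -\eta\,dt + \sigma\,dW} by one step of size
#' \code{dt}. With \code{scheme = "as_printed"} the update keeps the
#' Milstein-form correction term \eqn{\tfrac12\sigma^2(\delta W^2 - dt)};
#' with \code{scheme = "euler_maruyama"} it is the plain Euler-Maruyama
#' update. Because the noise is additive, both schemes share the stationary
#' law (mean 0, variance \eqn{\sigma^2/(2\tau)}).
#'
#' @param eta current noise value (vectorized).
#' @param sigma OU amplitude.
#' @param dt step size (min).
#' @param dW Wiener increment(s), Normal(0, dt).
#' @param tauNoise OU relaxation time (min).
#' @param scheme \code{"as_printed"} or \code{"euler_maruyama"}.
#' @return next noise value(s).
#' @export
ouUpdate <- function(eta, sigma, dt, dW, tauNoise = 1,
                     scheme = c("as_printed", "euler_maruyama")) {
  scheme <- match.arg(scheme)
  corr <- if (scheme == "as_printed") 0.5 * sigma^2 * (dW^2 - dt) else 0
  eta + (-eta * dt + sigma * dW + corr) / tauNoise
}

## marshal effective parameters + Hill constants for the C++ engine
.enginePar <- function(p, tab) {
  list(tau = unname(p@tau), k = unname(p@k), ymax = unname(p@ymax),
       secretion = unname(p@secretion), cell = unname(p@cell),
       orGate = unname(p@orGate), tGAP = p@tGAP,
       B = tab$B, K = tab$K, n = tab$n)
}

#' Simulate the circuit with Ornstein-Uhlenbeck noise
#'
#' Fixed-step Euler integration of the circuit on [0, \code{tEnd}] min at
#' step \code{noise@dt}, with OU noise channels advanced by the configured
#' scheme and injected according to \code{noise@mode}: into the stimulus
#' (inside fact1); additionally into each species equation (inside the
#' tau-scaled bracket for the five GTPase variables, added directly to dS/dt
#' and dX/dt) with a perturbed tGAP entering fact8's argument; or
#' additionally into every activation function and the nonlinear secretion /
#' endocytosis / proliferation rates. Each channel is an independent OU
#' process. S and X are floored at 0 if a step takes them negative (a
#' warning reports how often).
#'
#' @inheritParams circuitRHS
#' @param noise a [NoiseConfig-class] object.
#' @param init initial state; default [preEquilibrate()] at the given
#'   stimulus (the pre-stimulus steady state convention uses stimulus 0).
#' @param tEnd end time (min).
#' @param recordEvery record the state every this many Euler steps.
#' @param seed RNG seed for this run; default \code{noise@seed}.
#' @return a [CircuitTimeCourse-class] object.
#' @export
simulateStochastic <- function(params, stimulus,
                               variant = c("coupled", "uncoupled",
                                           "giv_depleted"),
                               gate = c("AND", "OR"),
                               noise = noiseConfig(), init = NULL,
                               tEnd = 1440, recordEvery = 100L,
                               seed = NULL) {
  variant <- match.arg(variant)
  gate <- match.arg(gate)
  stopifnot(is(noise, "NoiseConfig"))
  if (is.null(init))
    init <- preEquilibrate(params, variant, gate, stimulus = 0)
  init <- .asStateVector(init)
  if (is.null(seed)) seed <- noise@seed
  p <- .effectiveParams(params, variant)
  tab <- .hillTable(p)
  nSteps <- round(tEnd / noise@dt)
  modeCode <- match(noise@mode, c("stimulus_only", "stimulus_and_species",
                                  "stimulus_and_connections")) - 1L
  set.seed(seed)
  res <- tryCatch(
    .stochasticEngine(unname(init), stimulus, .enginePar(p, tab),
                      ifelse(variant == "uncoupled", 1L, 0L),
                      ifelse(gate == "AND", 0L, 1L),
                      modeCode, noise@sigmaSti, noise@tauNoise,
                      unname(noise@sigmaSpe), unname(noise@sigmaLink),
                      noise@dt, as.integer(nSteps), as.integer(recordEvery),
                      ifelse(noise@scheme == "as_printed", 0L, 1L)),
    error = function(e)
      stop("stochastic simulation failed (seed ", seed, "): ",
           conditionMessage(e)))
  if (res$nFloored > 0)
    warning("S or X floored at 0 in ", res$nFloored, " step(s) (seed ",
            seed, ")")
  states <- res$states
  colnames(states) <- .STATE_VARS
  new("CircuitTimeCourse", time = res$time, states = states,
      stimulus = stimulus, variant = variant, gate = gate)
}

#' Run a stochastic ensemble and summarize it
#'
#' Performs \code{noise@nRuns} independent stochastic simulations (replicate
#' r uses seed \code{seed + r - 1}) and returns the per-variable mean and
#' standard deviation (N-1 denominator) of the state at
#' \code{evaluationTime} (default 1,440 min).
#'
#' @inheritParams simulateStochastic
#' @param evaluationTime time (min) at which the ensemble statistics are
#'   taken.
#' @return an [EnsembleSummary-class] object.
#' @export
runEnsemble <- function(params, stimulus,
                        variant = c("coupled", "uncoupled", "giv_depleted"),
                        gate = c("AND", "OR"), noise = noiseConfig(),
                        init = NULL, evaluationTime = 1440, seed = NULL) {
  variant <- match.arg(variant)
  gate <- match.arg(gate)
  stopifnot(is(noise, "NoiseConfig"))
  if (noise@nRuns < 2L) stop("nRuns must be >= 2 for ensemble statistics")
  if (is.null(init))
    init <- preEquilibrate(params, variant, gate, stimulus = 0)
  init <- .asStateVector(init)
  if (is.null(seed)) seed <- noise@seed
  p <- .effectiveParams(params, variant)
  tab <- .hillTable(p)
  ep <- .enginePar(p, tab)
  nSteps <- as.integer(round(evaluationTime / noise@dt))
  modeCode <- match(noise@mode, c("stimulus_only", "stimulus_and_species",
                                  "stimulus_and_connections")) - 1L
  finals <- matrix(NA_real_, noise@nRuns, 7L,
                   dimnames = list(NULL, .STATE_VARS))
  nFloored <- 0L
  for (r in seq_len(noise@nRuns)) {
    set.seed(seed + r - 1L)
    res <- tryCatch(
      .stochasticEngine(unname(init), stimulus, ep,
                        ifelse(variant == "uncoupled", 1L, 0L),
                        ifelse(gate == "AND", 0L, 1L),
                        modeCode, noise@sigmaSti, noise@tauNoise,
                        unname(noise@sigmaSpe), unname(noise@sigmaLink),
                        noise@dt, nSteps, nSteps, # record final state only
                        ifelse(noise@scheme == "as_printed", 0L, 1L)),
      error = function(e)
        stop("ensemble replicate ", r, " (seed ", seed + r - 1L,
             ") failed: ", conditionMessage(e)))
    nFloored <- nFloored + res$nFloored
    finals[r, ] <- res$states[nrow(res$states), ]
  }
  if (nFloored > 0)
    warning("S or X floored at 0 in ", nFloored, " step(s) across the ensemble")
  new("EnsembleSummary",
      mean = colMeans(finals),
      sd = apply(finals, 2L, sd),
      nRuns = noise@nRuns, evaluationTime = evaluationTime)
}

#' @describeIn EnsembleSummary-class compact display
#' @param object an \code{EnsembleSummary} object.
#' @export
setMethod("show", "EnsembleSummary", function(object) {
  cat("EnsembleSummary over", object@nRuns, "runs at t =",
      object@evaluationTime, "min\n")
  print(round(rbind(mean = object@mean, sd = object@sd), 6))
  invisible(NULL)
})
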