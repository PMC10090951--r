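#' @import methods
#' @importFrom stats setNames rnorm sd lm coef optim quantile runif median var
#' @importFrom stats fitted residuals
#' @importFrom utils read.csv write.csv read.delim write.table head tail
#' @importFrom tools file_ext
NULL

## canonical state ordering used by every solver and summary in the package
.STATE_VARS <- c("mGEF", "mGAP", "mGstar", "tGEF", "tGstar", "S", "X")
.TAU_VARS   <- c("mGEF", "mGAP", "mGstar", "tGEF", "tGstar")
.YMAX_VARS  <- c("mGEF", "mGAP", "tGEF")

#' Kinetic parameters of the coupled GTPase circuit
#'
#' Container for every kinetic constant of the coupled-switch model: the nine
#' normalized-Hill reaction parameters (half-maximal activation \code{ec50} and
#' Hill coefficient \code{hillN} for reactions fact1..fact9), the per-species
#' time scales \code{tau} (min) and basal production rates \code{k}, the
#' maximal fractional activations \code{ymax} for mGEF, mGAP and tGEF, the
#' constant fractional tGAP level, the secretion/endocytosis constants, the
#' cell proliferation constants, and the OR-gate rescaling constants.
#'
#' @slot ec50 named numeric(9), half-maximal activations for fact1..fact9,
#'   each in (0, 1).
#' @slot hillN named numeric(9), Hill coefficients for fact1..fact9, > 0.
#' @slot tau named numeric(5), time scales (min) for mGEF, mGAP, mGstar,
#'   tGEF, tGstar.
#' @slot k named numeric(5), basal production rates (dimensionless).
#' @slot ymax named numeric(3), maximal fractional activations for mGEF,
#'   mGAP, tGEF, each in (0, 1].
#' @slot tGAP numeric(1), constant fractional tGAP level.
#' @slot secretion named numeric(5): \code{beta_S} (maximal secretion rate),
#'   \code{k_S} (basal secretion rate), \code{alpha_S} (maximal endocytosis
#'   rate), \code{gamma} (secreted-GF degradation rate), \code{K2} (binding
#'   affinity of secreted GFs).
#' @slot cell named numeric(4): \code{lambda} (proliferation rate), \code{mu}
#'   (death rate), \code{K1} (half-max secretion level for proliferation),
#'   \code{K_capacity} (carrying capacity).
#' @slot orGate named numeric(2): rescaling constants \code{c_tGEF},
#'   \code{c_tGstar} applied to the two mGAP-drive terms under OR logic.
#' @seealso [circuitParameters()], [defaultCircuitParameters()],
#'   [readCircuitParameters()]
#' @export
setClass("CircuitParameters",
  slots = c(
    ec50      = "numeric",
    hillN     = "numeric",
    tau       = "numeric",
    k         = "numeric",
    ymax      = "numeric",
    tGAP      = "numeric",
    secretion = "numeric",
    cell      = "numeric",
    orGate    = "numeric"
  )
)

setValidity("CircuitParameters", function(object) {
  msg <- character()
  fct <- paste0("fact", 1:9)
  if (length(object@ec50) != 9L || !identical(names(object@ec50), fct))
    msg <- c(msg, "ec50 must be numeric(9) named fact1..fact9")
  if (length(object@hillN) != 9L || !identical(names(object@hillN), fct))
    msg <- c(msg, "hillN must be numeric(9) named fact1..fact9")
  if (!length(msg)) {
    if (any(object@ec50 <= 0 | object@ec50 >= 1))
      msg <- c(msg, "all ec50 must lie in (0, 1)")
    if (any(object@hillN <= 0))
      msg <- c(msg, "all Hill coefficients must be > 0")
    if (any(abs(object@ec50^object@hillN - 0.5) < 1e-12))
      msg <- c(msg, "degenerate Hill parameters: ec50^n == 0.5")
  }
  if (length(object@tau) != 5L || !identical(names(object@tau), .TAU_VARS))
    msg <- c(msg, "tau must be numeric(5) named mGEF,mGAP,mGstar,tGEF,tGstar")
  else if (any(object@tau <= 0))
    msg <- c(msg, "all time scales must be > 0")
  if (length(object@k) != 5L || !identical(names(object@k), .TAU_VARS))
    msg <- c(msg, "k must be numeric(5) named mGEF,mGAP,mGstar,tGEF,tGstar")
  else if (any(object@k < 0))
    msg <- c(msg, "basal rates must be >= 0")
  if (length(object@ymax) != 3L || !identical(names(object@ymax), .YMAX_VARS))
    msg <- c(msg, "ymax must be numeric(3) named mGEF,mGAP,tGEF")
  else if (any(object@ymax <= 0 | object@ymax > 1))
    msg <- c(msg, "maximal fractional activations must lie in (0, 1]")
  if (length(object@tGAP) != 1L || object@tGAP < 0 || object@tGAP > 1)
    msg <- c(msg, "tGAP must be a single value in [0, 1]")
  sn <- c("beta_S", "k_S", "alpha_S", "gamma", "K2")
  if (length(object@secretion) != 5L || !identical(names(object@secretion), sn))
    msg <- c(msg, "secretion must be numeric(5) named beta_S,k_S,alpha_S,gamma,K2")
  else {
    if (any(object@secretion[c("beta_S", "k_S", "alpha_S", "gamma")] < 0))
      msg <- c(msg, "secretion rates must be >= 0")
    if (object@secretion[["K2"]] <= 0)
      msg <- c(msg, "K2 must be > 0")
  }
  cn <- c("lambda", "mu", "K1", "K_capacity")
  if (length(object@cell) != 4L || !identical(names(object@cell), cn))
    msg <- c(msg, "cell must be numeric(4) named lambda,mu,K1,K_capacity")
  else {
    if (any(object@cell[c("lambda", "mu")] < 0))
      msg <- c(msg, "lambda and mu must be >= 0")
    if (any(object@cell[c("K1", "K_capacity")] <= 0))
      msg <- c(msg, "K1 and K_capacity must be > 0")
  }
  gn <- c("c_tGEF", "c_tGstar")
  if (length(object@orGate) != 2L || !identical(names(object@orGate), gn))
    msg <- c(msg, "orGate must be numeric(2) named c_tGEF,c_tGstar")
  if (length(msg)) msg else TRUE
})

#' Simulated circuit time course
#'
#' A trajectory of the seven state variables (mGEF, mGAP, mG*, tGEF, tG*,
#' secreted growth factor S, cell number X) over a time grid, together with
#' the stimulus applied after time zero.
#'
#' @slot time numeric, strictly increasing time grid (min).
#' @slot states numeric matrix, one row per time point, columns mGEF, mGAP,
#'   mGstar, tGEF, tGstar, S, X.
#' @slot stimulus numeric(1), dimensionless EGF input applied on the grid.
#' @slot variant character(1), model variant used.
#' @slot gate character(1), mGAP-drive logic gate used.
#' @export
setClass("CircuitTimeCourse",
  slots = c(
    time     = "numeric",
    states   = "matrix",
    stimulus = "numeric",
    variant  = "character",
    gate     = "character"
  )
)

setValidity("CircuitTimeCourse", function(object) {
  msg <- character()
  if (length(object@time) < 2L)
    msg <- c(msg, "time grid must contain at least 2 points")
  if (any(diff(object@time) <= 0))
    msg <- c(msg, "time grid must be strictly increasing")
  if (length(object@time) && object@time[1L] < 0)
    msg <- c(msg, "time grid must start at t >= 0")
  if (!identical(colnames(object@states), .STATE_VARS))
    msg <- c(msg, "state columns must be mGEF,mGAP,mGstar,tGEF,tGstar,S,X")
  if (nrow(object@states) != length(object@time))
    msg <- c(msg, "states must have one row per time point")
  if (any(!is.finite(object@states)))
    msg <- c(msg, "all states must be finite")
  if (length(msg)) msg else TRUE
})

#' Ornstein-Uhlenbeck noise configuration
#'
#' Amplitudes and mode of the OU noise channels injected into the stochastic
#' circuit. Channels are independent OU processes
#' \eqn{\tau\,d\eta = -\eta\,dt + \sigma\,dW} with zero mean and stationary
#' variance \eqn{\sigma^2/(2\tau)}.
#'
#' @slot mode one of \code{"stimulus_only"}, \code{"stimulus_and_species"},
#'   \code{"stimulus_and_connections"}.
#' @slot sigmaSti numeric(1), OU amplitude of the stimulus channel.
#' @slot tauNoise numeric(1), OU relaxation time (min), shared by channels.
#' @slot sigmaSpe named numeric, per-species amplitudes (mGEF..X plus tGAP).
#' @slot sigmaLink named numeric, per-connection amplitudes (fact1..fact9,
#'   the endocytosis rate channel \code{S2}, and the proliferation channel
#'   \code{X}).
#' @slot dt numeric(1), fixed Euler step (min).
#' @slot nRuns integer(1), ensemble size.
#' @slot seed integer(1), base RNG seed.
#' @slot scheme OU update scheme, \code{"as_printed"} (Euler plus the
#'   \eqn{\tfrac12\sigma^2(\delta W^2 - dt)} correction) or
#'   \code{"euler_maruyama"}.
#' @export
setClass("NoiseConfig",
  slots = c(
    mode      = "character",
    sigmaSti  = "numeric",
    tauNoise  = "numeric",
    sigmaSpe  = "numeric",
    sigmaLink = "numeric",
    dt        = "numeric",
    nRuns     = "integer",
    seed      = "integer",
    scheme    = "character"
  )
)

setValidity("NoiseConfig", function(object) {
  msg <- character()
  modes <- c("stimulus_only", "stimulus_and_species", "stimulus_and_connections")
  if (length(object@mode) != 1L || !object@mode %in% modes)
    msg <- c(msg, paste("mode must be one of:", paste(modes, collapse = ", ")))
  if (object@sigmaSti < 0) msg <- c(msg, "sigmaSti must be >= 0")
  if (object@tauNoise <= 0) msg <- c(msg, "tauNoise must be > 0")
  spe <- c(.STATE_VARS, "tGAP")
  if (!identical(names(object@sigmaSpe), spe))
    msg <- c(msg, "sigmaSpe must be named mGEF..X,tGAP")
  else if (any(object@sigmaSpe < 0))
    msg <- c(msg, "sigmaSpe must be >= 0")
  lnk <- c(paste0("fact", 1:9), "S2", "X")
  if (!identical(names(object@sigmaLink), lnk))
    msg <- c(msg, "sigmaLink must be named fact1..fact9,S2,X")
  else if (any(object@sigmaLink < 0))
    msg <- c(msg, "sigmaLink must be >= 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@nRuns < 1L) msg <- c(msg, "nRuns must be >= 1")
  if (!object@scheme %in% c("as_printed", "euler_maruyama"))
    msg <- c(msg, "scheme must be 'as_printed' or 'euler_maruyama'")
  if (length(msg)) msg else TRUE
})

#' Ensemble summary statistics
#'
#' Per-variable mean and standard deviation (N-1 denominator) of repeated
#' stochastic simulations evaluated at a fixed time.
#'
#' @slot mean named numeric(7), per-variable ensemble mean.
#' @slot sd named numeric(7), per-variable ensemble standard deviation.
#' @slot nRuns integer(1), ensemble size.
#' @slot evaluationTime numeric(1), evaluation time (min).
#' @export
setClass("EnsembleSummary",
  slots = c(
    mean           = "numeric",
    sd             = "numeric",
    nRuns          = "integer",
    evaluationTime = "numeric"
  )
)

setValidity("EnsembleSummary", function(object) {
  msg <- character()
  if (!identical(names(object@mean), .STATE_VARS) ||
      !identical(names(object@sd), .STATE_VARS))
    msg <- c(msg, "mean and sd must be named mGEF..X")
  if (any(object@sd < 0)) msg <- c(msg, "sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Steady-state dose-response curve
#'
#' Terminal-state statistics of every circuit variable over a stimulus grid,
#' as produced by [doseSweep()].
#'
#' @slot doses numeric, strictly increasing dimensionless stimulus grid.
#' @slot mean numeric matrix, per-dose per-variable steady-state mean.
#' @slot sd numeric matrix, per-dose per-variable SD (zero when deterministic).
#' @slot variant character(1), model variant.
#' @slot gate character(1), logic gate.
#' @slot stochastic logical(1), whether a noise ensemble was used.
#' @export
setClass("DoseResponseCurve",
  slots = c(
    doses      = "numeric",
    mean       = "matrix",
    sd         = "matrix",
    variant    = "character",
    gate       = "character",
    stochastic = "logical"
  )
)

setValidity("DoseResponseCurve", function(object) {
  msg <- character()
  if (any(diff(object@doses) <= 0))
    msg <- c(msg, "doses must be strictly increasing")
  if (!identical(colnames(object@mean), .STATE_VARS))
    msg <- c(msg, "mean columns must be mGEF..X")
  if (nrow(object@mean) != length(object@doses))
    msg <- c(msg, "one row per dose required")
  if (any(object@sd < 0)) msg <- c(msg, "sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Hill curve fit
#'
#' Result of fitting \eqn{a\,x^n/(x^n + K) + d} to a dose-response curve by
#' nonlinear least squares.
#'
#' @slot a numeric(1), amplitude.
#' @slot n numeric(1), Hill coefficient (> 0).
#' @slot K numeric(1), half-max constant on the \eqn{x^n} scale (> 0); the
#'   half-maximal input is \eqn{K^{1/n}}.
#' @slot d numeric(1), offset (0 when dropped).
#' @slot r2 numeric(1), coefficient of determination.
#' @slot offsetUsed logical(1), whether the offset term was retained.
#' @export
setClass("HillFit",
  slots = c(
    a          = "numeric",
    n          = "numeric",
    K          = "numeric",
    d          = "numeric",
    r2         = "numeric",
    offsetUsed = "logical"
  )
)

setValidity("HillFit", function(object) {
  msg <- character()
  if (object@n <= 0) msg <- c(msg, "n must be > 0")
  if (object@K <= 0) msg <- c(msg, "K must be > 0")
  if (object@r2 > 1 + 1e-12) msg <- c(msg, "r2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' Fold-change time-course dataset
#'
#' Mean +/- SEM fold-change measurements over a time grid, for one readout
#' (active mGTPase or active tGTPase) in one condition (control or
#' GIV-depleted). This is the statistical shape of densitometry/FRET
#' time-course data.
#'
#' @slot time numeric, increasing time grid (min) starting at 0.
#' @slot mean numeric, mean fold change per time point (baseline = 1 at t 0).
#' @slot sem numeric, standard error per time point.
#' @slot condition character(1), "control" or "giv_depleted".
#' @slot readout character(1), "mGstar" or "tGstar".
#' @export
setClass("TimeCourseDataset",
  slots = c(
    time      = "numeric",
    mean      = "numeric",
    sem       = "numeric",
    condition = "character",
    readout   = "character"
  )
)

setValidity("TimeCourseDataset", function(object) {
  msg <- character()
  if (length(object@time) < 2L || any(diff(object@time) <= 0))
    msg <- c(msg, "time must be increasing with >= 2 points")
  if (length(object@time) && object@time[1L] != 0)
    msg <- c(msg, "time grid must include t = 0")
  if (length(object@mean) != length(object@time) ||
      length(object@sem) != length(object@time))
    msg <- c(msg, "mean and sem must match the time grid")
  if (any(object@sem < 0)) msg <- c(msg, "sem must be >= 0")
  if (!object@condition %in% c("control", "giv_depleted"))
    msg <- c(msg, "condition must be 'control' or 'giv_depleted'")
  if (!object@readout %in% c("mGstar", "tGstar"))
    msg <- c(msg, "readout must be 'mGstar' or 'tGstar'")
  if (length(msg)) msg else TRUE
})

#' Parameter-fit report
#'
#' Output of [fitParameters()]: the fitted parameter object, per-dataset
#' normalized RMSE and R-squared, and pass flags against the acceptance
#' thresholds (active mGTPase: 0.2; active tGTPase: 0.45).
#'
#' @slot parameters fitted [CircuitParameters-class] object.
#' @slot nrmse named numeric, normalized RMSE per dataset.
#' @slot r2 named numeric, R-squared per dataset.
#' @slot pass named logical, threshold pass flag per dataset.
#' @slot thresholds named numeric, the cutoffs used per readout.
#' @slot freeParams character, names of the parameters that were free.
#' @slot objective numeric(1), final summed normalized RMSE.
#' @slot evaluations integer(1), number of objective evaluations spent.
#' @export
setClass("FitReport",
  slots = c(
    parameters  = "CircuitParameters",
    nrmse       = "numeric",
    r2          = "numeric",
    pass        = "logical",
    thresholds  = "numeric",
    freeParams  = "character",
    objective   = "numeric",
    evaluations = "integer"
  )
)

#' Scored protein-protein interaction graph
#'
#' An undirected PPI graph built from a STRING-style edge table after applying
#' a combined-score cutoff, together with the seed protein set.
#'
#' @slot graph an \code{igraph} object (undirected, simple).
#' @slot seeds character, seed protein symbols (subset of the vertex names).
#' @slot cutoff numeric(1), combined-score cutoff that was applied.
#' @export
setClass("InteractionGraph",
  slots = c(
    graph  = "ANY",
    seeds  = "character",
    cutoff = "numeric"
  )
)

setValidity("InteractionGraph", function(object) {
  msg <- character()
  if (!igraph::is_igraph(object@graph))
    msg <- c(msg, "graph must be an igraph object")
  else {
    if (igraph::is_directed(object@graph))
      msg <- c(msg, "graph must be undirected")
    if (any(igraph::which_loop(object@graph)))
      msg <- c(msg, "graph must not contain self-loops")
    if (!all(object@seeds %in% igraph::V(object@graph)$name))
      msg <- c(msg, "all seeds must be graph vertices")
  }
  if (length(msg)) msg else TRUE
})
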