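## model variants:
##   coupled    - full circuit, mGAP driven by the tGEF/tG* feedback gate
##   uncoupled  - single mGTPase switch: mGAP relaxes to its basal level only
##   giv_depleted - coupled circuit with ymax_tGEF forced to 0.1 (10% GIV)
.VARIANTS <- c("coupled", "uncoupled", "giv_depleted")
.GIV_DEPLETED_YMAX_TGEF <- 0.1

## effective parameters for a variant (GIV depletion caps ymax_tGEF)
.effectiveParams <- function(params, variant) {
  if (variant == "giv_depleted")
    params@ymax[["tGEF"]] <- .GIV_DEPLETED_YMAX_TGEF
  params
}

## right-hand side with a precomputed Hill table; state is an unnamed
## numeric(7) in canonical order. This inner function is the single source of
## truth for the deterministic model; solvers and fold-change pipelines all
## route through it.
.rhsCore <- function(state, stimulus, p, tab, variant, gate) {
  mGEF <- state[1L]; mGAP <- state[2L]; mGstar <- state[3L]
  tGEF <- state[4L]; tGstar <- state[5L]; S <- state[6L]; X <- state[7L]
  tau <- p@tau; k <- p@k; ymax <- p@ymax
  drive <- if (variant == "uncoupled") 0
           else .mgapDriveTab(tGEF, tGstar, tab, gate, p@orGate)
  dmGEF <- ((.fact(1L, stimulus, tab) + k[["mGEF"]]) * ymax[["mGEF"]] - mGEF) /
    tau[["mGEF"]]
  dmGAP <- ((drive + k[["mGAP"]]) * ymax[["mGAP"]] - mGAP) / tau[["mGAP"]]
  dmGstar <- ((.fact(4L, mGEF, tab) + k[["mGstar"]]) * (1 - mGstar) -
    .fact(5L, mGAP, tab) * mGstar) / tau[["mGstar"]]
  dtGEF <- ((.fact(6L, mGstar, tab) + k[["tGEF"]]) * ymax[["tGEF"]] - tGEF) /
    tau[["tGEF"]]
  dtGstar <- ((.fact(7L, tGEF, tab) + k[["tGstar"]]) * (1 - tGstar) -
    .fact(8L, p@tGAP, tab) * tGstar) / tau[["tGstar"]]
  sec <- p@secretion; cl <- p@cell
  dS <- (sec[["beta_S"]] * .fact(9L, mGAP, tab) + sec[["k_S"]] -
    sec[["alpha_S"]] * S / (S + sec[["K2"]])) * X - sec[["gamma"]] * S
  dX <- cl[["lambda"]] * S / (S + cl[["K1"]]) *
    (1 - X / cl[["K_capacity"]]) - cl[["mu"]] * X
  c(dmGEF, dmGAP, dmGstar, dtGEF, dtGstar, dS, dX)
}

#' Right-hand side of the coupled GTPase circuit ODEs
#'
#' Evaluates the time derivatives of the seven state variables (mGEF, mGAP,
#' mG*, tGEF, tG*, secreted growth factor S, cell number X) for the chosen
#' model variant and mGAP logic gate. The five GTPase equations are
#' tau-scaled relaxation equations driven by normalized-Hill activations; the
#' secretion equation balances mGAP-dependent secretion, basal secretion and
#' saturable endocytosis against degradation; the cell equation balances
#' secretion-dependent logistic proliferation against death.
#'
#' @param state named or unnamed numeric(7) in the order mGEF, mGAP, mGstar,
#'   tGEF, tGstar, S, X.
#' @param stimulus dimensionless EGF input, >= 0.
#' @param params a [CircuitParameters-class] object.
#' @param variant \code{"coupled"} (full circuit), \code{"uncoupled"} (single
#'   mGTPase switch: the mGAP equation loses its feedback drive), or
#'   \code{"giv_depleted"} (coupled with \code{ymax_tGEF} forced to 0.1).
#' @param gate \code{"AND"} or \code{"OR"} logic for the two feedback arrows
#'   onto mGAP.
#' @return named numeric(7) of derivatives.
#' @export
circuitRHS <- function(state, stimulus, params,
                       variant = c("coupled", "uncoupled", "giv_depleted"),
                       gate = c("AND", "OR")) {
  variant <- match.arg(variant)
  gate <- match.arg(gate)
  state <- .asStateVector(state)
  if (any(!is.finite(state))) stop("non-finite state")
  if (!is.finite(stimulus) || stimulus < 0) stop("stimulus must be >= 0")
  p <- .effectiveParams(params, variant)
  tab <- .hillTable(p)
  setNames(.rhsCore(unname(state), stimulus, p, tab, variant, gate),
           .STATE_VARS)
}

.asStateVector <- function(state) {
  state <- unlist(state)
  if (length(state) != 7L) stop("state must have 7 components")
  if (!is.null(names(state)) && all(.STATE_VARS %in% names(state)))
    state <- state[.STATE_VARS]
  setNames(as.numeric(state), .STATE_VARS)
}

#' Pre-equilibrate the circuit to its steady state
#'
#' Relaxes the circuit to the fixed point at the given (usually zero)
#' stimulus by stiff adaptive integration from an arbitrary starting state
#' (default: all seven variables at 0.5), in doubling time spans up to
#' \code{tMax}, exiting early once the infinity norm of the right-hand side
#' drops below \code{tol}. The result is independent of the arbitrary start
#' whenever the basal fixed point is unique.
#'
#' @inheritParams circuitRHS
#' @param stimulus stimulus held during equilibration (default 0, starved).
#' @param init starting state (default: all variables 0.5).
#' @param tol convergence tolerance on the infinity norm of the derivatives.
#' @param tMax time cap for the relaxation (min).
#' @return named numeric(7) steady state.
#' @export
preEquilibrate <- function(params,
                           variant = c("coupled", "uncoupled", "giv_depleted"),
                           gate = c("AND", "OR"), stimulus = 0,
                           init = NULL, tol = 1e-8, tMax = 144000) {
  variant <- match.arg(variant)
  gate <- match.arg(gate)
  if (is.null(init)) init <- setNames(rep(0.5, 7L), .STATE_VARS)
  state <- .asStateVector(init)
  p <- .effectiveParams(params, variant)
  tab <- .hillTable(p)
  span <- 200
  elapsed <- 0
  repeat {
    if (max(abs(.rhsCore(unname(state), stimulus, p, tab, variant, gate))) < tol)
      return(state)
    if (elapsed >= tMax)
      stop("pre-equilibration did not converge within ", tMax,
           " min (residual ",
           format(max(abs(.rhsCore(unname(state), stimulus, p, tab,
                                   variant, gate)))), ")")
    span <- min(span, tMax - elapsed)
    sol <- deSolve::lsoda(
      y = unname(state), times = c(0, span),
      func = function(t, y, parms)
        list(.rhsCore(y, stimulus, p, tab, variant, gate)),
      rtol = 1e-10, atol = 1e-12
    )
    state <- setNames(as.numeric(sol[nrow(sol), -1L]), .STATE_VARS)
    elapsed <- elapsed + span
    span <- span * 2
  }
}

#' Simulate the deterministic circuit
#'
#' Integrates the circuit ODEs with a stiff-capable adaptive solver
#' (\code{deSolve::lsoda}, rtol 1e-8 / atol 1e-10) and returns the solution
#' on the requested time grid. The standard stimulation protocol starts from
#' [preEquilibrate()] at stimulus 0 and switches the stimulus to 0.23
#' (corresponding to 50 nM EGF) at time zero.
#'
#' @inheritParams circuitRHS
#' @param times strictly increasing output time grid (min); default
#'   0..1440 min at 1-min resolution.
#' @param init initial state; default the pre-equilibrated starved state.
#' @return a [CircuitTimeCourse-class] object.
#' @examples
#' \donttest{
#' p <- defaultCircuitParameters()
#' tc <- simulateCircuit(p, stimulus = 0.23, times = seq(0, 60, by = 1))
#' head(asDataFrame(tc))
#' }
#' @export
simulateCircuit <- function(params, stimulus,
                            variant = c("coupled", "uncoupled", "giv_depleted"),
                            gate = c("AND", "OR"),
                            times = seq(0, 1440, by = 1), init = NULL) {
  variant <- match.arg(variant)
  gate <- match.arg(gate)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least 2 points")
  if (!is.finite(stimulus) || stimulus < 0) stop("stimulus must be >= 0")
  if (is.null(init))
    init <- preEquilibrate(params, variant, gate, stimulus = 0)
  state <- .asStateVector(init)
  if (any(!is.finite(state))) stop("non-finite initial state")
  p <- .effectiveParams(params, variant)
  tab <- .hillTable(p)
  sol <- deSolve::lsoda(
    y = unname(state), times = times,
    func = function(t, y, parms)
      list(.rhsCore(y, stimulus, p, tab, variant, gate)),
    rtol = 1e-8, atol = 1e-10
  )
  if (nrow(sol) < length(times))
    stop("integrator failed at t = ", sol[nrow(sol), 1L],
         " min (variant ", variant, ", stimulus ", stimulus, ")")
  states <- as.matrix(sol[, -1L, drop = FALSE])
  colnames(states) <- .STATE_VARS
  new("CircuitTimeCourse", time = as.numeric(times), states = states,
      stimulus = stimulus, variant = variant, gate = gate)
}

#' @describeIn CircuitTimeCourse-class data.frame view with columns
#'   \code{t_min}, the seven state variables, and \code{stimulus}.
#' @param x a \code{CircuitTimeCourse} object.
#' @export
setGeneric("asDataFrame", function(x) standardGeneric("asDataFrame"))

#' @rdname CircuitTimeCourse-class
#' @export
setMethod("asDataFrame", "CircuitTimeCourse", function(x) {
  data.frame(t_min = x@time, as.data.frame(x@states),
             stimulus = x@stimulus)
})

#' Extract one state variable from a time course
#'
#' @param tc a [CircuitTimeCourse-class] object.
#' @param variable one of mGEF, mGAP, mGstar, tGEF, tGstar, S, X.
#' @return numeric vector over the time grid.
#' @export
stateVariable <- function(tc, variable) {
  stopifnot(is(tc, "CircuitTimeCourse"))
  variable <- match.arg(variable, .STATE_VARS)
  tc@states[, variable]
}

#' Time grid of a time course
#' @param tc a [CircuitTimeCourse-class] object.
#' @return numeric vector of times (min).
#' @export
timeGrid <- function(tc) {
  stopifnot(is(tc, "CircuitTimeCourse"))
  tc@time
}

#' @describeIn CircuitTimeCourse-class compact display
#' @param object a \code{CircuitTimeCourse} object.
#' @export
setMethod("show", "CircuitTimeCourse", function(object) {
  cat("CircuitTimeCourse:", length(object@time), "time points on [",
      object@time[1L], ",", object@time[length(object@time)],
      "] min\n  variant =", object@variant, ", gate =", object@gate,
      ", stimulus =", object@stimulus, "\n  final state:",
      paste(sprintf("%s=%.4g", .STATE_VARS,
                    object@states[nrow(object@states), ]), collapse = " "),
      "\n")
  invisible(NULL)
})

#' Write a time course to CSV
#'
#' Columns: \code{t_min,mGEF,mGAP,mGstar,tGEF,tGstar,S,X,stimulus}.
#'
#' @param tc a [CircuitTimeCourse-class] object.
#' @param path destination CSV file.
#' @return invisibly, the path.
#' @export
writeTimeCourse <- function(tc, path) {
  write.csv(asDataFrame(tc), path, row.names = FALSE)
  invisible(path)
}

#' Read a time course from CSV written by [writeTimeCourse()]
#'
#' @param path CSV file path.
#' @return a [CircuitTimeCourse-class] object (variant and gate are recorded
#'   as \code{"unknown"} since the CSV does not carry them).
#' @export
readTimeCourse <- function(path) {
  df <- read.csv(path)
  need <- c("t_min", .STATE_VARS, "stimulus")
  if (!all(need %in% names(df)))
    stop("time-course CSV must have columns: ", paste(need, collapse = ","))
  states <- as.matrix(df[, .STATE_VARS])
  colnames(states) <- .STATE_VARS
  new("CircuitTimeCourse", time = df$t_min, states = states,
      stimulus = df$stimulus[1L], variant = "unknown", gate = "unknown")
}
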