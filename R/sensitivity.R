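#' Logarithmic sensitivity of a model output to one parameter
#'
#' Local sensitivity \eqn{d\ln X / d\ln\alpha}, approximated by perturbing
#' the parameter to 1.1 and 0.9 times its value. The default scheme divides
#' the difference of \eqn{\ln X} by 0.2 (the symmetric relative
#' perturbation), giving the dimensionless logarithmic gain; the
#' \code{"as_printed"} scheme divides by \eqn{0.2\,\alpha} instead, giving
#' \eqn{d\ln X/d\alpha}. The two differ exactly by the factor \eqn{\alpha}.
#'
#' @param outputFn function taking a [CircuitParameters-class] object and
#'   returning a single positive number.
#' @param params base [CircuitParameters-class] object.
#' @param paramName flat name of the parameter to perturb (see
#'   [flattenParameters()]).
#' @param scheme \code{"default"} or \code{"as_printed"}.
#' @return dimensionless sensitivity (default scheme).
#' @examples
#' \donttest{
#' p <- defaultCircuitParameters()
#' logSensitivity(function(q) .getParam(q, "K1")^2, p, "K1") # ~2
#' }
#' @export
logSensitivity <- function(outputFn, params, paramName,
                           scheme = c("default", "as_printed")) {
  scheme <- match.arg(scheme)
  alpha <- .getParam(params, paramName)
  xs <- vapply(c(1.1, 0.9), function(f) {
    p2 <- .setParam(params, paramName, f * alpha)
    outputFn(p2)
  }, numeric(1L))
  if (any(!is.finite(xs)) || any(xs <= 0))
    stop("output must be positive and finite at the perturbed values of ",
         paramName)
  denom <- if (scheme == "default") 0.2 else 0.2 * alpha
  (log(xs[1L]) - log(xs[2L])) / denom
}

## the four standard outputs: steady-state secretion and cell number at the
## stimulated state, and normalized RMSE of the mG*/tG* fold-change traces
## against reference datasets
.standardOutputs <- function(reference, stimulus = 0.23, gate = "AND") {
  ssOutput <- function(variable) {
    force(variable)
    function(p) {
      basal <- preEquilibrate(p, "coupled", gate, stimulus = 0)
      tc <- simulateCircuit(p, stimulus, "coupled", gate,
                            times = c(0, 720, 1440), init = basal)
      tc@states[nrow(tc@states), variable]
    }
  }
  nrmseOutput <- function(readout) {
    force(readout)
    ds <- Filter(function(d)
      d@condition == "control" && d@readout == readout, reference)
    if (!length(ds))
      stop("no control reference dataset for readout ", readout)
    ds <- ds[[1L]]
    function(p) normalizedRMSE(.predictDataset(p, ds, stimulus, gate),
                               ds@mean)
  }
  list(secretion_ss = ssOutput("S"),
       cellnumber_ss = ssOutput("X"),
       nrmse_mGstar = function(p) nrmseOutput("mGstar")(p),
       nrmse_tGstar = function(p) nrmseOutput("tGstar")(p))
}

#' Sensitivity table over parameters and outputs
#'
#' Computes the logarithmic sensitivity of the requested outputs to each
#' requested kinetic parameter (plus/minus 10% central difference). The
#' standard outputs are the steady-state secretion and cell number under
#' stimulus 0.23 and the normalized RMSE of the control mG* and tG*
#' fold-change traces against reference datasets (defaults to the bundled
#' synthetic datasets, see [syntheticTimecourses()]).
#'
#' @param params base [CircuitParameters-class] object.
#' @param outputs character subset of \code{c("secretion_ss",
#'   "cellnumber_ss", "nrmse_mGstar", "nrmse_tGstar")}.
#' @param paramNames flat parameter names to perturb; default every kinetic
#'   parameter (OR-gate constants excluded). Duplicates are removed with a
#'   warning.
#' @param reference list of [TimeCourseDataset-class] used by the nRMSE
#'   outputs; default [syntheticTimecourses()] with the given seed.
#' @param scheme passed to [logSensitivity()].
#' @param seed seed for the default reference datasets.
#' @return data.frame with columns \code{parameter}, \code{output},
#'   \code{sensitivity}, sorted by decreasing absolute sensitivity. A
#'   parameter whose +10% perturbation leaves the admissible range (e.g. a
#'   maximal fractional activation already at 1) yields \code{NA}.
#' @export
sensitivityTable <- function(params,
                             outputs = c("secretion_ss", "cellnumber_ss",
                                         "nrmse_mGstar", "nrmse_tGstar"),
                             paramNames = NULL, reference = NULL,
                             scheme = c("default", "as_printed"),
                             seed = 1L) {
  scheme <- match.arg(scheme)
  outputs <- match.arg(outputs, several.ok = TRUE)
  if (is.null(paramNames)) {
    paramNames <- setdiff(names(flattenParameters(params)),
                          c("or_gate_c_tGEF", "or_gate_c_tGstar"))
  }
  if (anyDuplicated(paramNames)) {
    warning("duplicate parameter names removed")
    paramNames <- unique(paramNames)
  }
  needsRef <- any(grepl("^nrmse_", outputs))
  if (needsRef && is.null(reference))
    reference <- syntheticTimecourses(params, seed = seed)$datasets
  fns <- .standardOutputs(reference, gate = "AND")[outputs]
  rows <- list()
  for (pn in paramNames) {
    for (out in outputs) {
      s <- tryCatch(logSensitivity(fns[[out]], params, pn, scheme),
                    error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = pn, output = out, sensitivity = s)
    }
  }
  tab <- do.call(rbind, rows)
  tab[order(-abs(tab$sensitivity)), , drop = FALSE]
}
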