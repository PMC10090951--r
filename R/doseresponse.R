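## EGF normalization: 0.23 dimensionless stimulus corresponds to 50 nM EGF,
## so concentrations are divided by 50/0.23 = 217.4 nM (to 4 significant
## figures; the exact ratio is used internally).
.EGF_NORM_NM <- 50 / 0.23

#' Convert an EGF concentration to the dimensionless stimulus
#'
#' Divides the EGF concentration (nM) by 217.4 nM (= 50 nM / 0.23), so that
#' 50 nM maps to the standard simulation stimulus 0.23.
#'
#' @param egf_nM EGF concentration in nM, >= 0 (vectorized).
#' @return dimensionless stimulus.
#' @examples
#' egfToStimulus(50)  # 0.23
#' @export
egfToStimulus <- function(egf_nM) {
  if (any(!is.finite(egf_nM)) || any(egf_nM < 0))
    stop("EGF concentration must be finite and >= 0")
  egf_nM / .EGF_NORM_NM
}

#' Convert a dimensionless stimulus back to an EGF concentration (nM)
#'
#' Inverse of [egfToStimulus()].
#'
#' @param stimulus dimensionless stimulus, >= 0 (vectorized).
#' @return EGF concentration in nM.
#' @export
stimulusToEgf <- function(stimulus) {
  if (any(!is.finite(stimulus)) || any(stimulus < 0))
    stop("stimulus must be finite and >= 0")
  stimulus * .EGF_NORM_NM
}

#' Default stimulus grid for dose sweeps
#'
#' The seven doses used for the printed dose tables ({0, 0.1, 1, 10, 25, 50,
#' 100} nM, i.e. {0, 0.00046, 0.0046, 0.046, 0.115, 0.23, 0.46}
#' dimensionless) plus \code{nExtra} log-spaced points in [1e-4, 0.46] for
#' fit stability.
#'
#' @param nExtra number of additional log-spaced doses (default 20).
#' @return sorted numeric vector of dimensionless doses.
#' @export
defaultDoseGrid <- function(nExtra = 20) {
  printed <- egfToStimulus(c(0, 0.1, 1, 10, 25, 50, 100))
  extra <- if (nExtra > 0) 10^seq(log10(1e-4), log10(0.46), length.out = nExtra)
           else numeric()
  sort(unique(c(printed, extra)))
}

#' Steady-state dose sweep of the circuit
#'
#' For each dose, pre-equilibrates the circuit at stimulus 0, then either
#' integrates deterministically to \code{tEnd} (default 1,440 min) or runs a
#' stochastic ensemble ([runEnsemble()]) and records the terminal mean and SD
#' of every state variable.
#'
#' @inheritParams circuitRHS
#' @param doses strictly increasing dimensionless stimulus grid.
#' @param noise optional [NoiseConfig-class]; \code{NULL} for the
#'   deterministic sweep.
#' @param tEnd evaluation time (min).
#' @return a [DoseResponseCurve-class] object.
#' @export
doseSweep <- function(params, doses = defaultDoseGrid(),
                      variant = c("coupled", "uncoupled", "giv_depleted"),
                      gate = c("AND", "OR"), noise = NULL, tEnd = 1440) {
  variant <- match.arg(variant)
  gate <- match.arg(gate)
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  basal <- preEquilibrate(params, variant, gate, stimulus = 0)
  nv <- length(.STATE_VARS)
  mu <- matrix(NA_real_, length(doses), nv, dimnames = list(NULL, .STATE_VARS))
  sdm <- matrix(0, length(doses), nv, dimnames = list(NULL, .STATE_VARS))
  for (i in seq_along(doses)) {
    res <- tryCatch({
      if (is.null(noise)) {
        tc <- simulateCircuit(params, doses[i], variant, gate,
                              times = c(0, tEnd / 2, tEnd), init = basal)
        list(mean = tc@states[nrow(tc@states), ], sd = rep(0, nv))
      } else {
        es <- runEnsemble(params, doses[i], variant, gate, noise,
                          init = basal, evaluationTime = tEnd)
        list(mean = es@mean, sd = es@sd)
      }
    }, error = function(e)
      stop("dose sweep failed at dose ", doses[i], ": ", conditionMessage(e)))
    mu[i, ] <- res$mean
    sdm[i, ] <- res$sd
  }
  new("DoseResponseCurve", doses = doses, mean = mu, sd = sdm,
      variant = variant, gate = gate, stochastic = !is.null(noise))
}

#' @describeIn DoseResponseCurve-class data.frame view (one row per dose)
#' @export
setMethod("asDataFrame", "DoseResponseCurve", function(x) {
  df <- data.frame(dose = x@doses)
  for (v in colnames(x@mean)) {
    df[[paste0(v, "_mean")]] <- x@mean[, v]
    df[[paste0(v, "_sd")]] <- x@sd[, v]
  }
  df
})

#' @describeIn DoseResponseCurve-class compact display
#' @param object a \code{DoseResponseCurve} object.
#' @export
setMethod("show", "DoseResponseCurve", function(object) {
  cat("DoseResponseCurve:", length(object@doses), "doses in [",
      min(object@doses), ",", max(object@doses), "], variant =",
      object@variant, ",", if (object@stochastic) "stochastic" else
      "deterministic", "\n")
  invisible(NULL)
})

.rss <- function(y, f) sum((y - f)^2)

#' Fit a Hill curve to dose-response data
#'
#' Nonlinear least-squares fit of \eqn{y = a\,x^n/(x^n + K) + d} from
#' multiple starting points (n in {0.5, 1, 2, 4} crossed with K built from
#' the quartiles of x), keeping the best residual and breaking ties toward
#' the smaller n. The offset d is retained only when it reduces the residual
#' sum of squares by more than 1% relative to the no-offset fit
#' (\code{includeOffset = "auto"}).
#'
#' @param x numeric vector of inputs (>= 0), at least 4 points.
#' @param y numeric response vector of the same length.
#' @param includeOffset \code{"auto"} (default), \code{"always"} or
#'   \code{"never"}.
#' @return a [HillFit-class] object.
#' @examples
#' x <- seq(0, 1, length.out = 20)
#' f <- fitHill(x, x^2 / (x^2 + 0.01))
#' c(f@n, f@K, f@r2)
#' @export
fitHill <- function(x, y, includeOffset = c("auto", "always", "never")) {
  includeOffset <- match.arg(includeOffset)
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("at least 4 points are required")
  if (any(x < 0)) stop("x must be >= 0")
  fitOne <- function(withOffset) .fitHillMultistart(x, y, withOffset)
  best <- switch(includeOffset,
    never  = fitOne(FALSE),
    always = fitOne(TRUE),
    auto   = {
      f0 <- fitOne(FALSE)
      f1 <- fitOne(TRUE)
      if (!is.null(f1) && (is.null(f0) || f1$rss < 0.99 * f0$rss)) f1 else f0
    })
  if (is.null(best))
    stop("Hill fit did not converge from any of the tried starts")
  pred <- best$a * x^best$n / (x^best$n + best$K) + best$d
  tss <- .rss(y, mean(y))
  r2 <- if (tss > 0) 1 - .rss(y, pred) / tss else NA_real_
  new("HillFit", a = best$a, n = best$n, K = best$K, d = best$d,
      r2 = r2, offsetUsed = best$d != 0)
}

.fitHillMultistart <- function(x, y, withOffset) {
  xq <- quantile(x[x > 0], c(0.25, 0.5, 0.75), names = FALSE)
  amp <- max(y) - min(y)
  if (amp <= 0) amp <- max(abs(y), 1)
  best <- NULL
  for (n0 in c(0.5, 1, 2, 4)) {
    for (x50 in xq) {
      st <- list(a = amp, n = n0, K = x50^n0)
      if (withOffset) st$d <- min(y)
      fml <- if (withOffset) y ~ a * x^n / (x^n + K) + d
             else y ~ a * x^n / (x^n + K)
      fit <- tryCatch(
        minpack.lm::nlsLM(fml, data = data.frame(x = x, y = y), start = st,
                          lower = if (withOffset) c(-Inf, 1e-6, 1e-12, -Inf)
                                  else c(-Inf, 1e-6, 1e-12),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      cf <- as.list(coef(fit))
      if (!("d" %in% names(cf))) cf$d <- 0
      pr <- cf$a * x^cf$n / (x^cf$n + cf$K) + cf$d
      rss <- .rss(y, pr)
      better <- is.null(best) || rss < best$rss * (1 - 1e-9) ||
        (abs(rss - best$rss) <= best$rss * 1e-9 && cf$n < best$n)
      if (better)
        best <- list(a = cf$a, n = cf$n, K = cf$K, d = cf$d, rss = rss)
    }
  }
  best
}

#' @describeIn HillFit-class compact display
#' @param object a \code{HillFit} object.
#' @export
setMethod("show", "HillFit", function(object) {
  cat(sprintf(
    "HillFit: a = %.4g, n = %.3f, K = %.4g (half-max x = %.4g), d = %.4g, r2 = %.4f\n",
    object@a, object@n, object@K, object@K^(1 / object@n), object@d,
    object@r2))
  invisible(NULL)
})

#' Ordinary least-squares linear fit with R-squared
#'
#' @param x numeric predictor, at least 2 points, not all equal.
#' @param y numeric response.
#' @return list with \code{slope}, \code{intercept}, \code{r2}.
#' @export
fitLinear <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("at least 2 points are required")
  if (var(x) == 0) stop("degenerate x: all values equal")
  fit <- lm(y ~ x)
  pred <- fitted(fit)
  tss <- .rss(y, mean(y))
  r2 <- if (tss > 0) 1 - .rss(y, pred) / tss else NA_real_
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r2 = r2)
}

#' Dose-response alignment (DoRA) report
#'
#' Bundles steady-state dose sweeps under the coupled and single-switch
#' (uncoupled) variants and fits the four standard upstream-downstream pairs:
#' mGEF vs mG* (linear fit; DoRA implies linearity), tGEF vs tG*, EGF
#' (stimulus) vs tG*, and stimulus vs secretion S (all Hill fits).
#' Fractional-activation means are used on both axes.
#'
#' @inheritParams doseSweep
#' @param variants character vector of variants to sweep.
#' @return a list with one entry per variant, each containing the
#'   [DoseResponseCurve-class] \code{curve}, the linear fit of (mGEF, mG*)
#'   and the [HillFit-class] objects for (tGEF, tG*), (stimulus, tG*) and
#'   (stimulus, S).
#' @export
doraReport <- function(params, doses = defaultDoseGrid(), noise = NULL,
                       gate = "AND", variants = c("coupled", "uncoupled")) {
  out <- list()
  for (v in variants) {
    curve <- doseSweep(params, doses, v, gate, noise)
    m <- curve@mean
    pairFits <- list(
      mGEF_mGstar = fitLinear(m[, "mGEF"], m[, "mGstar"]),
      tGEF_tGstar = tryCatch(fitHill(m[, "tGEF"], m[, "tGstar"]),
                             error = function(e) NULL),
      stimulus_tGstar = tryCatch(fitHill(curve@doses, m[, "tGstar"]),
                                 error = function(e) NULL),
      stimulus_S = tryCatch(fitHill(curve@doses, m[, "S"]),
                            error = function(e) NULL)
    )
    out[[v]] <- c(list(curve = curve), pairFits)
  }
  out
}
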