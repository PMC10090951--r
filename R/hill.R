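#' Normalized-Hill constants
#'
#' Computes the two constants of the normalized Hill function,
#' \eqn{B = (EC_{50}^n - 1)/(2\,EC_{50}^n - 1)} and \eqn{K = (B - 1)^{1/n}},
#' chosen so that the activation function satisfies \code{fact(0) = 0},
#' \code{fact(EC50) = 0.5} and \code{fact(1) = 1}.
#'
#' The constants are real and positive only when \eqn{EC_{50}^n < 0.5}; other
#' parameter combinations are degenerate (zero denominator at
#' \eqn{EC_{50}^n = 0.5}, complex \eqn{K} beyond) and raise an error.
#'
#' @param ec50 half-maximal activation on the fractional scale, in (0, 1).
#' @param n Hill coefficient, > 0.
#' @return list with components \code{B} and \code{K}.
#' @examples
#' hillConstants(0.5, 2) # B = 1.5, K = sqrt(0.5)
#' @export
hillConstants <- function(ec50, n) {
  stopifnot(is.numeric(ec50), length(ec50) == 1L, is.numeric(n), length(n) == 1L)
  if (!is.finite(ec50) || ec50 <= 0 || ec50 >= 1)
    stop("ec50 must lie in (0, 1)")
  if (!is.finite(n) || n <= 0)
    stop("Hill coefficient n must be > 0")
  en <- ec50^n
  if (abs(2 * en - 1) < 1e-12)
    stop("degenerate Hill parameters: ec50^n = 0.5 (zero denominator for B)")
  B <- (en - 1) / (2 * en - 1)
  if (B <= 1)
    stop("degenerate Hill parameters: B <= 1 so K is not real ",
         "(requires ec50^n < 0.5)")
  K <- (B - 1)^(1 / n)
  list(B = B, K = K)
}

#' Normalized Hill activation function
#'
#' Evaluates the normalized Hill function
#' \eqn{f(x) = B x^n / (K^n + x^n)} for \eqn{0 \le x < 1}, saturating at
#' exactly 1 for \eqn{x \ge 1}. Inputs below 0 (which can arise transiently
#' under additive noise) return 0, keeping the output within [0, 1].
#'
#' @param x numeric vector of fractional inputs.
#' @inheritParams hillConstants
#' @return numeric vector of activations in [0, 1].
#' @examples
#' normalizedHill(c(0, 0.5, 1), ec50 = 0.5, n = 2)
#' @export
normalizedHill <- function(x, ec50, n) {
  bk <- hillConstants(ec50, n)
  .normalizedHillBK(x, bk$B, bk$K, n)
}

## inner evaluation with precomputed constants; reused by the ODE right-hand
## sides where recomputing B and K per call would dominate the cost
.normalizedHillBK <- function(x, B, K, n) {
  out <- numeric(length(x))
  mid <- is.finite(x) & x > 0 & x < 1
  out[x >= 1] <- 1
  xm <- x[mid]
  out[mid] <- B * xm^n / (K^n + xm^n)
  out[!is.finite(x)] <- NA_real_
  out
}

## per-parameter-set table of the nine (B, K, n) triples
.hillTable <- function(p) {
  B <- numeric(9); K <- numeric(9)
  for (i in 1:9) {
    bk <- hillConstants(p@ec50[[i]], p@hillN[[i]])
    B[i] <- bk$B; K[i] <- bk$K
  }
  list(B = B, K = K, n = unname(p@hillN))
}

## fact_i with precomputed table
.fact <- function(i, x, tab) .normalizedHillBK(x, tab$B[i], tab$K[i], tab$n[i])

#' mGAP production drive from the two feedback arrows
#'
#' Combines the tGEF and active-tGTPase feedback onto mGAP under AND logic,
#' \code{fact2(tGEF) * fact3(tGstar)}, or OR logic,
#' \code{c_tGEF * fact2(tGEF) + c_tGstar * fact3(tGstar)}, where the two
#' rescaling constants (defaults 0.24 and 0.0017) are chosen so that the basal
#' steady states of all species agree between the two gates.
#'
#' @param tGEF fractional activation of the tGTPase GEF (GIV).
#' @param tGstar fractional activation of the tGTPase.
#' @param params a [CircuitParameters-class] object.
#' @param gate \code{"AND"} or \code{"OR"}.
#' @return dimensionless production drive.
#' @export
mgapDrive <- function(tGEF, tGstar, params, gate = c("AND", "OR")) {
  gate <- match.arg(gate)
  stopifnot(all(is.finite(tGEF)), all(is.finite(tGstar)))
  tab <- .hillTable(params)
  .mgapDriveTab(tGEF, tGstar, tab, gate, params@orGate)
}

.mgapDriveTab <- function(tGEF, tGstar, tab, gate, orGate) {
  f2 <- .fact(2L, tGEF, tab)
  f3 <- .fact(3L, tGstar, tab)
  if (gate == "AND") f2 * f3
  else orGate[["c_tGEF"]] * f2 + orGate[["c_tGstar"]] * f3
}
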