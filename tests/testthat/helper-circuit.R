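# shared fixtures: the bundled parameter set, cached basal states, and an
# independent fixed-step RK4 integrator used as a brute-force oracle

testParams <- function() defaultCircuitParameters()

# cache expensive shared objects across test files within one run
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

basalState <- function(variant = "coupled", gate = "AND") {
  cached(paste("basal", variant, gate, sep = "."),
         preEquilibrate(testParams(), variant, gate, stimulus = 0))
}

# independent RK4 reference integrator built directly on circuitRHS
rk4Integrate <- function(params, stimulus, variant, gate, init, tEnd, dt) {
  nSteps <- round(tEnd / dt)
  y <- as.numeric(init)
  out <- matrix(NA_real_, nSteps + 1L, 7L)
  out[1L, ] <- y
  f <- function(y) as.numeric(circuitRHS(y, stimulus, params, variant, gate))
  for (i in seq_len(nSteps)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- y
  }
  colnames(out) <- c("mGEF", "mGAP", "mGstar", "tGEF", "tGstar", "S", "X")
  list(time = seq(0, tEnd, by = dt), states = out)
}

# random valid normalized-Hill parameters (ec50^n < 0.5 required)
randomHillParams <- function(n = 1L) {
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    ec50 <- runif(1, 0.05, 0.9)
    hn <- runif(1, 0.5, 6)
    if (ec50^hn < 0.49) {
      out[[i]] <- list(ec50 = ec50, n = hn)
      i <- i + 1L
    }
  }
  out
}
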