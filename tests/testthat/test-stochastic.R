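# R-side fixed-step Euler reference for the noise-free circuit, independent
# of the compiled engine
eulerReference <- function(params, stimulus, variant, gate, init, tEnd, dt) {
  nSteps <- round(tEnd / dt)
  y <- as.numeric(init)
  out <- matrix(NA_real_, nSteps + 1L, 7L)
  out[1L, ] <- y
  for (i in seq_len(nSteps)) {
    y <- y + dt * as.numeric(circuitRHS(y, stimulus, params, variant, gate))
    out[i + 1L, ] <- y
  }
  out
}

test_that("the OU update has the printed deterministic and degenerate limits", {
  # sigma = 0: pure decay eta (1 - dt)
  expect_equal(ouUpdate(0.5, sigma = 0, dt = 0.01, dW = 0.3), 0.5 * 0.99,
               tolerance = 1e-15)
  # both schemes coincide when dW^2 = dt
  dW <- sqrt(0.01)
  expect_equal(ouUpdate(0.2, 0.05, 0.01, dW, scheme = "as_printed"),
               ouUpdate(0.2, 0.05, 0.01, dW, scheme = "euler_maruyama"),
               tolerance = 1e-15)
})

test_that("OU stationary statistics match sigma^2 / (2 tau) for both schemes", {
  dt <- 0.01
  nSteps <- 1e6
  for (scheme in c("as_printed", "euler_maruyama")) {
    set.seed(8)
    dW <- rnorm(nSteps, 0, sqrt(dt))
    incr <- 0.02 * dW +
      if (scheme == "as_printed") 0.5 * 0.02^2 * (dW^2 - dt) else 0
    # eta_{n+1} = eta_n (1 - dt) + incr_n : linear recursion
    eta <- stats::filter(incr, 1 - dt, method = "recursive")
    eta <- eta[-(1:1000)]  # discard burn-in
    expect_lt(abs(mean(eta)), 3 * sd(eta) / sqrt(nSteps * dt)) # ~zero mean
    expect_equal(var(eta), 0.02^2 / 2, tolerance = 0.05)
  }
})

test_that("noise-off stochastic engine equals the R Euler reference exactly", {
  p <- testParams()
  init <- basalState()
  nc <- noiseConfig("stimulus_and_species",
                    sigmaSti = 0,
                    sigmaSpe = setNames(rep(0, 8),
                                        c("mGEF","mGAP","mGstar","tGEF",
                                          "tGstar","S","X","tGAP")),
                    dt = 0.01, nRuns = 2L, seed = 1L)
  tc <- simulateStochastic(p, 0.23, "coupled", "AND", nc, init = init,
                           tEnd = 5, recordEvery = 100L)
  ref <- eulerReference(p, 0.23, "coupled", "AND", init, tEnd = 5, dt = 0.01)
  refSub <- ref[seq(1, 501, by = 100), ]
  expect_equal(unname(tc@states), unname(refSub), tolerance = 1e-12)
})

test_that("identical seeds give bit-identical trajectories and summaries", {
  p <- testParams()
  init <- basalState()
  nc <- noiseConfig("stimulus_and_connections", nRuns = 4L, seed = 17L,
                    dt = 0.02)
  a <- simulateStochastic(p, 0.23, "coupled", "AND", nc, init = init,
                          tEnd = 10, recordEvery = 50L)
  b <- simulateStochastic(p, 0.23, "coupled", "AND", nc, init = init,
                          tEnd = 10, recordEvery = 50L)
  expect_identical(a@states, b@states)

  esA <- suppressWarnings(runEnsemble(p, 0.23, "coupled", "AND", nc,
                                      init = init, evaluationTime = 10))
  esB <- suppressWarnings(runEnsemble(p, 0.23, "coupled", "AND", nc,
                                      init = init, evaluationTime = 10))
  expect_identical(esA@mean, esB@mean)
  expect_identical(esA@sd, esB@sd)
})

test_that("ensemble SD uses the N-1 denominator and zero noise gives zero SD", {
  # the SD formula on the toy sample {1, 2, 3} is 1
  expect_equal(sd(c(1, 2, 3)), 1)

  p <- testParams()
  init <- basalState()
  nc0 <- noiseConfig("stimulus_only", sigmaSti = 0, nRuns = 3L, seed = 2L,
                     dt = 0.05)
  es <- runEnsemble(p, 0.23, "coupled", "AND", nc0, init = init,
                    evaluationTime = 20)
  expect_true(all(es@sd == 0))
})

test_that("stimulus-noise ensemble mean tracks the deterministic steady state", {
  p <- testParams()
  init <- basalState()
  nc <- noiseConfig("stimulus_only", nRuns = 40L, seed = 5L, dt = 0.02)
  es <- cached("ensemble.mean.check",
               runEnsemble(p, 0.23, "coupled", "AND", nc, init = init,
                           evaluationTime = 400))
  det <- simulateCircuit(p, 0.23, "coupled", "AND",
                         times = c(0, 200, 400), init = init)
  target <- det@states[nrow(det@states), ]
  for (v in c("mGEF", "mGstar", "tGstar")) {
    se <- es@sd[[v]] / sqrt(es@nRuns)
    expect_lt(abs(es@mean[[v]] - target[[v]]), max(3 * se, 0.02 * target[[v]]))
  }
})
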