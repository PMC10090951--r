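test_that("normalized RMSE matches hand arithmetic and is scale-free", {
  expect_identical(normalizedRMSE(c(1, 2), c(1, 2)), 0)
  expect_equal(normalizedRMSE(c(1, 3), c(2, 2)), 0.5, tolerance = 1e-12)
  set.seed(4)
  sim <- runif(10); dat <- runif(10, 0.5, 1.5)
  expect_equal(normalizedRMSE(3.7 * sim, 3.7 * dat),
               normalizedRMSE(sim, dat), tolerance = 1e-12)
  expect_error(normalizedRMSE(c(1, -1), c(1, -1)), "zero")
})

test_that("r squared covers the perfect, mean and negative cases", {
  obs <- c(0.2, 0.8, 1.4, 2.2)
  expect_equal(rSquared(obs, obs), 1, tolerance = 1e-12)
  expect_equal(rSquared(obs, rep(mean(obs), 4)), 0, tolerance = 1e-12)
  expect_equal(rSquared(c(0, 1), c(1, 0)), -3, tolerance = 1e-12)
  expect_error(rSquared(rep(1, 3), 1:3), "zero variance")
})

test_that("r squared and normalized RMSE agree with spreadsheet-style recomputation", {
  set.seed(11)
  for (i in 1:5) {
    obs <- runif(8, 0.5, 3); pred <- obs + rnorm(8, 0, 0.3)
    r2Hand <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    nrHand <- sqrt(sum((pred - obs)^2) / 8) / (sum(obs) / 8)
    expect_equal(rSquared(obs, pred), r2Hand, tolerance = 1e-12)
    expect_equal(normalizedRMSE(pred, obs), nrHand, tolerance = 1e-12)
  }
})

test_that("exponential fitting recovers saturating kinetics", {
  t <- c(0, 1, 2, 4, 8)
  y <- 1 - exp(-t)
  f <- fitExponential(t, y)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)
  expect_equal(f$rate, 1, tolerance = 1e-6)
  expect_equal(f$offset, 0, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)

  t2 <- seq(0, 30, by = 5)
  y2 <- 0.6 * (1 - exp(-0.2 * t2)) + 0.04
  f2 <- fitExponential(t2, y2)
  expect_equal(f2$amplitude, 0.6, tolerance = 1e-5)
  expect_equal(f2$rate, 0.2, tolerance = 1e-5)

  expect_warning(fflat <- fitExponential(t, rep(2, 5)), "flat")
  expect_true(fflat$degenerate)
  expect_equal(fflat$amplitude, 0)
})

test_that("fold change normalizes a trace to its baseline", {
  p <- testParams()
  tc <- simulateCircuit(p, 0, "coupled", "AND", times = c(0, 10, 20),
                        init = basalState())
  expect_equal(unname(foldChange(tc, "mGstar")), rep(1, 3), tolerance = 1e-6)
})

test_that("dataset CSV round-trips through the documented columns", {
  ds <- list(
    timeCourseDataset(c(0, 5, 15, 30), c(1, 3, 2, 1.4), c(0, .2, .2, .1),
                      "control", "mGstar"),
    timeCourseDataset(seq(0, 30, 5), seq(1, 2.2, length.out = 7),
                      rep(.1, 7), "giv_depleted", "tGstar"))
  path <- tempfile(fileext = ".csv")
  writeTimeCourseDatasets(ds, path)
  back <- readTimeCourseDatasets(path)
  expect_length(back, 2L)
  conds <- vapply(back, function(d) d@condition, "")
  ctrl <- back[[which(conds == "control")]]
  expect_equal(ctrl@mean, ds[[1]]@mean)
  expect_equal(ctrl@sem, ds[[1]]@sem)
})

test_that("fitting noiseless self-generated data is self-consistent", {
  p <- testParams()
  syn <- syntheticTimecourses(p, noiseScale = 0, seed = 1)
  fit <- fitParameters(syn$datasets, p, freeParams = character(),
                       budget = 1L, strict = TRUE)
  expect_true(all(fit@pass))
  expect_true(all(fit@nrmse < 1e-6))
  expect_true(all(fit@r2 > 1 - 1e-8))
})

test_that("frozen wrong parameters raise a no-feasible-point error", {
  p <- testParams()
  syn <- syntheticTimecourses(p, noiseScale = 0, seed = 1)
  wrong <- coupledGTPase:::.setParam(p, "tau_mGAP",
                                     coupledGTPase:::.getParam(p, "tau_mGAP") * 20)
  wrong <- coupledGTPase:::.setParam(wrong, "k_mGstar",
                                     coupledGTPase:::.getParam(p, "k_mGstar") * 8)
  expect_error(
    fitParameters(syn$datasets, wrong, freeParams = character(),
                  budget = 1L, strict = TRUE),
    "no feasible point")
})

test_that("threshold pass flags use the strict printed cutoffs", {
  p <- testParams()
  ds <- timeCourseDataset(c(0, 5, 15, 30), c(1, 3, 2, 1.4),
                          rep(0.1, 4), "control", "mGstar")
  fit <- fitParameters(list(ds), p, freeParams = character(), budget = 1L,
                       strict = FALSE)
  expect_identical(unname(fit@pass), unname(fit@nrmse < fit@thresholds))
})
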