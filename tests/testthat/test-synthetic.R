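test_that("zero-noise synthetic datasets equal the deterministic fold-change traces", {
  p <- testParams()
  syn <- cached("syn.noiseless", syntheticTimecourses(p, noiseScale = 0))
  for (key in names(syn$datasets)) {
    d <- syn$datasets[[key]]
    expect_equal(unname(d@mean), unname(syn$truth[[key]]), tolerance = 1e-10,
                 label = key)
    expect_true(all(d@sem == 0))
  }
})

test_that("control mG* peaks at 5 min and declines; GIV-depleted stays sustained", {
  syn <- cached("syn.default", syntheticTimecourses(testParams(), seed = 1))
  ctrl <- syn$datasets[["control_mGstar"]]
  expect_equal(ctrl@time, c(0, 5, 15, 30))
  expect_equal(which.max(ctrl@mean), 2L)           # the 5-min point
  expect_lt(ctrl@mean[4L], max(ctrl@mean))         # declined by 30 min
  expect_gt(ctrl@mean[2L], 2)                      # strong activation peak

  dep <- syn$datasets[["giv_depleted_mGstar"]]
  i5 <- which(dep@time == 5); i15 <- which(dep@time == 15)
  expect_gte(dep@mean[i15], 0.9 * dep@mean[i5])    # sustained

  tg <- syn$datasets[["control_tGstar"]]
  expect_gt(tg@mean[length(tg@mean)], tg@mean[1L]) # activated by 30 min
})

test_that("baselines are pinned at fold change 1", {
  syn <- cached("syn.default", syntheticTimecourses(testParams(), seed = 1))
  for (d in syn$datasets) {
    expect_identical(d@mean[1L], 1)
    expect_identical(d@sem[1L], 0)
  }
})

test_that("generation is reproducible under a fixed seed", {
  a <- syntheticTimecourses(testParams(), seed = 33)
  b <- syntheticTimecourses(testParams(), seed = 33)
  for (key in names(a$datasets)) {
    expect_identical(a$datasets[[key]]@mean, b$datasets[[key]]@mean)
    expect_identical(a$datasets[[key]]@sem, b$datasets[[key]]@sem)
  }
})

test_that("replicate SEM scales as noiseScale * mean / sqrt(n)", {
  # large replicate count pins the empirical SEM to its expectation
  syn <- syntheticTimecourses(testParams(), noiseScale = 0.1,
                              nReplicates = 400L, seed = 21)
  d <- syn$datasets[["control_mGstar"]]
  truth <- syn$truth[["control_mGstar"]]
  idx <- which(d@time > 0)
  expect_equal(unname(d@sem[idx]),
               unname(0.1 * truth[idx] / sqrt(400)),
               tolerance = 0.2)

  # and averaging SEM/mean over repeated small-n regenerations matches too
  ratios <- vapply(1:20, function(s) {
    g <- syntheticTimecourses(testParams(), noiseScale = 0.1,
                              nReplicates = 3L, seed = 100 + s)
    dd <- g$datasets[["control_mGstar"]]
    mean(dd@sem[-1L] / dd@mean[-1L])
  }, numeric(1))
  expect_equal(mean(ratios), 0.1 / sqrt(3), tolerance = 0.2)
})

test_that("fitted trajectories recover the ground truth under SEM-level noise", {
  p <- testParams()
  syn <- cached("syn.default", syntheticTimecourses(p, seed = 1))
  # fitting from the truth with a modest free set must stay near the truth
  fit <- cached("fit.recovery",
                fitParameters(syn$datasets, p,
                              freeParams = c("k_mGstar", "tau_mGAP"),
                              budget = 60L, seed = 2L, strict = FALSE))
  for (key in names(syn$truth)) {
    d <- syn$datasets[[key]]
    pred <- coupledGTPase:::.predictDataset(fit@parameters, d, 0.23)
    expect_lt(normalizedRMSE(pred, unname(syn$truth[[key]])), 0.1)
  }
})
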