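test_that("predictRelease evaluates the four laws and passes the origin", {
  expect_equal(predictRelease("zero_order", c(K0 = 0.246), 10), 2.46)
  expect_equal(predictRelease("first_order", c(K1 = 0.002), 0), 0)
  expect_equal(predictRelease("korsmeyer_peppas", c(KP = 1.192, n = 0.650), 1),
               1.192)
  for (m in names(releaseTruth))
    expect_equal(predictRelease(m, releaseTruth[[m]], 0), 0)
})

test_that("predictRelease rejects invalid arguments", {
  expect_error(predictRelease("weibull", c(K0 = 1), 1),
               class = "invalidArgumentError")
  expect_error(predictRelease("zero_order", c(K0 = 1), -1),
               class = "invalidArgumentError")
  expect_error(predictRelease("zero_order", c(K1 = 1), 1),
               class = "invalidArgumentError")
  expect_error(predictRelease("korsmeyer_peppas", c(KP = 1), 1),
               class = "invalidArgumentError")
  expect_error(predictRelease("korsmeyer_peppas", c(KP = 1, n = 0.5, K0 = 1), 1),
               class = "invalidArgumentError")
  expect_error(predictRelease("zero_order", c(K0 = -0.1), 1),
               class = "invalidArgumentError")
  expect_error(predictRelease("korsmeyer_peppas", c(KP = 1, n = 2.5), 1),
               class = "invalidArgumentError")
})

test_that("release is non-decreasing in time for positive constants", {
  grid <- seq(0, 24, by = 0.25)
  for (m in names(releaseTruth)) {
    f <- predictRelease(m, releaseTruth[[m]], grid)
    expect_true(all(diff(f) >= 0), info = m)
  }
})

test_that("Korsmeyer-Peppas degenerates to zero-order (n=1) and Higuchi (n=0.5)", {
  t <- seq(0, 12, by = 0.5)
  expect_equal(predictRelease("korsmeyer_peppas", c(KP = 0.7, n = 1), t),
               predictRelease("zero_order", c(K0 = 0.7), t))
  expect_equal(predictRelease("korsmeyer_peppas", c(KP = 2.3, n = 0.5), t),
               predictRelease("higuchi", c(KH = 2.3), t))
})

test_that("rSquared matches its definition including degenerate directions", {
  obs <- c(1, 2, 4)
  expect_equal(rSquared(obs, obs), 1)
  expect_equal(rSquared(obs, rep(mean(obs), 3)), 0)
  # anti-correlated 3-point toy series: SS_res/SS_tot computed by hand
  obs2 <- c(1, 2, 3); pred2 <- c(3, 2, 1)
  expect_equal(rSquared(obs2, pred2), 1 - 8 / 2)   # = -3
  expect_lt(rSquared(obs2, pred2), 0)
  expect_error(rSquared(1:3, 1:4), class = "invalidArgumentError")
  expect_error(rSquared(c(2, 2, 2), c(1, 2, 3)),
               class = "invalidArgumentError")
})

test_that("noiseless profiles return the generating constants", {
  t <- 1:12
  for (m in names(releaseTruth)) {
    prof <- simulateDissolution(m, releaseTruth[[m]], t)
    fit <- fitKineticModel(prof, m)
    expect_equal(constants(fit), releaseTruth[[m]], tolerance = 1e-6)
    expect_equal(rSquaredValue(fit), 1, tolerance = 1e-9)
  }
})

test_that("fitting rejects degenerate or undersized profiles", {
  flat <- DissolutionProfile(1:12, rep(0, 12))
  expect_error(fitKineticModel(flat, "zero_order"),
               class = "fitFailureError")
  two <- DissolutionProfile(1:2, c(0.01, 0.02))
  expect_error(fitKineticModel(two, "zero_order"),
               class = "invalidArgumentError")
  expect_error(fitKineticModel(flat, "nope"),
               class = "invalidArgumentError")
})

test_that("recovered parameters converge as noise shrinks", {
  t <- 1:12
  err <- vapply(c(1e-2, 1e-3, 1e-4), function(sigma) {
    prof <- simulateDissolution("korsmeyer_peppas", c(KP = 1.192, n = 0.650),
                                t, noiseSd = sigma, seed = 42)
    fit <- fitKineticModel(prof, "korsmeyer_peppas")
    abs(constants(fit)[["n"]] - 0.650) / 0.650
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("nonlinear Korsmeyer-Peppas fit agrees with a grid-search oracle", {
  t <- 1:8
  prof <- simulateDissolution("korsmeyer_peppas", c(KP = 1.0, n = 0.7),
                              t, noiseSd = 2e-3, seed = 11)
  y <- 100 * releasedFraction(prof)
  grid <- expand.grid(KP = seq(0.5, 1.5, by = 0.01),
                      n = seq(0.4, 1.0, by = 0.01))
  sse <- mapply(function(kp, n) sum((y - kp * t^n)^2), grid$KP, grid$n)
  oracle <- grid[which.min(sse), ]
  fit <- constants(fitKineticModel(prof, "korsmeyer_peppas"))
  expect_lt(abs(fit[["KP"]] - oracle$KP), 0.011)
  expect_lt(abs(fit[["n"]] - oracle$n), 0.011)
})

test_that("model selection maximizes R² and breaks ties by parsimony", {
  fits <- list(fitShell("zero_order", 0.852), fitShell("first_order", 0.899),
               fitShell("higuchi", 0.969), fitShell("korsmeyer_peppas", 0.974))
  expect_equal(bestModel(selectModel(fits)), "korsmeyer_peppas")

  fits2 <- list(fitShell("zero_order", 0.993), fitShell("first_order", 0.990))
  expect_equal(bestModel(selectModel(fits2)), "zero_order")

  tie <- list(fitShell("korsmeyer_peppas", 0.95), fitShell("higuchi", 0.95))
  expect_equal(bestModel(selectModel(tie)), "higuchi")

  expect_error(selectModel(fits[1]), class = "invalidArgumentError")
  expect_error(selectModel(list(fitShell("higuchi", 0.9),
                                fitShell("higuchi", 0.8))),
               class = "invalidArgumentError")
})

test_that("detection limits follow the 3.3/10 sigma-over-slope convention", {
  expect_equal(lodLoq(0, 1), c(lod = 0, loq = 0))
  expect_equal(lodLoq(1, 10), c(lod = 0.33, loq = 1.0))
  lim <- lodLoq(sigma = 0.00944 * 225.19 / 3.3, slope = 225.19)
  expect_equal(unname(lim[["lod"]]), 0.00944)
  expect_equal(signif(lim[["loq"]], 3), 0.0286)
  # the LOQ/LOD ratio is structural
  lim2 <- lodLoq(0.37, 4.2)
  expect_equal(unname(lim2[["loq"]] / lim2[["lod"]]), 10 / 3.3)
  expect_error(lodLoq(1, 0), class = "invalidArgumentError")
})

test_that("calibration fitting recovers a linear assay and feeds lodLoq", {
  set.seed(5)
  conc <- seq(0.25, 2, by = 0.25)
  resp <- 225.19 * conc + 0.1074 + rnorm(length(conc), 0, 0.5)
  cal <- fitCalibration(conc, resp)
  expect_equal(cal@slope, 225.19, tolerance = 0.01)
  lim <- lodLoq(cal)
  expect_equal(unname(lim[["loq"]] / lim[["lod"]]), 10 / 3.3)
})
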