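test_that("initial-volume dropping trims data, mask and motion consistently", {
  run <- RunTimeSeries(matrix(rnorm(120 * 3), 120, 3), tr = 2)
  mot <- simulateMotion(120, spikeRate = 0, seed = 1)$motion
  out <- dropInitialVolumes(run, censorConfig(), motion = mot)
  expect_equal(nrow(seriesData(out$run)), 116L)
  expect_equal(nrow(out$motion), 116L)
  expect_equal(length(censorMask(out$run)), 116L)

  same <- dropInitialVolumes(run, 0)
  expect_equal(seriesData(same), seriesData(run))
  expect_error(dropInitialVolumes(RunTimeSeries(matrix(0, 3, 1), tr = 2),
                                  censorConfig()), "cannot drop")
})

test_that("the nuisance set holds 12 motion regressors plus a ventricle signal", {
  mot <- matrix(rnorm(50 * 6), 50, 6,
                dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                        "rot_x", "rot_y", "rot_z")))
  ns <- buildNuisanceSet(mot, seed = 1)
  expect_equal(ncol(ns$design), 13L)
  expect_equal(ncol(ns$motionDerivatives), 6L)

  # derivative of a constant column is all zero; backward difference of 0,1,3
  const <- matrix(1, 4, 6)
  const[, 1] <- c(0, 1, 3, 3)
  ns2 <- buildNuisanceSet(const, ventricleSignal = rep(0, 4))
  expect_equal(unname(ns2$motionDerivatives[, 2]), rep(0, 4))
  expect_equal(unname(ns2$motionDerivatives[, 1]), c(0, 1, 2, 0))

  expect_error(buildNuisanceSet(mot[, 1:5]), "6 columns")
})

test_that("nuisance regression projects out the design exactly", {
  set.seed(2)
  mot <- matrix(rnorm(40 * 6), 40, 6)
  ns <- buildNuisanceSet(mot, ventricleSignal = rnorm(40))
  # data equal to a motion column vanishes
  run <- RunTimeSeries(cbind(a = mot[, 3], b = rnorm(40)), tr = 2)
  res <- regressNuisance(run, ns)
  expect_lt(max(abs(seriesData(res)[, 1])), 1e-10)
  # residual orthogonality to every regressor
  D <- cbind(1, ns$design)
  dots <- crossprod(D, seriesData(res))
  norms <- outer(sqrt(colSums(D^2)), sqrt(colSums(seriesData(res)^2) + 1e-30))
  expect_lt(max(abs(dots) / norms), 1e-8)

  # hat-matrix oracle on a 10-frame toy case (3 regressors so the normal
  # equations stay well posed)
  Z <- matrix(rnorm(10 * 3), 10, 3)
  y <- matrix(rnorm(10 * 2), 10, 2)
  runT <- RunTimeSeries(y, tr = 2)
  DT <- cbind(1, Z)
  H <- DT %*% solve(crossprod(DT)) %*% t(DT)
  expect_equal(seriesData(regressNuisance(runT, Z)),
               (diag(10) - H) %*% y, ignore_attr = TRUE, tolerance = 1e-8)

  # collinear columns are dropped with a warning
  bad <- cbind(ns$design, ns$design[, 1])
  expect_warning(regressNuisance(RunTimeSeries(cbind(rnorm(40)), tr = 2), bad),
                 "collinear")
})

test_that("detrending removes exactly the least-squares line", {
  n <- 60
  ramp <- RunTimeSeries(cbind(3 + 0.2 * seq_len(n)), tr = 2)
  expect_lt(max(abs(seriesData(detrendSeries(ramp)))), 1e-10)

  y <- matrix(rnorm(n * 2), n, 2)
  run <- RunTimeSeries(y, tr = 2)
  fit <- lm(y ~ seq_len(n))
  expect_equal(seriesData(detrendSeries(run)), unname(residuals(fit)),
               ignore_attr = TRUE, tolerance = 1e-10)

  sine <- sin(2 * pi * seq_len(n) / 10)
  run2 <- RunTimeSeries(cbind(sine), tr = 2)
  expect_equal(seriesData(detrendSeries(run2))[, 1], unname(residuals(lm(sine ~ seq_len(n)))),
               tolerance = 1e-10)
})

test_that("framewise displacement drives scrubbing and the run-discard rule", {
  quiet <- matrix(0, 30, 6)
  c0 <- computeCensoring(quiet)
  expect_equal(c0$nCensored, 0L)
  expect_false(c0$discardRun)

  jump <- quiet; jump[15, 1] <- 3.5
  expect_true(computeCensoring(jump)$discardRun)
  ok <- quiet; ok[15, 1] <- 2.9
  expect_false(computeCensoring(ok)$discardRun)

  # FD formula: sum of |d translations| + 50 * sum |d rotations|
  m <- quiet; m[10, ] <- c(0.1, 0.2, 0, 0.001, 0, 0.002)
  fd <- computeCensoring(m)$fd
  expect_equal(fd[10], 0.1 + 0.2 + 50 * 0.003)

  # simulated spikes are censored exactly at the spike frame and its successor
  sim <- simulateMotion(120, spikeRate = 0.05, spikeAmplitude = 0.8, seed = 5)
  cens <- computeCensoring(sim$motion)
  flagged <- which(!cens$censorMask)
  expected <- sort(unique(c(sim$spikeFrames,
                            sim$spikeFrames[sim$spikeFrames < 120] + 1)))
  expect_equal(flagged, expected)
})

test_that("spectral interpolation reconstructs in-band signal and honors its contract", {
  tr <- 2; n <- 120; t <- (seq_len(n) - 1) * tr
  x <- sin(2 * pi * 0.03 * t + 0.4)
  run <- RunTimeSeries(cbind(x), tr = tr)

  # empty mask: exact no-op
  same <- lssdInterpolate(run)
  expect_identical(seriesData(same), seriesData(run))

  mask <- rep(TRUE, n); mask[c(20, 21, 55, 80, 99)] <- FALSE
  out <- lssdInterpolate(applyCensorMask(run, mask))
  relErr <- abs(seriesData(out)[!mask, 1] - x[!mask]) / max(abs(x))
  expect_lt(max(relErr), 0.01)
  # retained frames bit-identical
  expect_identical(seriesData(out)[mask, ], seriesData(run)[mask, ])

  few <- applyCensorMask(run, c(TRUE, rep(FALSE, n - 1)))
  expect_error(lssdInterpolate(few), "retained")
})

test_that("the band-pass filter has the specified frequency response", {
  n <- 2000; tr <- 2
  flat <- RunTimeSeries(cbind(rep(1, n)), tr = tr)
  expect_lt(max(abs(seriesData(bandpassSeries(flat)))), 1e-8)

  expect_gt(probeGain(0.03), 0.95)
  expect_lt(probeGain(0.03), 1.05)
  expect_lt(probeGain(0.2), 0.1)

  # gain rises monotonically across the lower transition band and falls across
  # the upper one
  lower <- vapply(c(0.002, 0.005, 0.009, 0.02), probeGain, numeric(1))
  expect_true(all(diff(lower) > 0))
  upper <- vapply(c(0.08, 0.12, 0.2), probeGain, numeric(1))
  expect_true(all(diff(upper) < 0))

  expect_error(bandpassSeries(flat, filterSpec(highHz = 0.3)), "Nyquist")
})

test_that("censor removal applies the 3-minute retention rule inclusively", {
  run <- RunTimeSeries(matrix(rnorm(120 * 2), 120, 2), tr = 2)
  # 85 retained frames = 170 s -> excluded
  m85 <- c(rep(TRUE, 85), rep(FALSE, 35))
  r1 <- applyCensorAndRetention(applyCensorMask(run, m85))
  expect_true(r1$excluded)
  expect_null(r1$run)
  # 90 retained frames = 180 s -> retained (boundary inclusive)
  m90 <- c(rep(TRUE, 90), rep(FALSE, 30))
  r2 <- applyCensorAndRetention(applyCensorMask(run, m90))
  expect_false(r2$excluded)
  expect_equal(nrow(seriesData(r2$run)), 90L)
  # no censored frames: count unchanged
  r3 <- applyCensorAndRetention(run)
  expect_equal(nrow(seriesData(r3$run)), 120L)
})

test_that("with no censoring, interpolate-then-filter equals direct filtering exactly", {
  run <- RunTimeSeries(matrix(rnorm(150 * 3), 150, 3), tr = 2)
  via <- bandpassSeries(lssdInterpolate(run))
  direct <- bandpassSeries(run)
  expect_identical(seriesData(via), seriesData(direct))
})

test_that("pipeline steps refuse to run out of order and record provenance", {
  run <- RunTimeSeries(matrix(rnorm(120 * 2), 120, 2), tr = 2)
  bp <- bandpassSeries(run)
  expect_error(detrendSeries(bp), "cannot run after")
  expect_error(regressNuisance(bp, matrix(rnorm(120 * 3), 120, 3)),
               "cannot run after")

  mot <- simulateMotion(120, spikeRate = 0.03, spikeAmplitude = 0.8,
                        seed = 9)$motion
  pp <- preprocessRun(run, mot, seed = 10)
  expect_false(pp$discardRun)
  expect_equal(pp$steps,
               c("drop_initial", "nuisance_regression", "detrend",
                 "lssd_interpolate", "bandpass", "censor_removed"))
  expect_equal(pp$censorReport$retainedFrames + pp$censorReport$nCensored, 116)
})
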