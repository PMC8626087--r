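test_that("cohort generation has the right shape and is reproducible", {
  coh <- generateCohort(seed = 11)
  expect_equal(nrow(coh), 30)
  expect_equal(unname(table(coh$group)), rep(10L, 3), ignore_attr = TRUE)
  expect_equal(generateCohort(seed = 11), coh)

  small <- generateCohort(groups = "only", nPerGroup = 2, sessions = 1,
                          seed = 3)
  expect_equal(nrow(small), 2)
  expect_true(all(small$group == "only"))

  expect_error(generateCohort(groups = c("A", "A")), "unique")
  expect_error(generateCohort(nPerGroup = 1), "nPerGroup")
})

test_that("simulated series reproduce the target correlation structure", {
  # identity target: all empirical correlations near zero at n = 5000
  rts <- simulateRoiTimeSeries(4, nFrames = 5000, seed = 21)
  r <- cor(seriesData(rts))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # target r = 0.6 between two ROIs recovered within +/- 0.05
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.6
  rts2 <- simulateRoiTimeSeries(3, nFrames = 5000, baseCorrelation = C,
                                arCoeff = 0.3, seed = 22)
  expect_lt(abs(cor(seriesData(rts2))[1, 2] - 0.6), 0.05)

  # default run shape: 120 volumes at TR 2 s = 240 s of data
  rts3 <- simulateRoiTimeSeries(dvanRois(), seed = 23)
  expect_equal(dim(rts3), c(120L, 10L))
  expect_equal(nrow(seriesData(rts3)) * repetitionTime(rts3), 240)

  # determinism
  expect_equal(seriesData(simulateRoiTimeSeries(3, seed = 5)),
               seriesData(simulateRoiTimeSeries(3, seed = 5)))

  # non-PSD target rejected with the offending eigenvalue named
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(simulateRoiTimeSeries(3, baseCorrelation = bad),
               "eigenvalue")
})

test_that("connectivity effects are confined to the target cell", {
  base <- list(DVAN = exchangeableCorrFixture(10, 0.25),
               DMN = exchangeableCorrFixture(10, 0.25))
  eff <- effectSpec("Parietal", "DVAN", 2, deltaZ = 0.3)
  specs <- injectConnectivityEffect(base, eff)

  for (g in names(specs)) for (s in 1:2) {
    expect_equal(specs[[g]][[s]]$DMN$corr, base$DMN)
    expect_equal(max(abs(specs[[g]][[s]]$DMN$achievedDeltaZ)), 0)
  }
  expect_equal(specs$hMT[[2]]$DVAN$corr, base$DVAN)
  expect_equal(specs$Parietal[[1]]$DVAN$corr, base$DVAN)
  hit <- specs$Parietal[[2]]$DVAN
  off <- upper.tri(hit$corr)
  expect_equal(unname(hit$achievedDeltaZ[off]), rep(0.3, 45), tolerance = 1e-8)

  # zero increment leaves every spec identical to base
  specs0 <- injectConnectivityEffect(base, effectSpec(deltaZ = 0))
  for (g in names(specs0)) for (s in 1:2)
    expect_equal(specs0[[g]][[s]]$DVAN$corr, base$DVAN)
})

test_that("z increments that break PSD are repaired or rejected", {
  C <- exchangeableCorrFixture(10, -0.1)    # near the equicorrelation floor
  res <- applyZIncrement(C, -0.5, repair = TRUE)
  ev <- eigen(res$corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(unname(diag(res$corr)), rep(1, 10))
  expect_error(applyZIncrement(C, -0.5, repair = FALSE), "non-PSD")
})

test_that("motion traces have bounded drift, known spikes, and trigger discard", {
  clean <- simulateMotion(120, spikeRate = 0, driftAmplitude = 0.2, seed = 31)
  expect_equal(length(clean$spikeFrames), 0)
  expect_lte(max(abs(clean$motion[, 1:3])), 0.2)

  spiky <- simulateMotion(120, spikeRate = 0.1, spikeAmplitude = 3.5, seed = 32)
  expect_gt(length(spiky$spikeFrames), 0)
  cens <- computeCensoring(spiky$motion, censorConfig())
  expect_true(cens$discardRun)

  expect_equal(simulateMotion(50, seed = 7), simulateMotion(50, seed = 7))
})

test_that("rendered volumes round-trip through ROI extraction", {
  rs <- toyRoiSet(2, spacing = 18, radius = 5)
  rts <- simulateRoiTimeSeries(rs, nFrames = 20, seed = 41)
  grid <- toyGrid(dim = c(12, 8, 8), voxelSize = 3, origin = c(-9, -9, -9))
  vol <- renderVolume(rts, rs, grid, noiseSd = 0)

  rec <- extractRoiTimeseries(vol$volume, vol$affine, rs)
  expect_equal(rec, seriesData(rts), ignore_attr = TRUE, tolerance = 1e-12)

  # voxel membership equals brute-force distance enumeration (3 mm grid)
  tab <- roiTable(rs)
  for (i in seq_len(nrow(tab))) {
    cnt <- 0
    for (ix in 0:(grid$dim[1] - 1)) for (iy in 0:(grid$dim[2] - 1))
      for (iz in 0:(grid$dim[3] - 1)) {
        w <- grid$origin + c(ix, iy, iz) * grid$voxelSize
        if (sum((w - as.numeric(tab[i, c("x", "y", "z")]))^2) <=
            tab$radius_mm[i]^2) cnt <- cnt + 1
      }
    expect_equal(sum(vol$membership == i), cnt)
  }

  # ROI outside the grid and overlapping spheres raise
  out <- RoiSet(data.frame(name = "far", hemisphere = "L", x = 500, y = 0,
                           z = 0, radius_mm = 6), "far")
  rts1 <- simulateRoiTimeSeries(out, nFrames = 5, seed = 1)
  expect_error(renderVolume(rts1, out, grid), "outside the grid")
  overlap <- RoiSet(data.frame(name = c("a", "b"), hemisphere = "L",
                               x = c(0, 4), y = 0, z = 0, radius_mm = 6), "ov")
  rts2 <- simulateRoiTimeSeries(overlap, nFrames = 5, seed = 1)
  expect_error(renderVolume(rts2, overlap, grid), "overlap")
})

test_that("synthetic volumes survive a NIfTI round trip", {
  rs <- toyRoiSet(1, radius = 4)
  rts <- simulateRoiTimeSeries(rs, nFrames = 6, seed = 51)
  vol <- renderVolume(rts, rs, toyGrid(dim = c(8, 8, 8)))
  path <- tempfile(fileext = ".nii.gz")
  writeVolumeNifti(vol, path)
  back <- readVolumeNifti(path)
  expect_equal(back$volume, vol$volume, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(back$affine[1:3, 4], vol$affine[1:3, 4],
               ignore_attr = TRUE, tolerance = 1e-6)
  rec <- extractRoiTimeseries(back$volume, back$affine, rs)
  expect_equal(rec, seriesData(rts), ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("observer model obeys its psychometric contract", {
  m <- observerModel(pse = 2, slope = 1)
  expect_equal(pDifferent(m, 2), 0.5)
  ml <- observerModel(pse = 2, slope = 1, lapseRate = 0.1)
  expect_equal(pDifferent(ml, 1e6), 0.9)

  # empirical response rate at a fixed offset within the binomial CI
  p <- pDifferent(m, 2.7)
  resp <- simulateObserverResponse(m, rep(2.7, 1e4), "different", seed = 61)
  phat <- mean(resp == "different")
  ci <- p + c(-1, 1) * 3.3 * sqrt(p * (1 - p) / 1e4)
  expect_gt(phat, ci[1]); expect_lt(phat, ci[2])
})

test_that("behavioral cohorts follow the configured learning curves", {
  coh <- generateCohort(seed = 71)
  flat <- simulateBehavioralCohort(coh, learningRates = list(
    Parietal = list(OD = 0, TOJ = 0), hMT = list(OD = 0, TOJ = 0),
    Sham = list(OD = 0, TOJ = 0)), seed = 72)
  pre <- flat$accuracy[flat$phase == "pre"]
  post <- flat$accuracy[flat$phase == "post"]
  expect_lt(abs(mean(post) - mean(pre)), 0.03)

  beh <- simulateBehavioralCohort(coh, seed = 73)
  par <- beh[beh$group == "Parietal", ]
  odGain <- with(par[par$task == "OD", ],
                 mean(accuracy[phase == "post"]) - mean(accuracy[phase == "pre"]))
  tojGain <- with(par[par$task == "TOJ", ],
                  mean(accuracy[phase == "post"]) - mean(accuracy[phase == "pre"]))
  expect_gt(odGain, 0.15)
  expect_lt(abs(tojGain), 0.08)
  expect_equal(simulateBehavioralCohort(coh, seed = 73), beh)
})

test_that("attention-network effects leave control-network edges unchanged in distribution", {
  base <- list(DVAN = exchangeableCorrFixture(5, 0.2),
               DMN = exchangeableCorrFixture(5, 0.2))
  eff <- effectSpec("Parietal", "DVAN", 2, deltaZ = 0.3)
  specsE <- injectConnectivityEffect(base, eff, groups = "Parietal",
                                     sessions = 2)
  specs0 <- injectConnectivityEffect(base, NULL, groups = "Parietal",
                                     sessions = 2)
  edges <- function(specs, seed) {
    run <- simulateRoiTimeSeries(5, nFrames = 60,
      baseCorrelation = specs$Parietal[[2]]$DMN$corr, seed = seed)
    cm <- connectivityMatrix(run, roiSetLabel = "DMN")
    edgeVector(cm)
  }
  zE <- unlist(lapply(1:100, function(i) edges(specsE, 1000 + i)))
  z0 <- unlist(lapply(1:100, function(i) edges(specs0, 5000 + i)))
  expect_gt(stats::ks.test(zE, z0)$p.value, 0.01)
})
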