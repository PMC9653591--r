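test_that("mean pixel pitch is physical over pixel diameter", {
  expect_equal(meanPixelPitch(13.352, 2000), 6.676)
  expect_equal(meanPixelPitch(1.5, 1500), 1)
  expect_equal(meanPixelPitch(13.352, 4000),
               meanPixelPitch(13.352, 2000) / 2)
  expect_error(meanPixelPitch(-1, 100), "positive")
})

test_that("ROI-to-disc ratio divides and round-trips", {
  expect_equal(roiDiscRatio(1802.4, 291.4), 1802.4 / 291.4)
  expect_equal(roiDiscRatio(1802.4, 291.4), 6.186, tolerance = 2e-4)
  expect_equal(roiDiscRatio(512, 512), 1)
  r <- roiDiscRatio(1802.4, 281.45)
  expect_equal(r * 281.45, 1802.4, tolerance = 1e-12)
  expect_error(roiDiscRatio(100, 0), "disc diameter")
})

test_that("offline calibration summarises per-image ratios", {
  s <- offlineCalibrate(1920, 300, scope = "one")
  expect_equal(ratioMean(s), 6.4)
  expect_equal(ratioSd(s), 0)
  expect_equal(s@n, 1L)

  # duplicated cohort leaves mean and population sd unchanged
  lr <- c(1900, 1910, 1895, 1920); ld <- c(300, 296, 310, 305)
  s1 <- offlineCalibrate(lr, ld)
  s2 <- offlineCalibrate(rep(lr, 2), rep(ld, 2))
  expect_equal(ratioMean(s2), ratioMean(s1))
  expect_equal(ratioSd(s2), ratioSd(s1))
  expect_equal(s2@lRoiStd, s1@lRoiStd)

  # population (1/n) standard deviation, not the sample sd
  expect_equal(ratioSd(s1), sqrt(mean((lr / ld - mean(lr / ld))^2)))

  # failed detections and serious ametropia are excluded
  s3 <- offlineCalibrate(c(lr, NA, 1900), c(ld, 300, 299),
                         diopters = c(0, -1, 2, 0, 0, -8))
  expect_equal(s3@n, 4L)
  expect_error(offlineCalibrate(NA_real_, NA_real_), "no valid")
})

test_that("offline calibration recovers a known ratio at cohort scale", {
  set.seed(1)
  n <- 2000
  r <- rnorm(n, 6.40, 0.6)
  s <- offlineCalibrate(rep(1920, n), 1920 / r)
  expect_lt(abs(ratioMean(s) - 6.40), 3 * 0.6 / sqrt(n))
  expect_equal(ratioSd(s), 0.6, tolerance = 0.1)
})

test_that("pitch formula reproduces the tabulated per-camera estimates", {
  expect_equal(round(estimatePitch(6.404, 1.921, 1802.4), 3), 6.825)
  expect_equal(round(estimatePitch(6.186, 1.921, 1802.4), 3), 6.593)
  expect_equal(round(estimatePitch(6.404, 1.921, 2123.717), 3), 5.793)
  expect_error(estimatePitch(0, 1.9, 1800), "positive")
})

test_that("ratio and pitch compose to the disc-scale identity", {
  lRoi <- 1856.96; lDisc <- 289.7; Ld <- 1.921
  p <- estimatePitch(roiDiscRatio(lRoi, lDisc), Ld, lRoi)
  expect_equal(p, Ld * 1000 / lDisc, tolerance = 1e-9)
})

test_that("uncertainty propagates in quadrature over the three factors", {
  p <- estimatePitch(6.404, 1.921, 1802.4)
  u <- propagateUncertainty(p, 6.404, 0.619, 1.921, 0.026, 1802.4, 0.473)
  expect_equal(round(u, 3), 0.666)
  expect_equal(propagateUncertainty(p, 6.404, 0, 1.921, 0, 1802.4, 0), 0)
  # the combined relative uncertainty dominates each component
  expect_gte(u / p + 1e-12, 0.619 / 6.404)
  expect_gte(u / p + 1e-12, 0.026 / 1.921)
  # invariant under exchanging which factor carries a relative error
  u1 <- propagateUncertainty(p, 6.404, 6.404 * 0.05, 1.921, 0, 1802.4, 0)
  u2 <- propagateUncertainty(p, 6.404, 0, 1.921, 1.921 * 0.05, 1802.4, 0)
  expect_equal(u1, u2, tolerance = 1e-12)
})

test_that("ISO reference pitch is 1700 over the pixel count", {
  expect_equal(isoPitch(1700), 1)
  expect_equal(isoPitch(250), 6.8)
  expect_equal(isoPitch(246.5), 6.897, tolerance = 1e-4)
  expect_error(isoPitch(0), "positive")
})

test_that("bias against the ISO reference matches the tabulated values", {
  b <- pitchBias(estimatePitch(6.404, 1.921, 1802.4), 6.897, digits = 3)
  expect_lt(abs(b$deltaP - (-0.071)), 0.002)
  expect_lt(abs(b$deltaPRel - (-1.033)), 0.02)
  b2 <- pitchBias(estimatePitch(6.186, 1.921, 1802.4), 6.897, digits = 3)
  expect_lt(abs(b2$deltaPRel - (-4.402)), 0.02)
  expect_identical(pitchBias(6.9, 6.9)$deltaP, 0)
  expect_identical(pitchBias(6.9, 6.9)$deltaPRel, 0)
})

test_that("prior sensitivity recomputes biases and is monotone in Ldisc", {
  ci <- cameraCalibrationInputs()
  tab <- sensitivityToPrior(1.82, 6.404, ci$l_roi_px, ci$p_iso_um,
                            cameras = ci$camera)
  expect_lt(abs(tab$biasPct[tab$camera == "canon"] - (-6.2)), 0.06)
  # Table-5 prior reproduces the tabulated FOV-scenario biases
  tab2 <- sensitivityToPrior(1.921, 6.404, ci$l_roi_px, ci$p_iso_um,
                             cameras = ci$camera)
  expect_lt(max(abs(tab2$biasPct - c(-1.033, -2.673, 1.759, -2.733))),
            0.02)
  lds <- seq(1.7, 2.1, by = 0.05)
  mono <- sensitivityToPrior(lds, 6.404, ci$l_roi_px[1], ci$p_iso_um[1])
  expect_true(all(diff(mono$biasPct) > 0))
})

test_that("pitch estimate objects validate their bias fields", {
  e <- pitchEstimate(6.825, 0.666, "FOV-specified", pIso = 6.897)
  expect_equal(e@deltaP, 6.825 - 6.897)
  expect_error(new("PitchEstimate", pDisc = 6.8, uPdisc = 0.1,
                   scenario = "FOV-specified", pIso = 6.9,
                   deltaP = 1, deltaPRel = 0), "deltaP")
  expect_error(pitchEstimate(6.8, 0.1, scenario = "bogus"), "scenario")
})
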