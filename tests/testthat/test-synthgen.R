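test_that("camera profiles validate their geometry", {
  expect_error(cameraProfile("x", c(100, 100), roiDiameterPx = 500),
               "diagonal")
  expect_error(cameraProfile("x", c(100, 100), roiDiameterPx = 80,
                             cropFraction = 0.5), "cropFraction")
  profs <- defaultCameraProfiles(scale = 0.2)
  expect_named(profs, c("canon", "topcon", "zeiss", "newvision"))
  expect_gt(profs$zeiss@cropFraction, 0)      # ROI taller than frame
  expect_equal(profs$canon@cropFraction, 0)
})

test_that("rendering is deterministic for a fixed seed", {
  prof <- demoProfile()
  a <- renderFundus(prof, seed = 11)
  b <- renderFundus(prof, seed = 11)
  expect_identical(a@pixels, b@pixels)
  c <- renderFundus(prof, seed = 12)
  expect_false(identical(a@pixels, c@pixels))
})

test_that("declared cropping manifests at the frame edges", {
  prof <- defaultCameraProfiles(scale = 0.2)$zeiss
  img <- renderFundus(prof, seed = 4)
  m <- binarizeRed(img)
  H <- imageHeight(img)
  expect_true(any(m[, 1]))        # bright mask reaches the top row
  expect_true(any(m[, H]))        # ... and the bottom row
  # a profile declaring cropping whose frame holds the full circle is
  # rejected as inconsistent
  bad <- cameraProfile("bad", c(400, 400), roiDiameterPx = 200,
                       cropFraction = 0.1, pitchUmTruth = 60)
  expect_error(renderFundus(bad, seed = 1), "inconsistent")
})

test_that("ground truth enforces the disc inside the ROI", {
  prof <- demoProfile()
  expect_error(groundTruth(prof, discOffsetFrac = 1.05), "inconsistent")
  tr <- groundTruth(prof, diopterD = -3)
  # myopic eye: retina farther, pitch per pixel larger, disc smaller
  expect_gt(tr$pitchEyeUm, prof@pitchUmTruth)
  expect_lt(tr$discMajorPx, groundTruth(prof)$discMajorPx)
})

test_that("degenerate cohorts collapse to identical images", {
  prof <- demoProfile()
  co <- sampleCohort(prof, n = 2, discDiamMm = c(1.921, 0),
                     diopterD = c(0, 0), seed = 6, render = TRUE,
                     noiseSd = 0, nVessels = 0)
  expect_identical(co$images[[1]]@pixels, co$images[[2]]@pixels)
  expect_equal(co$truths$ratioTruth[1], co$truths$ratioTruth[2])
})

test_that("diopter draws respect the truncation bound", {
  co <- sampleCohort(demoProfile(), n = 500, seed = 13)
  expect_true(all(abs(co$truths$diopterD) <= 10))
  expect_true(all(co$truths$discDiamMm >= 1.921 - 3 * 0.19))
  expect_true(all(co$truths$discDiamMm <= 1.921 + 3 * 0.19))
})

test_that("cohort ratios match the generator's analytic expectation", {
  prof <- defaultCameraProfiles(scale = 0.2)$canon
  ex <- cohortRatioExpectation(prof)
  co <- sampleCohort(prof, n = 2000, seed = 7)
  se <- ex[["sd"]] / sqrt(2000)
  expect_lt(abs(mean(co$truths$ratioTruth) - ex[["mean"]]), 3 * se)
  expect_equal(sd(co$truths$ratioTruth), ex[["sd"]], tolerance = 0.1)
})

test_that("rendered truth is recovered by both detectors", {
  prof <- demoProfile()
  tr <- groundTruth(prof)
  img <- renderFundus(prof, tr, seed = 19)
  roi <- detectROI(img)
  expect_equal(roiDiameter(roi), tr$roiDiameterPx, tolerance = 0.01)
  d <- measureDisc(img, roi = roi)
  expect_equal(discDiameter(d), tr$discMajorPx, tolerance = 0.02)
})
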