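test_that("red-channel binarisation thresholds at one third of the mean", {
  px <- array(0, dim = c(64, 64, 3))
  px[, , 1] <- 90
  expect_true(all(binarizeRed(fundusImage(px))))

  px2 <- array(0, dim = c(64, 64, 3))
  px2[33:64, , 1] <- 120          # mean 60, threshold 20
  m <- binarizeRed(fundusImage(px2))
  expect_true(all(m[33:64, ]))
  expect_false(any(m[1:32, ]))

  blank <- array(0, dim = c(64, 64, 3))
  blank[, , 2:3] <- 10
  expect_error(binarizeRed(fundusImage(blank)), "blank image")
})

test_that("binarisation covers the ground-truth ROI on a rendered image", {
  img <- demoImage()
  m <- largestComponent(binarizeRed(img))
  tr <- groundTruth(demoProfile())
  X <- matrix(rep(seq_len(320) - 1, 320), 320, 320)
  Y <- matrix(rep(seq_len(320) - 1, each = 320), 320, 320)
  inside <- sqrt((X - tr$roiCenter[1])^2 +
                   (Y - tr$roiCenter[2])^2) <= tr$roiDiameterPx / 2 - 1
  expect_gt(sum(m & inside) / sum(inside), 0.99)
})

test_that("largest component keeps the biggest blob and drops specks", {
  m <- matrix(FALSE, 80, 80)
  m[10:19, 10:19] <- TRUE         # 100 px
  m[60:69, 60:64] <- TRUE         # 50 px
  keep <- largestComponent(m)
  expect_true(all(keep[10:19, 10:19]))
  expect_false(any(keep[60:69, 60:64]))

  single <- matrix(FALSE, 80, 80)
  single[20:40, 20:40] <- TRUE
  expect_identical(largestComponent(single), single)

  expect_error(largestComponent(matrix(FALSE, 10, 10)), "empty mask")

  # dust specks around a rendered ROI are removed
  img <- demoImage()
  px <- img@pixels
  px[5:7, 5:7, 1] <- 200
  px[310:312, 15:17, 1] <- 200
  speckled <- largestComponent(binarizeRed(fundusImage(px)))
  expect_false(any(speckled[5:7, 5:7]))
  expect_true(any(speckled[150:170, 150:170]))
})

test_that("ROI diameter is recovered within 1% on a full circle", {
  img <- demoImage()
  roi <- detectROI(img)
  expect_equal(roiDiameter(roi), 240, tolerance = 0.01)
  expect_false(any(roi@cropped))
  expect_equal(measurementCenter(roi), c(159.5, 159.5), tolerance = 0.02)
})

test_that("a cropped ROI circle is recovered within 2%", {
  prof <- demoProfile(roiDiameterPx = 300, cropFraction = 0.1,
                      imageSize = c(320, 250), pitchUmTruth = 40)
  img <- renderFundus(prof, seed = 7)
  roi <- detectROI(img)
  expect_equal(roiDiameter(roi), 300, tolerance = 0.02)
  expect_true(roi@cropped["top"] && roi@cropped["bottom"])
})

test_that("detection is deterministic, scale-equivariant and rotation-invariant", {
  img <- demoImage()
  r1 <- detectROI(img); r2 <- detectROI(img)
  expect_identical(r1@center, r2@center)
  expect_identical(r1@diameterPx, r2@diameterPx)

  # nearest-neighbour 2x upscale doubles the diameter within 2%
  up <- img@pixels[rep(seq_len(320), each = 2),
                   rep(seq_len(320), each = 2), ]
  rUp <- detectROI(fundusImage(up))
  expect_equal(roiDiameter(rUp) / roiDiameter(r1), 2, tolerance = 0.02)

  # 90-degree rotation changes the diameter by < 0.5%
  rot <- aperm(img@pixels, c(2, 1, 3))[, 320:1, ]
  rRot <- detectROI(fundusImage(rot))
  expect_equal(roiDiameter(rRot), roiDiameter(r1), tolerance = 0.005)
})

test_that("ROI diameter is stable across a rendered cohort", {
  prof <- defaultCameraProfiles(scale = 0.2)$canon
  co <- sampleCohort(prof, n = 12, seed = 3, render = TRUE)
  d <- vapply(co$images, function(im) roiDiameter(detectROI(im)),
              numeric(1))
  expect_lt(diameterStats(d)[["cv"]], 1e-2)
})

test_that("featureless images are rejected", {
  px <- array(60, dim = c(96, 96, 3))   # uniform: mask is the frame,
  img <- fundusImage(px)                # no circle exceeds the vote gate
  expect_error(detectROI(img), "ROI not found")
})
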