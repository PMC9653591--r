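test_that("the classical locator finds the disc near its true centre", {
  prof <- demoProfile()
  img <- demoImage()
  tr <- groundTruth(prof)
  expect_lt(sqrt(sum((locateDisc(img) - tr$discCenter)^2)), 10)

  # nasal offset variations of a macula-centred layout
  tr2 <- groundTruth(prof, discOffsetFrac = 0.45)
  img2 <- renderFundus(prof, tr2, seed = 5)
  expect_lt(sqrt(sum((locateDisc(img2) - tr2$discCenter)^2)), 10)

  expect_error(locateDisc(fundusImage(array(120, c(96, 96, 3)))),
               "disc not found")
})

test_that("polar transform maps circles to rows and round-trips", {
  # concentric-ring phantom: rows of the polar raster are constant
  size <- 257; ctr <- c(128, 128)
  X <- matrix(rep(seq_len(size) - 1, size), size, size)
  Y <- matrix(rep(seq_len(size) - 1, each = size), size, size)
  d <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
  rings <- fundusImage(128 + 60 * sin(2 * pi * d / 24))
  po <- polarTransform(rings, ctr, nTheta = 180, rMax = 100)
  rowSpread <- apply(po$values, 1L, function(v) max(v) - min(v))
  expect_lt(max(rowSpread), 4)    # bilinear interpolation tolerance

  # inverse resampling of a smooth phantom reproduces the annulus
  smooth <- fundusImage(100 + 80 * (d / max(d)) +
                          20 * sin(2 * pi * (X - 128) / 90))
  po2 <- polarTransform(smooth, ctr, nTheta = 720, dr = 0.5, rMax = 100)
  ann <- which(d >= 3 & d <= 95, arr.ind = TRUE)
  r <- d[ann]
  th <- (atan2(ann[, 2] - 1 - ctr[2], ann[, 1] - 1 - ctr[1])) %% (2 * pi)
  rec <- bilinearSample(po2$values, r / 0.5 - 1,
                        th / (2 * pi / 720))
  orig <- channelMatrix(smooth, 1L)[ann]
  expect_lt(mean(abs(rec - orig)), 2)

  expect_error(polarTransform(rings, c(-5, 10), rMax = 50), "inside")
})

test_that("disc edges concentrate at the true radius per angular column", {
  ph <- discPhantom(size = 420, a = 120)
  po <- polarTransform(ph, c(209.5, 209.5), nTheta = 360, rMax = 180)
  pts <- detectDiscEdge(po)
  r <- attr(pts, "r")
  expect_gte(mean(r >= 118 & r <= 122), 0.9)
  # one edge radius per angular column
  expect_identical(anyDuplicated(attr(pts, "theta")), 0L)

  # no-disc phantom
  flat <- fundusImage(matrix(130, 300, 300))
  poF <- polarTransform(flat, c(149.5, 149.5), rMax = 100)
  expect_error(detectDiscEdge(poF), "edge too weak")
})

test_that("elliptical disc edges match the closed-form polar radius", {
  a <- 130; b <- 110
  ph <- discPhantom(size = 460, a = a, b = b)
  po <- polarTransform(ph, c(229.5, 229.5), nTheta = 360, rMax = 200)
  pts <- detectDiscEdge(po, maxDevFrac = Inf)
  th <- attr(pts, "theta"); r <- attr(pts, "r")
  rTrue <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  expect_lt(sqrt(mean((r - rTrue)^2)), 3)
})

test_that("circumscribed-circle fit finds the exact farthest pair", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  f <- fitCircumscribedCircle(sq)
  expect_equal(discDiameter(f), sqrt(2), tolerance = 1e-12)
  expect_equal(measurementCenter(f), c(0.5, 0.5))
  expect_identical(f@farthestPair, c(1L, 4L))   # lexicographic tie-break

  th <- 2 * pi * (0:359) / 360
  circ <- fitCircumscribedCircle(cbind(3 + 10 * cos(th), -2 + 10 * sin(th)))
  expect_equal(discDiameter(circ), 20, tolerance = 2e-3 / 20)
  expect_equal(measurementCenter(circ), c(3, -2), tolerance = 1e-9)

  expect_error(fitCircumscribedCircle(rbind(c(0, 0))), "at least 2")
})

test_that("the fit equals a brute-force oracle on random clouds", {
  for (s in 1:100) {
    set.seed(s)
    pts <- matrix(rnorm(100), 50, 2)
    f <- fitCircumscribedCircle(pts)
    o <- bruteFarthestPair(pts)
    expect_identical(discDiameter(f), o$diameter)
    expect_identical(f@farthestPair, c(o$i, o$j))
  }
})

test_that("the fit is invariant to point order and rigid rotation", {
  set.seed(99)
  pts <- matrix(runif(160, -5, 5), 80, 2)
  f0 <- fitCircumscribedCircle(pts)
  perm <- sample(80)
  fP <- fitCircumscribedCircle(pts[perm, ])
  expect_equal(discDiameter(fP), discDiameter(f0), tolerance = 1e-12)
  phi <- 0.7
  Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  fR <- fitCircumscribedCircle(pts %*% Rm)
  expect_equal(discDiameter(fR), discDiameter(f0), tolerance = 1e-9)
})

test_that("the hull shortcut agrees with brute force on large sets", {
  set.seed(5)
  pts <- matrix(rnorm(4000), 2000, 2)
  f <- fitCircumscribedCircle(pts)
  sq <- rowSums(pts^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(pts)
  expect_equal(discDiameter(f), sqrt(max(d2)), tolerance = 1e-12)
})

test_that("full disc chain recovers circular discs within 2% over seeds", {
  prof <- demoProfile()
  tr <- groundTruth(prof, discAspect = 1)
  err <- vapply(1:40, function(s) {
    img <- renderFundus(prof, tr, seed = 1000 + s, nVessels = 0)
    discDiameter(measureDisc(img)) / tr$discMajorPx - 1
  }, numeric(1))
  expect_lt(max(abs(err)), 0.02)
})

test_that("vessel occlusion degrades the disc diameter by at most 5%", {
  prof <- demoProfile()
  tr <- groundTruth(prof, discAspect = 1)
  err <- vapply(1:20, function(s) {
    img <- renderFundus(prof, tr, seed = 1000 + s)
    discDiameter(measureDisc(img)) / tr$discMajorPx - 1
  }, numeric(1))
  expect_lt(max(abs(err)), 0.05)
  expect_lt(abs(mean(err)), 0.025)
})

test_that("the farthest-pair diameter tracks the major axis of an ellipse", {
  prof <- demoProfile(pitchUmTruth = 35)   # larger disc (~55 px)
  tr <- groundTruth(prof, discAspect = 0.85)
  img <- renderFundus(prof, tr, seed = 21)
  d <- measureDisc(img)
  expect_equal(discDiameter(d), tr$discMajorPx, tolerance = 0.03)
})

test_that("a custom locator strategy can replace the default", {
  prof <- demoProfile()
  tr <- groundTruth(prof)
  img <- renderFundus(prof, tr, seed = 8)
  fixed <- function(image, ...) tr$discCenter
  d <- measureDisc(img, locator = fixed)
  expect_equal(discDiameter(d), tr$discMajorPx, tolerance = 0.02)
})
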