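# Seeded generator of ground-truthed synthetic fundus photographs and
# cohorts.  The generator emulates the statistical structure the
# calibration method relies on: a per-camera stable ROI diameter, a
# population distribution of physical disc diameters, a macula-centred
# layout with the disc at a lateral offset, diopter-driven magnification
# changes through the reduced-eye model, optional vessel strokes,
# additive Gaussian noise, and optional frame cropping of the ROI
# circle.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

rnormTrunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

truncNormExp <- function(f, mean, sd, lower, upper) {
  if (sd == 0) return(f(mean))
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  stats::integrate(function(x) f(x) * stats::dnorm(x, mean, sd),
                   lower, upper, rel.tol = 1e-10)$value / z
}

#' Construct a synthetic camera profile
#'
#' @param name camera label.
#' @param imageSize integer(2), frame size (W, H) in pixels.
#' @param roiDiameterPx mean ROI diameter in pixels.
#' @param roiDiameterSdPx population sd of the ROI diameter.
#' @param pitchUmTruth true pixel pitch in um/px used as ground truth.
#' @param cropFraction per-side fraction of the ROI circle cropped by
#'   the frame, in [0, 0.3]; 0 renders the full circle.
#' @return A [CameraProfile-class].
#' @export
cameraProfile <- function(name, imageSize, roiDiameterPx,
                          roiDiameterSdPx = 0.5, pitchUmTruth = 6.9,
                          cropFraction = 0) {
  new("CameraProfile", name = name, imageSize = as.integer(imageSize),
      roiDiameterPx = roiDiameterPx, roiDiameterSdPx = roiDiameterSdPx,
      pitchUmTruth = pitchUmTruth, cropFraction = cropFraction)
}

#' Profiles of four 45-degree fundus cameras
#'
#' Profiles mimicking four commercial 45-degree cameras: frame sizes and
#' ROI-diameter means/sds follow the published per-camera ROI
#' statistics, and the true pitch is each camera's ISO-measured value.
#' The Zeiss- and Newvision-like frames are shorter than their ROI
#' circles, so those profiles render a top/bottom-cropped ROI.  A
#' \code{scale} below 1 shrinks frames and ROI
#' diameters (and scales the pitch up accordingly) for desk-scale
#' simulation.
#'
#' @param scale geometric down-scaling factor in (0, 1].
#' @return Named list of four [CameraProfile-class] objects.
#' @examples
#' defaultCameraProfiles(scale = 0.28)$canon
#' @export
defaultCameraProfiles <- function(scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  mk <- function(name, W, H, roi, roiSd, piso) {
    crop <- if (roi > H * 0.999) min(0.3, (roi - H) / (2 * roi) + 0.01)
    else 0
    cameraProfile(name,
                  c(max(64L, round(W * scale)),
                    max(64L, round(H * scale))),
                  roi * scale, roiSd * scale, piso / scale, crop)
  }
  list(canon = mk("canon", 2976, 1984, 1802.390, 0.513, 6.897),
       topcon = mk("topcon", 1956, 1934, 1856.985, 3.639, 6.807),
       zeiss = mk("zeiss", 2124, 2056, 2123.710, 0.481, 5.693),
       newvision = mk("newvision", 2091, 1992, 2090.593, 0.238, 6.050))
}

#' Ground truth for one synthetic fundus image
#'
#' Builds and checks a ground-truth description: the ROI circle, the
#' elliptical optic disc (major axis vertical, at a lateral offset from
#' the frame centre as in a macula-centred photograph), and the eye's
#' diopter.  The disc must lie entirely inside the ROI.
#'
#' @param profile a [CameraProfile-class].
#' @param roiDiameterPx ROI circle diameter in pixels.
#' @param discDiamMm physical disc (major-axis) diameter in mm.
#' @param diopterD axial ametropia in diopters.
#' @param discOffsetFrac lateral offset of the disc centre from the ROI
#'   centre as a fraction of the ROI radius.
#' @param discAspect minor/major axis ratio of the disc ellipse.
#' @param f1 first focal length of the eye in mm.
#' @return Named list with fields \code{roiCenter}, \code{roiDiameterPx},
#'   \code{discCenter}, \code{discMajorPx}, \code{discMinorPx},
#'   \code{diopterD}, \code{discDiamMm}, \code{pitchEyeUm}.
#' @export
groundTruth <- function(profile, roiDiameterPx = profile@roiDiameterPx,
                        discDiamMm = 1.921, diopterD = 0,
                        discOffsetFrac = 0.55, discAspect = 0.90,
                        f1 = 17) {
  W <- profile@imageSize[1L]; H <- profile@imageSize[2L]
  roiCenter <- c((W - 1) / 2, (H - 1) / 2)
  dd <- deltaDFromDiopter(diopterD, f1)
  pitchEye <- profile@pitchUmTruth * (f1 + dd) / f1
  major <- discDiamMm * 1000 / pitchEye
  minor <- discAspect * major
  R <- roiDiameterPx / 2
  discCenter <- roiCenter + c(-discOffsetFrac * R, 0)
  if (sqrt(sum((discCenter - roiCenter)^2)) + major / 2 > R)
    stop("truth inconsistent with profile: disc not inside ROI")
  if (roiDiameterPx <= 0 || roiDiameterPx > sqrt(W^2 + H^2) * 1.1)
    stop("truth inconsistent with profile: ROI diameter out of range")
  list(roiCenter = roiCenter, roiDiameterPx = roiDiameterPx,
       discCenter = discCenter, discMajorPx = major,
       discMinorPx = minor, diopterD = diopterD,
       discDiamMm = discDiamMm, pitchEyeUm = pitchEye)
}

#' Render a synthetic fundus photograph
#'
#' Dark background, a reddish ROI disc with radial shading, a brighter
#' elliptical optic disc at the truth centre (vertical major axis),
#' optional dark vessel strokes radiating from the disc, and additive
#' Gaussian noise.  Rendering is deterministic for a fixed seed.
#'
#' @param profile a [CameraProfile-class].
#' @param truth ground truth from [groundTruth()]; built with defaults
#'   when missing.
#' @param seed integer seed for vessels and noise; `NULL` uses the
#'   current RNG state.
#' @param noiseSd Gaussian noise sd in intensity units (0-255 scale).
#' @param nVessels number of vessel strokes (0 disables).
#' @param id,cameraLabel metadata for the returned image.
#' @return A [FundusImage-class].
#' @export
renderFundus <- function(profile, truth = NULL, seed = NULL,
                         noiseSd = 2, nVessels = 3, id = "synthetic",
                         cameraLabel = profile@name) {
  if (is.null(truth)) truth <- groundTruth(profile)
  W <- profile@imageSize[1L]; H <- profile@imageSize[2L]
  R <- truth$roiDiameterPx / 2
  # a profile declaring cropping must actually have its circle cropped
  if (profile@cropFraction > 0 && H >= 2 * R && W >= 2 * R)
    stop("truth inconsistent with profile: ROI not cropped as declared")
  withSeed(seed, {
    X <- matrix(rep(seq_len(W) - 1, H), W, H)
    Y <- matrix(rep(seq_len(H) - 1, each = W), W, H)
    dRoi <- sqrt((X - truth$roiCenter[1])^2 + (Y - truth$roiCenter[2])^2)
    wRoi <- pmin(1, pmax(0, (R + 0.75 - dRoi) / 1.5))
    s <- pmin(1, (dRoi / R)^2)
    red <- 8 + wRoi * (175 * (1 - 0.25 * s) - 8)
    green <- 8 + wRoi * (95 * (1 - 0.30 * s) - 8)
    blue <- 8 + wRoi * (28 * (1 - 0.30 * s) - 8)

    a <- truth$discMinorPx / 2; b <- truth$discMajorPx / 2
    e <- sqrt(((X - truth$discCenter[1]) / a)^2 +
                ((Y - truth$discCenter[2]) / b)^2)
    wD <- pmin(1, pmax(0, ((1 - e) * min(a, b) + 0.75) / 1.5)) * wRoi
    red <- red * (1 - wD) + 248 * wD
    green <- green * (1 - wD) + 214 * wD
    blue <- blue * (1 - wD) + 120 * wD

    # pmin/pmax with scalar first arguments drop dim attributes; the
    # vessel stamping below indexes with an n x 2 matrix, so restore them
    dim(red) <- dim(green) <- dim(blue) <- c(W, H)
    if (nVessels > 0) {
      vmask <- matrix(FALSE, W, H)
      for (v in seq_len(nVessels)) {
        ang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 0.6, 0.9) * R
        bend <- stats::runif(1, -0.6, 0.6)
        t <- seq(0, 1, length.out = 400)
        px <- truth$discCenter[1] + t * len * cos(ang + bend * t)
        py <- truth$discCenter[2] + t * len * sin(ang + bend * t)
        # peripheral vessels fade out before the vignetted ROI rim, so
        # strokes must not notch the mask boundary
        inRim <- sqrt((px - truth$roiCenter[1])^2 +
                        (py - truth$roiCenter[2])^2) < 0.88 * R
        px <- px[inRim]; py <- py[inRim]
        if (!length(px)) next
        for (ox in -1:1) for (oy in -1:1) {
          xi <- round(px) + ox; yi <- round(py) + oy
          ok <- xi >= 0 & xi < W & yi >= 0 & yi < H
          vmask[cbind(xi[ok] + 1, yi[ok] + 1)] <- TRUE
        }
      }
      red[vmask] <- red[vmask] * 0.55
      green[vmask] <- green[vmask] * 0.55
      blue[vmask] <- blue[vmask] * 0.60
    }
    if (noiseSd > 0) {
      red <- red + stats::rnorm(W * H, 0, noiseSd)
      green <- green + stats::rnorm(W * H, 0, noiseSd)
      blue <- blue + stats::rnorm(W * H, 0, noiseSd)
    }
    px <- array(c(pmin(255, pmax(0, red)),
                  pmin(255, pmax(0, green)),
                  pmin(255, pmax(0, blue))), dim = c(W, H, 3))
    fundusImage(px, id = id, cameraLabel = cameraLabel)
  })
}

#' Sample a ground-truthed synthetic cohort
#'
#' Draws per-image ROI diameters from the camera profile, physical disc
#' diameters and diopters from truncated normal population
#' distributions, converts disc sizes to pixels through the true pitch
#' and the reduced-eye magnification factor (f1 + delta d)/f1, and
#' optionally renders the images.
#'
#' @param profile a [CameraProfile-class].
#' @param n cohort size.
#' @param discDiamMm numeric(2), mean and sd (mm) of the physical disc
#'   diameter; draws truncated at \code{discTruncSd} sds.
#' @param diopterD numeric(2), mean and sd (diopters) of the axial
#'   ametropia; draws truncated at +/- \code{diopterTrunc} D.
#' @param diopterTrunc absolute truncation bound for diopters.
#' @param discTruncSd truncation half-width for the disc draw, in sds.
#' @param seed integer seed.
#' @param f1 first focal length of the eye, mm.
#' @param render if `TRUE`, also render each image.
#' @param ... passed to [renderFundus()] (noise, vessels).
#' @return List with \code{truths} (data.frame, one row per image,
#'   including the per-image true ratio \code{ratioTruth}) and
#'   \code{images} (list of [FundusImage-class] or `NULL`).
#' @examples
#' co <- sampleCohort(defaultCameraProfiles(0.28)$canon, n = 5, seed = 1)
#' co$truths$ratioTruth
#' @export
sampleCohort <- function(profile, n, discDiamMm = c(1.921, 0.19),
                         diopterD = c(-0.559, 3.522),
                         diopterTrunc = 10, discTruncSd = 3,
                         seed = NULL, f1 = 17, render = FALSE, ...) {
  stopifnot(n >= 1)
  withSeed(seed, {
    roi <- stats::rnorm(n, profile@roiDiameterPx,
                        profile@roiDiameterSdPx)
    Ld <- rnormTrunc(n, discDiamMm[1], discDiamMm[2],
                     discDiamMm[1] - discTruncSd * discDiamMm[2],
                     discDiamMm[1] + discTruncSd * discDiamMm[2])
    D <- rnormTrunc(n, diopterD[1], diopterD[2], -diopterTrunc,
                    diopterTrunc)
    truths <- vector("list", n)
    images <- if (render) vector("list", n) else NULL
    for (i in seq_len(n)) {
      tr <- groundTruth(profile, roiDiameterPx = roi[i],
                        discDiamMm = Ld[i], diopterD = D[i], f1 = f1)
      truths[[i]] <- data.frame(
        id = sprintf("%s_%04d", profile@name, i),
        roiCenterX = tr$roiCenter[1], roiCenterY = tr$roiCenter[2],
        roiDiameterPx = tr$roiDiameterPx,
        discCenterX = tr$discCenter[1], discCenterY = tr$discCenter[2],
        discMajorPx = tr$discMajorPx, discMinorPx = tr$discMinorPx,
        diopterD = tr$diopterD, discDiamMm = tr$discDiamMm,
        pitchEyeUm = tr$pitchEyeUm,
        ratioTruth = tr$roiDiameterPx / tr$discMajorPx)
      if (render)
        images[[i]] <- renderFundus(profile, tr, seed = NULL,
                                    id = truths[[i]]$id, ...)
    }
    list(truths = do.call(rbind, truths), images = images)
  })
}

#' Analytic cohort expectation of the ROI-to-disc ratio
#'
#' Closed-form (numerically integrated) mean and sd of the per-image
#' ratio implied by the generator's own sampling distributions:
#' r = lROI * P * (f1 + delta d)/f1 / (1000 * L_disc) with lROI, L_disc
#' and the diopter drawn independently.  Serves as the generator-side
#' oracle for cohort recovery checks.
#'
#' @inheritParams sampleCohort
#' @return Named numeric: \code{mean} and \code{sd} of the per-image
#'   ratio.
#' @export
cohortRatioExpectation <- function(profile, discDiamMm = c(1.921, 0.19),
                                   diopterD = c(-0.559, 3.522),
                                   diopterTrunc = 10, discTruncSd = 3,
                                   f1 = 17) {
  g <- function(D) 1 + deltaDFromDiopter(D, f1) / f1
  A1 <- truncNormExp(g, diopterD[1], diopterD[2], -diopterTrunc,
                     diopterTrunc)
  A2 <- truncNormExp(function(D) g(D)^2, diopterD[1], diopterD[2],
                     -diopterTrunc, diopterTrunc)
  lo <- discDiamMm[1] - discTruncSd * discDiamMm[2]
  hi <- discDiamMm[1] + discTruncSd * discDiamMm[2]
  B1 <- truncNormExp(function(L) 1 / L, discDiamMm[1], discDiamMm[2],
                     lo, hi)
  B2 <- truncNormExp(function(L) 1 / L^2, discDiamMm[1], discDiamMm[2],
                     lo, hi)
  c0 <- profile@pitchUmTruth / 1000
  m1 <- profile@roiDiameterPx
  m2 <- m1^2 + profile@roiDiameterSdPx^2
  mu <- m1 * c0 * A1 * B1
  second <- m2 * c0^2 * A2 * B2
  c(mean = mu, sd = sqrt(max(0, second - mu^2)))
}
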