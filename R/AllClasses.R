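#' @import methods
NULL

#' Reduced-eye and fundus-camera optical model
#'
#' Container for the constants of the reduced (single refracting surface)
#' schematic eye coupled to a fundus camera: first focal length \code{f1}
#' of the eye in air, second focal length \code{f2p} in vitreous humour
#' (informational), axial length \code{a} (informational), camera focal
#' length \code{f0} (usually unknown and therefore optional), field of
#' view \code{alpha}, axial ametropia \code{D} in diopters, and the
#' signed offset \code{deltaD} of the retina from the second focal plane
#' in millimetres.
#'
#' When both \code{D} and \code{deltaD} are set they must be consistent
#' through the axial-defocus relation (checked to 1e-9 mm); construct the
#' object through [eyeCameraModel()] which fills in \code{deltaD} from
#' \code{D}.
#'
#' @slot f1 numeric(1), first focal length of the eye in mm (> 0).
#' @slot f2p numeric(1), second focal length in vitreous in mm.
#' @slot a numeric(1), axial length in mm.
#' @slot f0 numeric(1), camera focal length in mm; `NA` when unknown.
#' @slot alpha numeric(1), field of view in radians, in (0, pi).
#' @slot D numeric(1), axial ametropia in diopters; `NA` when unknown.
#' @slot deltaD numeric(1), retina offset from the second focal plane in
#'   mm; `NA` when unknown.
#'
#' @seealso [eyeCameraModel()], [deltaDFromDiopter()], [magnification()]
#' @exportClass EyeCameraModel
setClass("EyeCameraModel",
  representation(
    f1 = "numeric", f2p = "numeric", a = "numeric", f0 = "numeric",
    alpha = "numeric", D = "numeric", deltaD = "numeric"
  ),
  prototype(
    f1 = 17.0, f2p = 22.7, a = 23.87, f0 = NA_real_,
    alpha = pi / 4, D = 0, deltaD = 0
  )
)

setValidity("EyeCameraModel", function(object) {
  msg <- character()
  if (length(object@f1) != 1L || !is.finite(object@f1) || object@f1 <= 0)
    msg <- c(msg, "'f1' must be a single positive number (mm)")
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 0 || object@alpha >= pi)
    msg <- c(msg, "'alpha' must lie in (0, pi) radians")
  if (is.finite(object@D) && is.finite(object@deltaD)) {
    dd <- deltaDFromDiopter(object@D, object@f1)
    if (abs(dd - object@deltaD) > 1e-9)
      msg <- c(msg, sprintf(
        "'deltaD' (%.9f mm) inconsistent with 'D' (%g dpt): expected %.9f mm",
        object@deltaD, object@D, dd))
  }
  if (length(msg)) msg else TRUE
})

#' Fundus photograph
#'
#' A colour fundus photograph held as a width x height x 3 numeric array
#' (red, green, blue planes) with values in [0, 255], following the
#' EBImage x-first orientation.  Pixel-centre coordinates are 0-based with
#' \code{(x, y) = (column, row)}, so the centre of the top-left pixel is
#' \code{(0, 0)}.
#'
#' @slot pixels numeric array, dim \code{c(W, H, 3)}, values in [0, 255].
#' @slot id character(1) free-text image identifier.
#' @slot cameraLabel character(1) free-text camera label.
#'
#' @seealso [fundusImage()], [readFundusImage()], [renderFundus()]
#' @exportClass FundusImage
setClass("FundusImage",
  representation(pixels = "array", id = "character",
                 cameraLabel = "character"))

setValidity("FundusImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("'pixels' must be a W x H x 3 array")
  if (d[1] < 64L || d[2] < 64L)
    return("image must be at least 64 x 64 pixels")
  rng <- range(object@pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    return("pixel values must be finite and in [0, 255]")
  TRUE
})

#' Fitted circular region of interest of a fundus photograph
#'
#' Result of the circular Hough fit to the bright circular imaging area.
#' The centre is continuous and may lie outside the frame only when the
#' circle is cropped on some side.
#'
#' @slot center numeric(2), (x, y) circle centre in 0-based pixel
#'   coordinates.
#' @slot diameterPx numeric(1), fitted circle diameter in pixels.
#' @slot votes numeric(1), number of edge points supporting the circle.
#' @slot cropped named logical(4), whether the circle extends beyond the
#'   frame on the left/top/right/bottom side.
#'
#' @seealso [detectROI()]
#' @exportClass RoiMeasurement
setClass("RoiMeasurement",
  representation(center = "numeric", diameterPx = "numeric",
                 votes = "numeric", cropped = "logical"))

setValidity("RoiMeasurement", function(object) {
  if (length(object@center) != 2L)
    return("'center' must be length-2 (x, y)")
  if (length(object@diameterPx) != 1L || object@diameterPx <= 0)
    return("'diameterPx' must be a single positive number")
  if (length(object@cropped) != 4L)
    return("'cropped' must be length-4 (left, top, right, bottom)")
  TRUE
})

#' Optic-disc measurement
#'
#' Optic-disc edge points and the circumscribed-circle diameter, defined
#' as the largest pairwise Euclidean distance over the edge points; the
#' circle centre is the midpoint of that farthest pair.  Note this is
#' deliberately not the minimum enclosing circle: the farthest-pair
#' diameter tracks the major axis of an irregular disc.
#'
#' @slot center numeric(2), midpoint of the farthest pair (x, y).
#' @slot edgePoints numeric matrix N x 2 of edge coordinates.
#' @slot diameterPx numeric(1), farthest-pair distance in pixels.
#' @slot farthestPair integer(2), row indices of the farthest pair.
#'
#' @seealso [fitCircumscribedCircle()], [measureDisc()]
#' @exportClass DiscMeasurement
setClass("DiscMeasurement",
  representation(center = "numeric", edgePoints = "matrix",
                 diameterPx = "numeric", farthestPair = "integer"))

setValidity("DiscMeasurement", function(object) {
  p <- object@edgePoints
  if (ncol(p) != 2L || nrow(p) < 2L)
    return("'edgePoints' must be an N x 2 matrix with N >= 2")
  i <- object@farthestPair
  if (length(i) != 2L || any(i < 1L) || any(i > nrow(p)))
    return("'farthestPair' must index two rows of 'edgePoints'")
  d <- sqrt(sum((p[i[1], ] - p[i[2], ])^2))
  if (abs(d - object@diameterPx) > 1e-6)
    return("'diameterPx' must equal the farthest-pair distance")
  mid <- (p[i[1], ] + p[i[2], ]) / 2
  if (max(abs(mid - object@center)) > 1e-6)
    return("'center' must be the midpoint of the farthest pair")
  TRUE
})

#' Offline ROI-to-disc ratio statistics
#'
#' Cohort statistics of the ROI-to-disc diameter ratio r = lROI / ldisc
#' computed in the offline calibration phase, per camera or per field of
#' view.  Standard deviations are population (1/n) standard deviations.
#' \code{rOfMeans} additionally reports the ratio of the mean diameters,
#' an alternative summary of the same cohort.
#'
#' @slot scope character(1), camera label or e.g. "FOV45".
#' @slot rMean numeric(1), mean per-image ratio.
#' @slot rStd numeric(1), population sd of the ratio (the uncertainty Ur).
#' @slot n integer(1), number of images retained.
#' @slot lRoiMean numeric(1), mean ROI diameter in pixels.
#' @slot lRoiStd numeric(1), population sd of the ROI diameter (UlROI).
#' @slot rOfMeans numeric(1), mean(lROI) / mean(ldisc).
#'
#' @seealso [offlineCalibrate()]
#' @exportClass RatioStatistics
setClass("RatioStatistics",
  representation(scope = "character", rMean = "numeric", rStd = "numeric",
                 n = "integer", lRoiMean = "numeric", lRoiStd = "numeric",
                 rOfMeans = "numeric"))

setValidity("RatioStatistics", function(object) {
  if (object@rMean <= 0) return("'rMean' must be positive")
  if (object@n < 1L) return("'n' must be at least 1")
  if (object@rStd < 0 || object@lRoiStd < 0)
    return("standard deviations must be non-negative")
  TRUE
})

#' Anatomical optic-disc diameter prior
#'
#' Population prior on the physical (vertical) optic-disc diameter,
#' typically the pooled mean of a random-effects meta-analysis of
#' published studies.
#'
#' @slot lDisc numeric(1), prior mean diameter in mm (> 0).
#' @slot uLdisc numeric(1), its uncertainty (standard error) in mm.
#' @slot source character(1), free-text provenance.
#'
#' @seealso [poolRandomEffects()], [estimatePitch()]
#' @exportClass DiscDiameterPrior
setClass("DiscDiameterPrior",
  representation(lDisc = "numeric", uLdisc = "numeric",
                 source = "character"),
  prototype(source = ""))

setValidity("DiscDiameterPrior", function(object) {
  if (object@lDisc <= 0) return("'lDisc' must be positive (mm)")
  if (object@uLdisc < 0) return("'uLdisc' must be non-negative (mm)")
  TRUE
})

#' Random-effects pooling of optic-disc diameter studies
#'
#' Result of DerSimonian-Laird random-effects pooling of per-study
#' means and standard errors: the pooled mean and standard error, the
#' between-study variance tau2, Cochran's Q, the 95% confidence interval,
#' and per-study relative weights (percent) and standardised residuals.
#'
#' @slot pooled numeric(1), pooled mean (mm).
#' @slot se numeric(1), standard error of the pooled mean (mm).
#' @slot ci numeric(2), 95% confidence interval.
#' @slot tau2 numeric(1), between-study variance.
#' @slot Q numeric(1), Cochran's heterogeneity statistic.
#' @slot weights numeric, per-study relative weights in percent.
#' @slot studies data.frame, the input table augmented with weights and
#'   standardised residuals.
#'
#' @seealso [poolRandomEffects()], [discPrior()]
#' @exportClass PooledDiscDiameter
setClass("PooledDiscDiameter",
  representation(pooled = "numeric", se = "numeric", ci = "numeric",
                 tau2 = "numeric", Q = "numeric", weights = "numeric",
                 studies = "data.frame"))

#' Pixel-pitch estimate with uncertainty
#'
#' A per-image (or per-camera) pixel pitch around the optic disc in
#' micrometres per pixel, with the propagated uncertainty, the
#' calibration scenario ("camera-specified" or "FOV-specified"), and,
#' when an ISO 10940:2009 reference pitch is available, the absolute and
#' relative bias against it.
#'
#' @slot pDisc numeric(1), estimated pitch in um/px (> 0).
#' @slot uPdisc numeric(1), propagated uncertainty in um/px.
#' @slot scenario character(1), "camera-specified" or "FOV-specified".
#' @slot pIso numeric(1), ISO reference pitch in um/px; `NA` if absent.
#' @slot deltaP numeric(1), pDisc - pIso in um; `NA` if no reference.
#' @slot deltaPRel numeric(1), relative bias in percent; `NA` if no
#'   reference.
#'
#' @seealso [estimatePitch()], [propagateUncertainty()], [pitchBias()]
#' @exportClass PitchEstimate
setClass("PitchEstimate",
  representation(pDisc = "numeric", uPdisc = "numeric",
                 scenario = "character", pIso = "numeric",
                 deltaP = "numeric", deltaPRel = "numeric"),
  prototype(pIso = NA_real_, deltaP = NA_real_, deltaPRel = NA_real_))

setValidity("PitchEstimate", function(object) {
  if (object@pDisc <= 0) return("'pDisc' must be positive")
  if (object@uPdisc < 0) return("'uPdisc' must be non-negative")
  if (!object@scenario %in% c("camera-specified", "FOV-specified"))
    return("'scenario' must be 'camera-specified' or 'FOV-specified'")
  if (is.finite(object@pIso) && is.finite(object@deltaP) &&
      abs(object@deltaP - (object@pDisc - object@pIso)) > 1e-9)
    return("'deltaP' must equal pDisc - pIso")
  TRUE
})

#' Synthetic camera profile
#'
#' Parameters of a simulated fundus camera: frame size, the mean and
#' population spread of the ROI diameter it produces, the true pixel
#' pitch used to render ground truth, and the per-side fraction by which
#' the ROI circle may be cropped by the frame.
#'
#' @slot name character(1).
#' @slot imageSize integer(2), (W, H) in pixels.
#' @slot roiDiameterPx numeric(1), mean ROI diameter in pixels.
#' @slot roiDiameterSdPx numeric(1), sd of the ROI diameter in pixels.
#' @slot pitchUmTruth numeric(1), true pixel pitch in um/px.
#' @slot cropFraction numeric(1), per-side crop fraction in [0, 0.3].
#'
#' @seealso [cameraProfile()], [renderFundus()], [sampleCohort()]
#' @exportClass CameraProfile
setClass("CameraProfile",
  representation(name = "character", imageSize = "integer",
                 roiDiameterPx = "numeric", roiDiameterSdPx = "numeric",
                 pitchUmTruth = "numeric", cropFraction = "numeric"))

setValidity("CameraProfile", function(object) {
  d <- sqrt(sum(as.numeric(object@imageSize)^2))
  if (length(object@imageSize) != 2L || any(object@imageSize < 64L))
    return("'imageSize' must be two integers >= 64")
  if (object@roiDiameterPx <= 0 || object@roiDiameterPx > d)
    return("mean ROI diameter must be positive and at most the frame diagonal")
  if (object@roiDiameterSdPx < 0) return("'roiDiameterSdPx' must be >= 0")
  if (object@pitchUmTruth <= 0) return("'pitchUmTruth' must be positive")
  if (object@cropFraction < 0 || object@cropFraction > 0.3)
    return("'cropFraction' must lie in [0, 0.3]")
  TRUE
})
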