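# Constructors, accessors and show() methods for the core classes.

#' Construct an eye-plus-camera optical model
#'
#' @param f1 first focal length of the eye in mm.
#' @param alpha field of view in radians (use \code{fovDeg} for degrees).
#' @param fovDeg optional field of view in degrees; overrides
#'   \code{alpha} when given.
#' @param D axial ametropia in diopters; the retina offset is derived
#'   from it.
#' @param f0 camera focal length in mm, `NA` when unknown.
#' @param f2p,a informational: second focal length in vitreous and axial
#'   length, mm.
#' @return An [EyeCameraModel-class] object with \code{deltaD} consistent
#'   with \code{D}.
#' @examples
#' eyeCameraModel()                  # emmetropic 45-degree model
#' eyeCameraModel(D = -3.27)         # about 1 mm axial defocus
#' @export
eyeCameraModel <- function(f1 = 17.0, alpha = pi / 4, fovDeg = NULL,
                           D = 0, f0 = NA_real_, f2p = 22.7, a = 23.87) {
  if (!is.null(fovDeg)) alpha <- fovDeg * pi / 180
  new("EyeCameraModel", f1 = f1, alpha = alpha, D = D,
      deltaD = deltaDFromDiopter(D, f1), f0 = f0, f2p = f2p, a = a)
}

#' Construct a fundus image from a pixel array
#'
#' @param pixels numeric array of dim \code{c(W, H, 3)} with values in
#'   [0, 255] (a greyscale W x H matrix is replicated across channels).
#' @param id image identifier.
#' @param cameraLabel camera label.
#' @return A [FundusImage-class].
#' @export
fundusImage <- function(pixels, id = "", cameraLabel = "") {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  new("FundusImage", pixels = pixels, id = id, cameraLabel = cameraLabel)
}

#' @rdname fundusImage
#' @param object a [FundusImage-class].
#' @return \code{imageWidth}/\code{imageHeight}: frame size in pixels.
#' @export
imageWidth <- function(object) dim(object@pixels)[1L]

#' @rdname fundusImage
#' @export
imageHeight <- function(object) dim(object@pixels)[2L]

#' @rdname fundusImage
#' @param channel 1 = red, 2 = green, 3 = blue.
#' @return \code{channelMatrix}: one colour plane as a W x H matrix.
#' @export
channelMatrix <- function(object, channel) object@pixels[, , channel]

#' Accessors for measurement and estimate objects
#'
#' \code{roiDiameter} and \code{discDiameter} return fitted diameters in
#' pixels; \code{measurementCenter} the fitted centre; \code{pitch} and
#' \code{pitchUncertainty} the estimate and its propagated uncertainty in
#' um/px; \code{ratioMean}/\code{ratioSd} the offline ratio statistics;
#' \code{pooledMean}/\code{pooledSE}/\code{relativeWeights}/\code{tau2}
#' the meta-analysis summaries; \code{discPrior} converts a pooling
#' result into a [DiscDiameterPrior-class].
#'
#' @param object one of the package's S4 result objects.
#' @name accessors
NULL

#' @rdname accessors
#' @export
roiDiameter <- function(object) object@diameterPx

#' @rdname accessors
#' @export
discDiameter <- function(object) object@diameterPx

#' @rdname accessors
#' @export
measurementCenter <- function(object) object@center

#' @rdname accessors
#' @export
edgePoints <- function(object) object@edgePoints

#' @rdname accessors
#' @export
pitch <- function(object) object@pDisc

#' @rdname accessors
#' @export
pitchUncertainty <- function(object) object@uPdisc

#' @rdname accessors
#' @export
ratioMean <- function(object) object@rMean

#' @rdname accessors
#' @export
ratioSd <- function(object) object@rStd

#' @rdname accessors
#' @export
pooledMean <- function(object) object@pooled

#' @rdname accessors
#' @export
pooledSE <- function(object) object@se

#' @rdname accessors
#' @export
relativeWeights <- function(object) object@weights

#' @rdname accessors
#' @export
tau2 <- function(object) object@tau2

#' @rdname accessors
#' @export
discPrior <- function(object) {
  new("DiscDiameterPrior", lDisc = object@pooled, uLdisc = object@se,
      source = "random-effects pooling")
}

setMethod("show", "EyeCameraModel", function(object) {
  cat("EyeCameraModel: f1 =", object@f1, "mm, FOV =",
      round(object@alpha * 180 / pi, 2), "deg, D =", object@D,
      "dpt, deltaD =", signif(object@deltaD, 4), "mm\n")
})

setMethod("show", "FundusImage", function(object) {
  cat(sprintf("FundusImage '%s' (%s): %d x %d px, 3 channels\n",
              object@id, object@cameraLabel,
              imageWidth(object), imageHeight(object)))
})

setMethod("show", "RoiMeasurement", function(object) {
  cat(sprintf(
    "RoiMeasurement: center (%.1f, %.1f), diameter %.2f px, %d votes%s\n",
    object@center[1], object@center[2], object@diameterPx,
    round(object@votes),
    if (any(object@cropped))
      paste0(", cropped: ",
             paste(names(object@cropped)[object@cropped], collapse = "/"))
    else ""))
})

setMethod("show", "DiscMeasurement", function(object) {
  cat(sprintf(
    "DiscMeasurement: center (%.1f, %.1f), diameter %.2f px from %d edge points\n",
    object@center[1], object@center[2], object@diameterPx,
    nrow(object@edgePoints)))
})

setMethod("show", "RatioStatistics", function(object) {
  cat(sprintf(
    "RatioStatistics [%s]: r = %.3f +/- %.3f (n = %d), lROI = %.2f +/- %.3f px\n",
    object@scope, object@rMean, object@rStd, object@n,
    object@lRoiMean, object@lRoiStd))
})

setMethod("show", "DiscDiameterPrior", function(object) {
  cat(sprintf("DiscDiameterPrior: %.3f +/- %.3f mm (%s)\n",
              object@lDisc, object@uLdisc, object@source))
})

setMethod("show", "PooledDiscDiameter", function(object) {
  cat(sprintf(
    "PooledDiscDiameter: %.3f mm (SE %.3f), 95%% CI [%.3f, %.3f], tau2 = %.4g, k = %d\n",
    object@pooled, object@se, object@ci[1], object@ci[2], object@tau2,
    length(object@weights)))
})

setMethod("show", "PitchEstimate", function(object) {
  cat(sprintf("PitchEstimate (%s): %.3f +/- %.3f um/px",
              object@scenario, object@pDisc, object@uPdisc))
  if (is.finite(object@pIso))
    cat(sprintf("; ISO %.3f um/px, bias %+.3f um (%+.2f%%)",
                object@pIso, object@deltaP, object@deltaPRel))
  cat("\n")
})

setMethod("show", "CameraProfile", function(object) {
  cat(sprintf(
    "CameraProfile '%s': %d x %d px, ROI %.1f +/- %.2f px, pitch %.3f um/px, crop %.2f\n",
    object@name, object@imageSize[1], object@imageSize[2],
    object@roiDiameterPx, object@roiDiameterSdPx, object@pitchUmTruth,
    object@cropFraction))
})
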