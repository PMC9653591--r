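# Offline ratio statistics and online pixel-pitch estimation.
#
# The calibration constant is the ROI-to-disc diameter ratio
# r = lROI / ldisc measured in pixels, which is stable per camera (and
# approximately per field of view).  Combined with an anatomical prior
# L_disc on the physical optic-disc diameter, the pitch around the disc
# is P_disc = r * L_disc / lROI, with uncertainty propagated in
# quadrature over the relative uncertainties of r, L_disc and lROI.

#' Mean pixel pitch of a fundus image
#'
#' \eqn{\bar P = L_{ROI} / l_{ROI}}: physical ROI diameter over ROI
#' diameter in pixels.
#'
#' @param LRoiMm physical ROI diameter on the fundus in mm.
#' @param lRoiPx ROI diameter in pixels.
#' @return Mean pitch in um/px.
#' @export
meanPixelPitch <- function(LRoiMm, lRoiPx) {
  if (any(LRoiMm <= 0) || any(lRoiPx <= 0))
    stop("diameters must be positive")
  LRoiMm * 1000 / lRoiPx
}

#' ROI-to-disc diameter ratio
#'
#' @param lRoiPx ROI diameter in pixels.
#' @param lDiscPx optic-disc diameter in pixels.
#' @return Dimensionless ratio r.
#' @export
roiDiscRatio <- function(lRoiPx, lDiscPx) {
  if (any(lRoiPx <= 0)) stop("ROI diameter must be positive")
  if (any(lDiscPx <= 0)) stop("disc diameter must be positive")
  lRoiPx / lDiscPx
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Offline cohort calibration of the ROI-to-disc ratio
#'
#' Computes the cohort statistics of the per-image ratio: mean,
#' population (1/n) standard deviation, and the ROI-diameter mean and
#' population sd.  Images failing either detection enter as `NA` and are
#' dropped; when diopters are supplied, eyes with serious axial
#' ametropia (|D| above \code{maxAbsDiopter}) are excluded.  The ratio
#' of mean diameters is reported alongside for transparency.
#'
#' @param lRoiPx,lDiscPx numeric vectors of per-image ROI and disc
#'   diameters in pixels (`NA` = failed detection).
#' @param scope label for the cohort (camera name or e.g. "FOV45").
#' @param diopters optional per-image spherical equivalent in diopters.
#' @param maxAbsDiopter exclusion threshold for |D|.
#' @return A [RatioStatistics-class].
#' @examples
#' offlineCalibrate(c(1920, 1918), c(300, 299), scope = "demo")
#' @export
offlineCalibrate <- function(lRoiPx, lDiscPx, scope = "cohort",
                             diopters = NULL, maxAbsDiopter = 6) {
  stopifnot(length(lRoiPx) == length(lDiscPx))
  keep <- is.finite(lRoiPx) & is.finite(lDiscPx) & lRoiPx > 0 &
    lDiscPx > 0
  if (!is.null(diopters)) {
    stopifnot(length(diopters) == length(lRoiPx))
    keep <- keep & (!is.finite(diopters) |
                      abs(diopters) <= maxAbsDiopter)
  }
  lRoi <- lRoiPx[keep]; lDisc <- lDiscPx[keep]
  if (!length(lRoi)) stop("no valid measurement pairs after exclusion")
  r <- lRoi / lDisc
  new("RatioStatistics", scope = scope,
      rMean = mean(r), rStd = popSd(r), n = length(r),
      lRoiMean = mean(lRoi), lRoiStd = popSd(lRoi),
      rOfMeans = mean(lRoi) / mean(lDisc))
}

#' Pixel pitch around the optic disc from the ratio statistic
#'
#' \eqn{P_{disc} = r \, L_{disc} / l_{ROI}} converted to um/px.
#'
#' @param r ROI-to-disc ratio (dimensionless).
#' @param lDiscMm anatomical optic-disc diameter prior in mm.
#' @param lRoiPx measured ROI diameter of the image in pixels.
#' @return Pitch in um/px.
#' @examples
#' estimatePitch(6.404, 1.921, 1802.4)   # ~6.825 um/px
#' @export
estimatePitch <- function(r, lDiscMm, lRoiPx) {
  if (any(r <= 0) || any(lDiscMm <= 0) || any(lRoiPx <= 0))
    stop("all inputs must be positive")
  r * lDiscMm * 1000 / lRoiPx
}

#' Propagated uncertainty of the pitch estimate
#'
#' Quadrature propagation over the three factors of the pitch formula:
#' \eqn{U_P = P \sqrt{(U_r/r)^2 + (U_L/L)^2 + (U_l/l)^2}}.
#'
#' @param pDisc pitch estimate in um/px.
#' @param r,uR ratio and its uncertainty.
#' @param lDiscMm,uLdiscMm prior diameter and its uncertainty, mm.
#' @param lRoiPx,uLroiPx ROI diameter and its uncertainty, px.
#' @return Uncertainty in um/px.
#' @export
propagateUncertainty <- function(pDisc, r, uR, lDiscMm, uLdiscMm,
                                 lRoiPx, uLroiPx) {
  if (any(r <= 0) || any(lDiscMm <= 0) || any(lRoiPx <= 0))
    stop("denominators must be positive")
  if (any(uR < 0) || any(uLdiscMm < 0) || any(uLroiPx < 0))
    stop("uncertainties must be non-negative")
  pDisc * sqrt((uR / r)^2 + (uLdiscMm / lDiscMm)^2 +
                 (uLroiPx / lRoiPx)^2)
}

#' ISO 10940:2009 reference pitch
#'
#' At the standard's geometry (100 mm scale photographed at 1000 mm
#' from the entrance pupil) the pitch in micrometres is 1700 / N, where
#' N is the pixel count spanning the scale; the constant 1700 embodies
#' the 17 mm focal length of the emmetropic eye.
#'
#' @param N number of pixels covering the 100 mm scale.
#' @return Pitch in um/px.
#' @export
isoPitch <- function(N) {
  if (any(N <= 0)) stop("'N' must be positive")
  1700 / N
}

#' Bias of a pitch estimate against an ISO reference
#'
#' Absolute bias \eqn{\Delta P = P_{disc} - P_{ISO}} in um and relative
#' bias in percent.
#'
#' @param pDisc pitch estimate in um/px.
#' @param pIso ISO reference pitch in um/px.
#' @param digits optional rounding of \code{pDisc} before differencing,
#'   for comparison against tabulated values; `NA` (default) for none.
#' @return List with \code{deltaP} (um) and \code{deltaPRel} (percent).
#' @export
pitchBias <- function(pDisc, pIso, digits = NA) {
  if (any(pIso <= 0)) stop("'pIso' must be positive")
  if (is.finite(digits)) pDisc <- round(pDisc, digits)
  dp <- pDisc - pIso
  list(deltaP = dp, deltaPRel = 100 * dp / pIso)
}

#' Sensitivity of the pitch bias to the disc-diameter prior
#'
#' Recomputes the pitch estimate and its relative bias against the ISO
#' reference for each alternative value of the anatomical prior, per
#' camera.
#'
#' @param lDiscAltMm numeric vector of alternative prior diameters, mm.
#' @param r ratio used for the estimate (scalar, e.g. the FOV-wide
#'   mean, or one value per camera).
#' @param lRoiPx per-camera ROI diameters in pixels.
#' @param pIso per-camera ISO reference pitches in um/px.
#' @param cameras camera labels.
#' @param digits rounding of the intermediate pitch, as in
#'   [pitchBias()].
#' @return data.frame with columns \code{lDisc}, \code{camera},
#'   \code{pDisc} and \code{biasPct}.
#' @export
sensitivityToPrior <- function(lDiscAltMm, r, lRoiPx, pIso,
                               cameras = names(lRoiPx), digits = 3) {
  stopifnot(length(lRoiPx) == length(pIso))
  if (is.null(cameras)) cameras <- paste0("camera", seq_along(lRoiPx))
  r <- rep_len(r, length(lRoiPx))
  out <- do.call(rbind, lapply(lDiscAltMm, function(L) {
    p <- estimatePitch(r, L, lRoiPx)
    b <- pitchBias(p, pIso, digits = digits)
    data.frame(lDisc = L, camera = cameras, pDisc = p,
               biasPct = b$deltaPRel, row.names = NULL)
  }))
  out
}

#' Assemble a pitch estimate object
#'
#' Bundles a pitch value, its uncertainty, the scenario and (optionally)
#' the comparison against an ISO reference into a
#' [PitchEstimate-class].
#'
#' @param pDisc pitch in um/px.
#' @param uPdisc propagated uncertainty in um/px.
#' @param scenario "camera-specified" or "FOV-specified".
#' @param pIso optional ISO reference pitch in um/px.
#' @param digits rounding used for the bias, as in [pitchBias()].
#' @return A [PitchEstimate-class].
#' @export
pitchEstimate <- function(pDisc, uPdisc, scenario = "camera-specified",
                          pIso = NA_real_, digits = NA) {
  if (is.finite(digits)) pDisc <- round(pDisc, digits)
  if (is.finite(pIso)) {
    b <- pitchBias(pDisc, pIso, digits = digits)
    new("PitchEstimate", pDisc = pDisc, uPdisc = uPdisc,
        scenario = scenario, pIso = pIso, deltaP = b$deltaP,
        deltaPRel = b$deltaPRel)
  } else {
    new("PitchEstimate", pDisc = pDisc, uPdisc = uPdisc,
        scenario = scenario)
  }
}
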