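# The two-phase calibration workflow: the offline phase runs both
# detectors over a cohort and summarises the ROI-to-disc ratio; the
# online phase measures only the ROI of a single image and converts it
# to a pitch with the stored ratio and the anatomical prior.

#' Measure ROI and optic disc of one image
#'
#' @param image a [FundusImage-class].
#' @param roiArgs,discArgs lists of extra arguments for [detectROI()]
#'   and [measureDisc()].
#' @return List with \code{roi} ([RoiMeasurement-class]) and \code{disc}
#'   ([DiscMeasurement-class]); a failed disc measurement is returned as
#'   `NULL` with the message in \code{discError}.
#' @export
measureImage <- function(image, roiArgs = list(), discArgs = list()) {
  roi <- do.call(detectROI, c(list(image), roiArgs))
  disc <- NULL; discError <- NA_character_
  res <- tryCatch(
    do.call(measureDisc, c(list(image, roi = roi), discArgs)),
    error = function(e) e)
  if (inherits(res, "error")) discError <- conditionMessage(res)
  else disc <- res
  list(roi = roi, disc = disc, discError = discError)
}

#' Offline phase: cohort calibration of the ROI-to-disc ratio
#'
#' Runs ROI and disc detection over every image, logs and skips
#' per-image failures, applies the ametropia exclusion when diopters are
#' given, and summarises the retained ratios into a
#' [RatioStatistics-class].  Optionally writes the per-image table as
#' CSV.
#'
#' @param images list of [FundusImage-class] objects, or a directory
#'   path containing PNG/JPEG/TIFF files.
#' @param scope cohort label.
#' @param diopters optional per-image diopters (same order as
#'   \code{images}).
#' @param maxAbsDiopter ametropia exclusion threshold.
#' @param csvOut optional path for the per-image CSV.
#' @param roiArgs,discArgs passed to the detectors.
#' @return List with \code{stats} ([RatioStatistics-class]),
#'   \code{perImage} (data.frame) and \code{failures} (character).
#' @export
runOffline <- function(images, scope = "cohort", diopters = NULL,
                       maxAbsDiopter = 6, csvOut = NULL,
                       roiArgs = list(), discArgs = list()) {
  if (is.character(images) && length(images) == 1L) {
    files <- list.files(images, "\\.(png|jpe?g|tiff?)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (!length(files)) stop("no readable images in ", images)
    images <- lapply(files, function(f) {
      tryCatch(readFundusImage(f), error = function(e) {
        message("skipping unreadable file ", f, ": ",
                conditionMessage(e))
        NULL
      })
    })
    images <- images[!vapply(images, is.null, logical(1))]
    if (!length(images)) stop("no readable images")
  }
  rows <- list(); failures <- character()
  lRoi <- rep(NA_real_, length(images))
  lDisc <- rep(NA_real_, length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    m <- tryCatch(measureImage(img, roiArgs, discArgs),
                  error = function(e) e)
    if (inherits(m, "error")) {
      failures <- c(failures,
                    paste0(img@id, ": ", conditionMessage(m)))
      next
    }
    if (is.null(m$disc)) {
      failures <- c(failures, paste0(img@id, ": ", m$discError))
    } else {
      lRoi[i] <- roiDiameter(m$roi)
      lDisc[i] <- discDiameter(m$disc)
    }
    rows[[length(rows) + 1L]] <-
      measurementRow(img@id, img@cameraLabel, m$roi, m$disc)
  }
  perImage <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  if (!is.null(csvOut) && nrow(perImage))
    utils::write.csv(perImage, csvOut, row.names = FALSE)
  stats <- offlineCalibrate(lRoi, lDisc, scope = scope,
                            diopters = diopters,
                            maxAbsDiopter = maxAbsDiopter)
  list(stats = stats, perImage = perImage, failures = failures)
}

#' Online phase: pixel pitch of a single image
#'
#' Measures only the ROI diameter (no disc detection is needed online),
#' applies the pitch formula with the stored ratio statistics and the
#' anatomical prior, propagates the uncertainty, optionally compensates
#' for the eye's diopter, and optionally compares against an ISO
#' reference pitch.
#'
#' @param image a [FundusImage-class].
#' @param ratioStats a [RatioStatistics-class] from the offline phase.
#' @param prior a [DiscDiameterPrior-class].
#' @param scenario "camera-specified" or "FOV-specified".
#' @param diopter optional eye diopter for compensation.
#' @param isoPitch optional ISO reference pitch in um/px.
#' @param f1 first focal length of the eye, mm.
#' @param roiArgs passed to [detectROI()].
#' @return A [PitchEstimate-class] with the measured ROI diameter in
#'   attribute \code{lRoiPx}.
#' @export
runOnline <- function(image, ratioStats, prior,
                      scenario = "camera-specified", diopter = NULL,
                      isoPitch = NULL, f1 = 17, roiArgs = list()) {
  roi <- do.call(detectROI, c(list(image), roiArgs))
  lRoi <- roiDiameter(roi)
  p <- estimatePitch(ratioStats@rMean, prior@lDisc, lRoi)
  u <- propagateUncertainty(p, ratioStats@rMean, ratioStats@rStd,
                            prior@lDisc, prior@uLdisc, lRoi,
                            ratioStats@lRoiStd)
  if (!is.null(diopter) && is.finite(diopter)) {
    f <- compensatePitch(1, diopter, f1)   # (f1 + dd)/f1
    p <- p * f; u <- u * f
  }
  est <- pitchEstimate(p, u, scenario = scenario,
                       pIso = if (is.null(isoPitch)) NA_real_
                       else isoPitch)
  attr(est, "lRoiPx") <- lRoi
  est
}
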