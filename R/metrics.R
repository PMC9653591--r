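# Validation statistics: segmentation confusion-matrix metrics,
# diameter-stability statistics, and physical lesion areas.

#' Segmentation metrics from a pixel confusion matrix
#'
#' Accuracy (tp+tn)/total, sensitivity tp/(tp+fn), specificity
#' tn/(tn+fp) and intersection-over-union tp/(tp+fn+fp).  A metric whose
#' denominator is zero is returned as `NA` with a warning; the others
#' are unaffected.
#'
#' @param tp,fn,fp,tn pixel counts (non-negative, total > 0).
#' @return Named numeric: \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{iou}.
#' @examples
#' confusionMetrics(tp = 77114, fn = 2467, fp = 2543, tn = 2539982)
#' @export
confusionMetrics <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("confusion matrix is empty")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("undefined metric '", what, "': zero denominator")
      return(NA_real_)
    }
    num / den
  }
  c(accuracy = (tp + tn) / total,
    sensitivity = safe(tp, tp + fn, "sensitivity"),
    specificity = safe(tn, tn + fp, "specificity"),
    iou = safe(tp, tp + fn + fp, "iou"))
}

#' Stability statistics of a diameter series
#'
#' Mean, population (1/n) standard deviation, and the coefficient of
#' variation V = sigma / E, which removes the data scale so that
#' cameras of different resolution can be compared.
#'
#' @param xs numeric vector of diameter measurements (n >= 1).
#' @return Named numeric: \code{mean}, \code{sd}, \code{cv}.
#' @export
diameterStats <- function(xs) {
  if (!length(xs) || any(!is.finite(xs)))
    stop("'xs' must be a non-empty finite vector")
  E <- mean(xs)
  s <- popSd(xs)
  if (E == 0 && s > 0) stop("coefficient of variation undefined: mean is 0")
  c(mean = E, sd = s, cv = if (s == 0) 0 else s / E)
}

#' Physical lesion area from a pixel count
#'
#' Converts a segmented pixel count into mm^2 with the calibrated
#' pitch: \eqn{A = n_{px} (P/1000)^2}.
#'
#' @param pxCount number of lesion pixels (>= 0).
#' @param pitchUm pixel pitch in um/px (> 0).
#' @return Area in mm^2.
#' @examples
#' lesionArea(17586, 5.99)   # ~0.631 mm^2
#' @export
lesionArea <- function(pxCount, pitchUm) {
  if (any(pxCount < 0)) stop("'pxCount' must be non-negative")
  if (any(pitchUm <= 0)) stop("'pitchUm' must be positive")
  pxCount * (pitchUm / 1000)^2
}
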