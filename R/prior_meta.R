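# Meta-analytic prior on the physical optic-disc diameter.
#
# Published population studies of the vertical disc diameter are pooled
# with a DerSimonian-Laird random-effects model; the pooled mean and its
# standard error become the anatomical prior (L_disc, U_Ldisc) of the
# pitch formula.  The pooling itself is delegated to metafor.

#' Bundled literature table of vertical optic-disc diameters
#'
#' The seven population studies (mean vertical diameter in mm, standard
#' error in mm, sample size) that ship with the package as the default
#' input of the meta-analytic prior.  Also available as a CSV at
#' \code{system.file("extdata", "disc_diameter_studies.csv",
#' package = "fundusPitch")}.
#'
#' @return data.frame with columns \code{label}, \code{mean}, \code{se}
#'   and \code{n}.
#' @examples
#' poolRandomEffects(opticDiscStudies())
#' @export
opticDiscStudies <- function() {
  data.frame(
    label = c("study1", "study2", "study3", "study4", "study5",
              "study6", "study7"),
    mean = c(1.97, 1.88, 1.88, 1.98, 1.82, 1.96, 1.97),
    se = c(0.003, 0.023, 0.009, 0.036, 0.015, 0.018, 0.031),
    n = c(3918L, 118L, 475L, 62L, 110L, 122L, 88L),
    stringsAsFactors = FALSE)
}

#' Read a study table from CSV
#'
#' Expects columns \code{label}, \code{mean_mm}, \code{se_mm}, \code{n}.
#'
#' @param path CSV file path.
#' @return data.frame in the format of [opticDiscStudies()].
#' @export
readStudyTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "mean_mm", "se_mm", "n")
  if (!all(need %in% names(d)))
    stop("study table must have columns: ", paste(need, collapse = ", "))
  data.frame(label = as.character(d$label), mean = d$mean_mm,
             se = d$se_mm, n = as.integer(d$n),
             stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects pooling of disc-diameter studies
#'
#' Pools per-study means and standard errors: fixed-effect weights
#' 1/se^2 give Cochran's Q; the between-study variance is
#' tau^2 = max(0, (Q - df) / C) with C = sum(w) - sum(w^2)/sum(w);
#' random-effects weights 1/(se^2 + tau^2) give the pooled mean, its
#' standard error (sum of weights)^(-1/2), and per-study relative
#' weights in percent.  The 95% confidence interval is mean +/- 1.96 SE.
#' Standardised residuals (x - pooled)/sqrt(se^2 + tau^2) are reported
#' for information.
#'
#' @param studies data.frame with columns \code{mean} and \code{se}
#'   (and optionally \code{label}, \code{n}), one row per study.
#' @return A [PooledDiscDiameter-class]; use [discPrior()] to convert it
#'   into the [DiscDiameterPrior-class] consumed by [estimatePitch()].
#' @examples
#' pool <- poolRandomEffects(opticDiscStudies())
#' pooledMean(pool)     # 1.921 mm
#' pooledSE(pool)       # 0.026 mm
#' @export
poolRandomEffects <- function(studies) {
  if (!is.data.frame(studies) || nrow(studies) < 1L)
    stop("need at least one study")
  if (any(studies$se <= 0)) stop("standard errors must be positive")
  if (!is.null(studies$n) && any(studies$n < 1))
    stop("sample sizes must be at least 1")
  lab <- if (!is.null(studies$label)) as.character(studies$label)
  else paste0("study", seq_len(nrow(studies)))
  if (nrow(studies) == 1L) {
    pooled <- studies$mean[1L]; se <- studies$se[1L]
    tau2 <- 0; Q <- 0; w <- 100
  } else {
    fit <- metafor::rma(yi = studies$mean, sei = studies$se,
                        method = "DL")
    pooled <- as.numeric(fit$b); se <- fit$se
    tau2 <- fit$tau2; Q <- fit$QE
    w <- as.numeric(stats::weights(fit))
  }
  out <- studies
  out$label <- lab
  out$weightPct <- w
  out$stdResidual <- (studies$mean - pooled) / sqrt(studies$se^2 + tau2)
  new("PooledDiscDiameter", pooled = pooled, se = se,
      ci = pooled + c(-1, 1) * 1.96 * se, tau2 = tau2, Q = Q,
      weights = w, studies = out)
}

#' Equivalent-circle diameter from an area
#'
#' Studies reporting only the optic-disc area are converted to an
#' approximate diameter via the equivalent circle,
#' \eqn{d = 2\sqrt{A/\pi}}.
#'
#' @param areaMm2 area in mm^2.
#' @return Diameter in mm.
#' @export
diameterFromArea <- function(areaMm2) {
  if (any(areaMm2 <= 0)) stop("'areaMm2' must be positive")
  2 * sqrt(areaMm2 / pi)
}
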