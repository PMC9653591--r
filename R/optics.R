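# Reduced-eye and fundus-camera geometric optics.
#
# The eye is modelled as a single refracting surface with first focal
# length f1 (~17 mm in air).  In an emmetropic eye the retina coincides
# with the second focal plane and the camera-plus-eye system behaves as a
# telescope; axial ametropia displaces the retina by a signed offset
# delta d which rescales the magnification and every retinal length.
# Unit contract: lengths in mm, pitch in um, angles in radians; the
# f1 * D product is evaluated with f1 in metres (D is in diopters = 1/m).

#' Retina offset from the second focal plane for a given ametropia
#'
#' Converts an axial refractive error in diopters into the signed axial
#' displacement of the retina from the second focal plane of the reduced
#' eye, \eqn{\Delta d = -f_1^2 D / (1 + f_1 D)} with \eqn{f_1} in metres.
#' A myopic (negative-D) eye yields a positive offset of roughly 1 mm per
#' three diopters.
#'
#' @param D axial ametropia in diopters (signed); vectorised.
#' @param f1 first focal length of the eye in mm (default 17).
#' @return Signed retina offset in mm.
#' @examples
#' deltaDFromDiopter(0)        # 0: emmetropic
#' deltaDFromDiopter(-3.27)    # ~ +1 mm
#' @export
deltaDFromDiopter <- function(D, f1 = 17) {
  stopifnot(is.numeric(D), length(f1) == 1L, f1 > 0)
  f1m <- f1 / 1000                       # metres, so f1m * D is unitless
  den <- 1 + f1m * D
  if (any(abs(den) < 1e-12))
    stop("non-physical diopter for f1 = ", f1,
         " mm: denominator 1 + f1*D vanishes")
  -(f1m^2 * D) / den * 1000              # back to mm
}

#' @rdname deltaDFromDiopter
#' @param deltaD retina offset in mm (signed); vectorised.
#' @return \code{diopterFromDeltaD}: the ametropia in diopters that
#'   produces the given offset (inverse of \code{deltaDFromDiopter}).
#' @export
diopterFromDeltaD <- function(deltaD, f1 = 17) {
  stopifnot(is.numeric(deltaD), length(f1) == 1L, f1 > 0)
  f1m <- f1 / 1000
  dm <- deltaD / 1000
  den <- f1m * (f1m + dm)
  if (any(abs(den) < 1e-18))
    stop("non-physical retina offset for f1 = ", f1, " mm")
  -dm / den
}

#' Magnification of the fundus image
#'
#' \eqn{m = f_0 / (f_1 + \Delta d)}: the lateral magnification of the
#' camera-plus-eye telescope, where \code{f0} is the camera focal length.
#'
#' @param f0 camera focal length in mm.
#' @param f1 first focal length of the eye in mm.
#' @param deltaD retina offset from the second focal plane in mm.
#' @return Dimensionless magnification.
#' @export
magnification <- function(f0, f1 = 17, deltaD = 0) {
  den <- f1 + deltaD
  if (any(den <= 0)) stop("f1 + deltaD must be positive")
  f0 / den
}

#' Relative magnification bias of an ametropic eye
#'
#' The relative deviation \eqn{\Delta d / f_1} of the emmetropic
#' magnification from the ametropic one; a 1 mm retina offset at
#' f1 = 17 mm gives 5.9%.
#'
#' @param deltaD retina offset in mm (signed); vectorised.
#' @param f1 first focal length in mm.
#' @return Signed fractional bias (multiply by 100 for percent).
#' @export
magnificationBias <- function(deltaD, f1 = 17) {
  stopifnot(length(f1) == 1L, f1 > 0)
  deltaD / f1
}

#' Physical ROI diameter on the fundus
#'
#' Arc length \eqn{L_{ROI} = \alpha (f_1 + \Delta d)} subtended by the
#' camera's field of view on the retinal sphere of radius
#' \eqn{f_1 + \Delta d}.
#'
#' @param alpha field of view in radians.
#' @param f1 first focal length in mm.
#' @param deltaD retina offset in mm.
#' @return ROI diameter on the fundus in mm.
#' @examples
#' roiFundusDiameter(pi / 4)   # 45-degree FOV, emmetropic: ~13.35 mm
#' @export
roiFundusDiameter <- function(alpha, f1 = 17, deltaD = 0) {
  if (any(alpha <= 0)) stop("'alpha' must be positive (radians)")
  if (any(f1 + deltaD <= 0)) stop("f1 + deltaD must be positive")
  alpha * (f1 + deltaD)
}

#' Diopter compensation of a pixel-pitch estimate
#'
#' Rescales a pitch estimated under the emmetropic assumption to the
#' actual ametropic eye: \eqn{P' = P (f_1 + \Delta d) / f_1}.
#'
#' @param pDisc pitch estimate in um/px.
#' @param D axial ametropia of the eye in diopters.
#' @param f1 first focal length in mm.
#' @return Compensated pitch in um/px.
#' @export
compensatePitch <- function(pDisc, D, f1 = 17) {
  dd <- deltaDFromDiopter(D, f1)
  pDisc * (f1 + dd) / f1
}
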