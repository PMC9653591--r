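# Optic-disc diameter measurement: classical disc locating, polar
# resampling around the located centre, Canny edge detection in polar
# coordinates (where the disc boundary becomes a single-valued curve
# r(theta)), and the farthest-pair circumscribed-circle fit that defines
# the disc diameter.

#' Locate the optic disc
#'
#' Deterministic classical locator: the brightest connected region of
#' the median-smoothed mean of the red and green channels, restricted to
#' the candidate ROI mask and excluding a frame margin.  The strategy is
#' pluggable: any function \code{function(image, ...) c(x, y)} (for
#' example the box centre of an external detector) can be passed to
#' [measureDisc()] in its place, since the downstream geometry only
#' needs an approximate centre.
#'
#' @param image a [FundusImage-class].
#' @param contrast minimum brightness excess (on a [0, 1] scale) of the
#'   brightest region over the in-ROI median; below it the image is
#'   rejected with "disc not found".
#' @param marginFrac per-side frame margin excluded from the search, as
#'   a fraction of each dimension.
#' @param medianRadius radius of the median smoothing window in pixels.
#' @param mask optional logical ROI mask; computed from
#'   [binarizeRed()] + [largestComponent()] when missing.
#' @return numeric(2), approximate disc centre (x, y), 0-based.
#' @export
locateDisc <- function(image, contrast = 0.1, marginFrac = 0.05,
                       medianRadius = 3, mask = NULL) {
  W0 <- imageWidth(image); H0 <- imageHeight(image)
  gray <- (channelMatrix(image, 1L) + channelMatrix(image, 2L)) / 2 / 255
  if (is.null(mask)) mask <- largestComponent(binarizeRed(image))
  # locating only needs ~10 px accuracy: subsample large frames before
  # the (costly) median smoothing
  sub <- max(1L, floor(min(W0, H0) / 300))
  if (sub > 1L) {
    gray <- gray[seq(1L, W0, by = sub), seq(1L, H0, by = sub)]
    mask <- mask[seq(1L, W0, by = sub), seq(1L, H0, by = sub)]
  }
  W <- nrow(gray); H <- ncol(gray)
  med <- EBImage::medianFilter(gray, medianRadius)
  allowed <- mask
  mx <- max(1L, round(marginFrac * W)); my <- max(1L, round(marginFrac * H))
  allowed[c(seq_len(mx), W + 1 - seq_len(mx)), ] <- FALSE
  allowed[, c(seq_len(my), H + 1 - seq_len(my))] <- FALSE
  if (!any(allowed)) stop("disc not found: empty search region")
  vals <- med[allowed]
  bg <- stats::median(vals)
  peak <- max(vals)
  if (peak - bg < contrast)
    stop("disc not found: no region brighter than background by ",
         contrast)
  bright <- allowed & med >= (peak + bg) / 2
  # vessels crossing the disc cut the bright region; a small
  # morphological closing bridges them before labelling
  bright <- EBImage::closing(bright * 1,
                             EBImage::makeBrush(5, "disc")) > 0
  lab <- EBImage::bwlabel(bright * 1)
  at <- which(allowed & med == peak, arr.ind = TRUE)[1L, ]
  comp <- lab == lab[at[1L], at[2L]]
  idx <- which(comp, arr.ind = TRUE)
  (c(mean(idx[, 1L]), mean(idx[, 2L])) - 1) * sub
}

#' Polar resampling of a fundus image around a centre
#'
#' Samples the mean of the red and green channels on a polar grid of
#' \code{nTheta} equally spaced angles and radii \code{dr, 2 dr, ...}
#' up to \code{rMax}, by bilinear interpolation (0 outside the frame).
#' A circle centred on the origin maps to a constant row, and the
#' boundary of an offset disc maps to a single-valued curve r(theta).
#'
#' @param image a [FundusImage-class].
#' @param center numeric(2), origin of the transform (x, y), 0-based;
#'   must lie inside the frame.
#' @param nTheta number of angular samples (>= 16).
#' @param dr radial step in pixels.
#' @param rMax maximum radius in pixels.
#' @return A list with \code{values} (nR x nTheta matrix, rows indexed
#'   by radius), \code{radii}, \code{thetas} and \code{center}.
#' @export
polarTransform <- function(image, center, nTheta = 360, dr = 1,
                           rMax = 120) {
  W <- imageWidth(image); H <- imageHeight(image)
  stopifnot(length(center) == 2L, nTheta >= 16L, dr > 0, rMax >= 16 * dr)
  if (center[1] < 0 || center[1] > W - 1 || center[2] < 0 ||
      center[2] > H - 1)
    stop("'center' must lie inside the frame")
  gray <- (channelMatrix(image, 1L) + channelMatrix(image, 2L)) / 2
  radii <- seq(dr, rMax, by = dr)
  thetas <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
  x <- center[1] + outer(radii, cos(thetas))
  y <- center[2] + outer(radii, sin(thetas))
  vals <- matrix(bilinearSample(gray, as.vector(x), as.vector(y)),
                 length(radii), nTheta)
  list(values = vals, radii = radii, thetas = thetas, center = center)
}

#' Optic-disc edge points from a polar raster
#'
#' Canny edge detection on the polar raster, then one edge radius per
#' angular column: among the Canny edges of that column, the pixel with
#' the strongest outward-darkening radial gradient — the disc boundary
#' is a bright-to-dark transition along the radius, whereas vessel side
#' edges run radially and carry mostly angular gradient (ties towards
#' the smallest radius).
#' Columns without any edge are skipped; if fewer than
#' \code{minColsFrac} of the columns yield an edge the image is rejected
#' ("edge too weak").  Selected radii then pass a radial-consistency
#' gate: columns whose radius deviates from the cohort median by more
#' than \code{maxDevFrac} of the median are discarded, which suppresses
#' spurious responses from vessels crossing the disc boundary.  The
#' surviving (theta, r) samples are mapped back to Cartesian
#' coordinates.
#'
#' @param polar output of [polarTransform()].
#' @param sigma,low,high Canny parameters on the polar raster.
#' @param minColsFrac minimum fraction of angular columns that must
#'   yield an edge.
#' @param maxDevFrac radial-consistency gate width as a fraction of the
#'   median selected radius; `Inf` disables the gate.
#' @param rMin radii below this value (px) are excluded from the edge
#'   search; near the origin a vessel a few pixels wide subtends a large
#'   angular range and would otherwise dominate many columns.
#' @return N x 2 matrix of Cartesian edge points, with the selected
#'   polar samples in attributes \code{theta} and \code{r}.
#' @export
detectDiscEdge <- function(polar, sigma = 1.5, low = 0.1, high = 0.3,
                           minColsFrac = 0.5, maxDevFrac = 0.35,
                           rMin = 0) {
  v <- polar$values
  cn <- cannyEdges(v, sigma = sigma, low = low, high = high)
  nTheta <- ncol(v)
  selR <- rep(NA_real_, nTheta)
  if (rMin > 0) cn$edge[polar$radii < rMin, ] <- FALSE
  # rows of the polar raster index the radius, so cn$gx is the radial
  # derivative; the disc boundary darkens outward (negative)
  score <- -cn$gx * cn$edge
  score[score <= 0] <- 0
  hit <- colSums(score) > 0
  if (sum(hit) < minColsFrac * nTheta)
    stop("edge too weak: edges in ", sum(hit), " of ", nTheta,
         " angular columns")
  # strongest outward-darkening response per column; which.max takes
  # the first (smallest radius) on ties
  rows <- apply(score[, hit, drop = FALSE], 2L, which.max)
  selR[hit] <- polar$radii[rows]
  if (is.finite(maxDevFrac)) {
    mr <- stats::median(selR, na.rm = TRUE)
    selR[abs(selR - mr) > maxDevFrac * mr] <- NA_real_
  }
  # isolated spikes (vessels crossing the boundary) are lethal to a
  # farthest-pair diameter: reject columns deviating from a circular
  # running median of r(theta), which smooth elliptical variation passes
  use <- which(!is.na(selR))
  if (length(use) > 15L) {
    robs <- selR[use]
    pad <- 5L
    med <- stats::runmed(c(robs[(length(robs) - pad + 1L):length(robs)],
                           robs, robs[1:pad]), 11L)
    med <- med[(pad + 1L):(pad + length(robs))]
    tol <- pmax(1.5, 0.05 * stats::median(robs))
    selR[use[abs(robs - med) > tol]] <- NA_real_
  }
  use <- which(!is.na(selR))
  if (length(use) < minColsFrac * nTheta)
    stop("edge too weak: only ", length(use),
         " consistent edge columns of ", nTheta)
  th <- polar$thetas[use]; r <- selR[use]
  pts <- cbind(x = polar$center[1] + r * cos(th),
               y = polar$center[2] + r * sin(th))
  attr(pts, "theta") <- th
  attr(pts, "r") <- r
  pts
}

#' Farthest-pair circumscribed-circle fit
#'
#' The disc diameter is defined as the largest pairwise Euclidean
#' distance over the edge points, and the circle centre as the midpoint
#' of that farthest pair.  This is deliberately not the minimum
#' enclosing circle: for an irregular (roughly elliptical) disc the
#' farthest pair tracks the major axis.  The pair is found exactly;
#' for large point sets the search is restricted to the convex hull,
#' which contains every farthest pair.  Ties are broken towards the
#' lexicographically smallest index pair.
#'
#' @param points N x 2 matrix of (x, y) coordinates, N >= 2.
#' @return A [DiscMeasurement-class].
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' fitCircumscribedCircle(sq)   # diameter sqrt(2), centre (0.5, 0.5)
#' @export
fitCircumscribedCircle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) != 2L)
    stop("need at least 2 points (N x 2 matrix)")
  n <- nrow(points)
  cand <- seq_len(n)
  if (n > 1500L) {
    hull <- sort(unique(grDevices::chull(points)))
    if (length(hull) >= 2L) cand <- hull
  }
  p <- points[cand, , drop = FALSE]
  sq <- rowSums(p^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(p)
  d2[lower.tri(d2, diag = TRUE)] <- -Inf
  m <- max(d2)
  # the expanded form above can be off by a few ulp: re-evaluate the
  # near-maximal pairs with the direct difference formula
  at <- which(d2 >= m - 1e-6 * max(m, 1), arr.ind = TRUE)
  ii <- cand[at[, 1L]]; jj <- cand[at[, 2L]]
  d2e <- (points[ii, 1L] - points[jj, 1L])^2 +
    (points[ii, 2L] - points[jj, 2L])^2
  best <- which(d2e == max(d2e))
  best <- best[order(ii[best], jj[best])][1L]
  i <- ii[best]; j <- jj[best]
  new("DiscMeasurement",
      center = as.numeric((points[i, ] + points[j, ]) / 2),
      edgePoints = unname(points),
      diameterPx = sqrt(sum((points[i, ] - points[j, ])^2)),
      farthestPair = as.integer(c(i, j)))
}

#' Measure the optic-disc diameter of a fundus image
#'
#' Full disc chain: locate the disc (with a pluggable locator), resample
#' the image in polar coordinates around the located centre, detect the
#' disc edge per angular column, and fit the farthest-pair circumscribed
#' circle.
#'
#' @param image a [FundusImage-class].
#' @param roi optional [RoiMeasurement-class]; when given, the expected
#'   disc radius defaults to the ROI diameter divided by twice the
#'   nominal ROI-to-disc ratio of a 45-degree camera (6.404).
#' @param locator locating strategy, a function
#'   \code{function(image, ...) c(x, y)}; defaults to [locateDisc()].
#' @param expectedRadius expected disc radius in pixels; the polar
#'   raster extends to three times this value.
#' @param nTheta,dr polar sampling resolution.
#' @param ... passed on to [detectDiscEdge()].
#' @return A [DiscMeasurement-class].
#' @export
measureDisc <- function(image, roi = NULL, locator = locateDisc,
                        expectedRadius = NULL, nTheta = 360, dr = 1,
                        ...) {
  center <- locator(image)
  if (is.null(expectedRadius)) {
    expectedRadius <- if (!is.null(roi)) roiDiameter(roi) / (2 * 6.404)
    else min(imageWidth(image), imageHeight(image)) / 12
  }
  polar <- polarTransform(image, center, nTheta = nTheta, dr = dr,
                          rMax = 3 * expectedRadius)
  pts <- detectDiscEdge(polar, rMin = 0.45 * expectedRadius, ...)
  fitCircumscribedCircle(pts)
}
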