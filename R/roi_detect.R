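# Detection of the circular region of interest (the valid imaging area)
# of a fundus photograph.  The ROI is bright against a dark frame and is
# often cropped top and bottom, so the circle is recovered with a
# gradient-voting circular Hough transform over the edge of the
# candidate mask: surviving arcs of a cropped circle still vote for the
# true centre and radius.

#' Threshold the red channel at one third of its mean
#'
#' The red channel carries the highest brightness in a fundus
#' photograph; thresholding it at one third of its whole-frame mean
#' separates the illuminated imaging area from the dark frame.
#'
#' @param image a [FundusImage-class].
#' @return Logical W x H matrix, `TRUE` inside the bright area.
#' @export
binarizeRed <- function(image) {
  red <- channelMatrix(image, 1L)
  if (all(red == 0)) stop("blank image: red channel is all zero")
  red >= mean(red) / 3
}

#' Keep the largest connected component of a binary mask
#'
#' 8-connected labelling; area ties are broken towards the component
#' whose bounding box has the smallest top-left corner (smallest y, then
#' smallest x).
#'
#' @param mask logical or 0/1 matrix.
#' @return Logical matrix retaining only the largest component.
#' @export
largestComponent <- function(mask) {
  if (!any(mask)) stop("empty mask: no foreground pixels")
  lab <- EBImage::bwlabel(mask * 1)
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    corner <- vapply(best, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      c(min(idx[, 2L]), min(idx[, 1L]))        # (ymin, xmin)
    }, numeric(2))
    best <- best[order(corner[1, ], corner[2, ])][1L]
  }
  lab == best
}

# algebraic least-squares circle fit (Kasa): minimises
# sum((x - cx)^2 + (y - cy)^2 - r^2)^2, linear in (2cx, 2cy, r^2 - |c|^2)
kasaCircle <- function(x, y) {
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  p <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(p)) return(NULL)
  p <- unname(p)
  cx <- p[1] / 2; cy <- p[2] / 2
  r2 <- p[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(cx = cx, cy = cy, r = sqrt(r2))
}

#' Detect the circular ROI of a fundus photograph
#'
#' Pipeline: red-channel binarisation, largest connected component,
#' Canny edge map of the candidate mask (so ROI texture cannot
#' contribute edges), then a gradient-voting circular Hough transform.
#' Each edge pixel votes for candidate centres along both directions of
#' its gradient for every radius in the search range; the accumulator
#' peak gives the centre (refined to sub-pixel by a local centroid) and
#' the modal distance from the edge points to that centre gives the
#' radius.  Edge pixels within \code{frameMargin} pixels of the image
#' border are excluded from voting: where the circle is cropped the mask
#' boundary runs along the frame and carries no information about the
#' circle.
#'
#' @param image a [FundusImage-class].
#' @param radiusRange numeric(2), search range for the radius as
#'   fractions of \code{max(W, H)}.
#' @param sigma Canny pre-smoothing sd in pixels.
#' @param cannyLow,cannyHigh Canny hysteresis fractions.
#' @param minVoteFrac minimum fraction of edge pixels that must support
#'   the winning circle; below it the fit is rejected.
#' @param frameMargin width in pixels of the border strip whose edge
#'   pixels are ignored.
#' @return A [RoiMeasurement-class].
#' @examples
#' prof <- cameraProfile("demo", c(320, 320), roiDiameterPx = 240,
#'                       pitchUmTruth = 50)
#' img <- renderFundus(prof, seed = 1)
#' detectROI(img)
#' @export
detectROI <- function(image, radiusRange = c(0.25, 0.75), sigma = 2,
                      cannyLow = 0.1, cannyHigh = 0.3,
                      minVoteFrac = 0.2, frameMargin = 2) {
  W <- imageWidth(image); H <- imageHeight(image)
  mask <- largestComponent(binarizeRed(image))
  cn <- cannyEdges(mask * 1, sigma = sigma, low = cannyLow,
                   high = cannyHigh)
  edge <- cn$edge
  if (frameMargin > 0) {
    fm <- seq_len(frameMargin)
    edge[fm, ] <- FALSE; edge[W + 1 - fm, ] <- FALSE
    edge[, fm] <- FALSE; edge[, H + 1 - fm] <- FALSE
  }
  idx <- which(edge, arr.ind = TRUE)
  np <- nrow(idx)
  if (np < 8L) stop("ROI not found: too few edge pixels")
  xs <- idx[, 1L] - 1; ys <- idx[, 2L] - 1
  gx <- cn$gx[idx]; gy <- cn$gy[idx]
  nrm <- sqrt(gx^2 + gy^2)
  ok <- nrm > 0
  xs <- xs[ok]; ys <- ys[ok]
  nx <- gx[ok] / nrm[ok]; ny <- gy[ok] / nrm[ok]
  np <- length(xs)

  rmin <- max(4, floor(radiusRange[1] * max(W, H)))
  rmax <- ceiling(radiusRange[2] * max(W, H))
  radii <- seq.int(rmin, rmax)

  # centre accumulator over all radii, voting both along and against
  # the gradient so the sign convention of the mask does not matter
  votes <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    cx <- round(c(xs + r * nx, xs - r * nx))
    cy <- round(c(ys + r * ny, ys - r * ny))
    keep <- cx >= 0 & cx < W & cy >= 0 & cy < H
    votes[[k]] <- (cx[keep] + 1) + cy[keep] * W
  }
  acc <- matrix(tabulate(unlist(votes), nbins = W * H), W, H)

  # 3x3 smoothing, then sub-pixel refinement by local centroid
  sm <- shiftMat(acc, 0, 0)
  for (dx in -1:1) for (dy in -1:1)
    if (dx != 0 || dy != 0) sm <- sm + shiftMat(acc, dx, dy)
  peak <- which(sm == max(sm), arr.ind = TRUE)
  if (nrow(peak) > 1L) {     # tie: centre closest to the frame centre
    d2 <- (peak[, 1L] - (W + 1) / 2)^2 + (peak[, 2L] - (H + 1) / 2)^2
    peak <- peak[which.min(d2), , drop = FALSE]
  }
  px <- peak[1, 1L]; py <- peak[1, 2L]
  wx <- max(1, px - 2):min(W, px + 2)
  wy <- max(1, py - 2):min(H, py + 2)
  wts <- sm[wx, wy]
  cxr <- sum(outer(wx - 1, rep(1, length(wy))) * wts) / sum(wts)
  cyr <- sum(outer(rep(1, length(wx)), wy - 1) * wts) / sum(wts)

  # radius: modal 1 px bin of edge-point distances to the voted centre;
  # ties towards larger radius
  d <- sqrt((xs - cxr)^2 + (ys - cyr)^2)
  inr <- d >= rmin - 4 & d <= rmax + 4
  if (!any(inr)) stop("ROI not found: no edge support in radius range")
  bin <- pmin(pmax(round(d[inr]) - rmin + 1L, 1L), rmax - rmin + 1L)
  counts <- tabulate(bin, nbins = rmax - rmin + 1L)
  mode <- radii[max(which(counts == max(counts)))]
  supp <- inr & abs(d - mode) <= 4
  if (sum(supp) < minVoteFrac * np)
    stop("ROI not found: best circle supported by ", sum(supp), " of ",
         np, " edge pixels")

  # sub-pixel refinement: iterated least-squares (Kasa) circle fit on
  # the supporting arc, shrinking the inlier window; this removes the
  # accumulator's 1 px quantisation and tolerates gradient-direction
  # noise of blocky mask boundaries
  cx <- cxr; cy <- cyr; radius <- mean(d[supp])
  for (win in c(4, 2.5, 1.5)) {
    supp <- abs(sqrt((xs - cx)^2 + (ys - cy)^2) - radius) <= win
    if (sum(supp) < 3L) break
    fit <- kasaCircle(xs[supp], ys[supp])
    if (is.null(fit)) break
    cx <- fit$cx; cy <- fit$cy; radius <- fit$r
  }
  dfin <- sqrt((xs - cx)^2 + (ys - cy)^2)
  nvotes <- sum(abs(dfin - radius) <= 2.5)
  if (nvotes < minVoteFrac * np)
    stop("ROI not found: best circle supported by ", nvotes, " of ",
         np, " edge pixels")
  cxr <- cx; cyr <- cy

  cropped <- c(left = cxr - radius < -0.5,
               top = cyr - radius < -0.5,
               right = cxr + radius > W - 0.5,
               bottom = cyr + radius > H - 0.5)
  new("RoiMeasurement", center = c(cxr, cyr), diameterPx = 2 * radius,
      votes = as.numeric(nvotes), cropped = cropped)
}
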