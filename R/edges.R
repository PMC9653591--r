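# Canny edge detector on plain matrices (x-first orientation).  EBImage
# supplies blur and labelling but no Canny, so the classic chain is
# implemented here: Gaussian smoothing, Sobel gradients, non-maximum
# suppression along the quantised gradient direction, and two-threshold
# hysteresis realised as connected-component selection.

shiftMat <- function(m, dx, dy) {
  # translate by (dx, dy) with zero fill; dx along the first (x) index
  W <- nrow(m); H <- ncol(m)
  out <- matrix(0, W, H)
  xs <- max(1, 1 + dx):min(W, W + dx)
  ys <- max(1, 1 + dy):min(H, H + dy)
  out[xs, ys] <- m[xs - dx, ys - dy]
  out
}

# separable convolution with a centred 1-D kernel along x then y;
# replicate padding via index clamping (kernels here are 3-13 taps, so
# direct shifting beats an FFT on these image sizes)
sepConv <- function(m, kx, ky = kx) {
  W <- nrow(m); H <- ncol(m)
  conv <- function(m, k, along) {
    n2 <- (length(k) - 1L) / 2L
    acc <- matrix(0, W, H)
    for (i in seq_along(k)) {
      off <- i - 1L - n2
      if (along == 1L) {
        idx <- pmin(pmax(seq_len(W) - off, 1L), W)
        acc <- acc + k[i] * m[idx, , drop = FALSE]
      } else {
        idx <- pmin(pmax(seq_len(H) - off, 1L), H)
        acc <- acc + k[i] * m[, idx, drop = FALSE]
      }
    }
    acc
  }
  conv(conv(m, kx, 1L), ky, 2L)
}

gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Canny edge detection on a single-channel raster
#'
#' Standard Canny chain with hysteresis thresholds expressed as
#' fractions of the maximum gradient magnitude after non-maximum
#' suppression.  Weak edge pixels are kept only when 8-connected to a
#' strong pixel.
#'
#' @param m numeric matrix, x-first orientation.
#' @param sigma Gaussian pre-smoothing sd in pixels.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   suppressed gradient magnitude.
#' @return A list with logical matrix \code{edge}, gradient components
#'   \code{gx}, \code{gy} and magnitude \code{mag} (all same dim as
#'   \code{m}).
#' @export
cannyEdges <- function(m, sigma = 2, low = 0.1, high = 0.3) {
  stopifnot(is.matrix(m), sigma > 0, low >= 0, high >= low)
  g <- sepConv(m, gaussKernel(sigma))
  gx <- sepConv(g, c(1, 0, -1), c(1, 2, 1))
  gy <- sepConv(g, c(1, 2, 1), c(1, 0, -1))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax <= 0)
    return(list(edge = matrix(FALSE, nrow(m), ncol(m)),
                gx = gx, gy = gy, mag = mag))

  # non-maximum suppression: quantise direction (mod 180 deg) to 4 bins
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4L)     # 0:x 1:diag 2:y 3:anti-diag
  keep <- matrix(FALSE, nrow(m), ncol(m))
  offs <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(1L, -1L))
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    n1 <- shiftMat(mag, o[1], o[2])
    n2 <- shiftMat(mag, -o[1], -o[2])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  nms <- mag * keep

  strong <- nms >= high * mmax
  weak <- nms >= low * mmax
  if (!any(strong))
    return(list(edge = strong, gx = gx, gy = gy, mag = mag))
  lab <- EBImage::bwlabel(weak * 1)
  good <- unique(lab[strong])
  good <- good[good > 0]
  edge <- weak & matrix(lab %in% good, nrow(m), ncol(m))
  list(edge = edge, gx = gx, gy = gy, mag = mag)
}

# bilinear sampling of matrix m at continuous 0-based (x, y); outside the
# frame the value 'fill' is returned
bilinearSample <- function(m, x, y, fill = 0) {
  W <- nrow(m); H <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  v <- numeric(length(x))
  pick <- function(xi, yi) {
    ok <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
    out <- numeric(length(xi))
    out[ok] <- m[cbind(xi[ok] + 1, yi[ok] + 1)]
    out[!ok] <- fill
    out
  }
  v <- pick(x0, y0) * (1 - fx) * (1 - fy) +
    pick(x0 + 1, y0) * fx * (1 - fy) +
    pick(x0, y0 + 1) * (1 - fx) * fy +
    pick(x0 + 1, y0 + 1) * fx * fy
  v
}
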