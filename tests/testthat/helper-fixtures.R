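# Shared fixtures, built in code.  The demo profile is small enough to
# keep per-test detection fast; the desk profiles scale the four
# camera-like profiles down geometrically (pitch scales up inversely).

demoProfile <- function(roiDiameterPx = 240, cropFraction = 0,
                        imageSize = c(320, 320), pitchUmTruth = 50) {
  cameraProfile("demo", imageSize, roiDiameterPx = roiDiameterPx,
                roiDiameterSdPx = 0, pitchUmTruth = pitchUmTruth,
                cropFraction = cropFraction)
}

demoImage <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- renderFundus(demoProfile(), seed = 42)
    cache
  }
})

# grayscale phantom with a bright disc (circle or ellipse) on a mid-grey
# background; a, b are semi-axes in px
discPhantom <- function(size = 400, a = 120, b = a, bg = 130,
                        fg = 230, center = NULL) {
  if (is.null(center)) center <- c((size - 1) / 2, (size - 1) / 2)
  X <- matrix(rep(seq_len(size) - 1, size), size, size)
  Y <- matrix(rep(seq_len(size) - 1, each = size), size, size)
  e <- sqrt(((X - center[1]) / a)^2 + ((Y - center[2]) / b)^2)
  w <- pmin(pmax(((1 - e) * min(a, b) + 0.75) / 1.5, 0), 1)
  m <- matrix(bg + (fg - bg) * w, size, size)
  fundusImage(m, id = "phantom")
}

# brute-force farthest-pair oracle used against the circumscribed fit
bruteFarthestPair <- function(pts) {
  n <- nrow(pts)
  best <- c(0, 1L, 2L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d2 <- sum((pts[i, ] - pts[j, ])^2)
    if (d2 > best[1]) best <- c(d2, i, j)
  }
  list(diameter = sqrt(best[1]), i = as.integer(best[2]),
       j = as.integer(best[3]))
}

# closed-form DerSimonian-Laird pooling, independent of metafor
dlPoolOracle <- function(m, s) {
  w <- 1 / s^2
  mu_fe <- sum(w * m) / sum(w)
  Q <- sum(w * (m - mu_fe)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (length(m) - 1)) / C)
  wr <- 1 / (s^2 + tau2)
  list(pooled = sum(wr * m) / sum(wr), se = 1 / sqrt(sum(wr)),
       tau2 = tau2, weights = 100 * wr / sum(wr))
}
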