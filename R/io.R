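# Image and table I/O.  Raster reading/writing is delegated to EBImage
# (PNG, JPEG, TIFF); pixel values are held on the 0-255 scale
# regardless of bit depth on disk.

#' Read a fundus photograph from disk
#'
#' Reads PNG/JPEG/TIFF through EBImage, rescales to [0, 255], replicates
#' greyscale rasters across the three channels, and drops any alpha
#' plane.
#'
#' @param path image file.
#' @param id image identifier (defaults to the file name).
#' @param cameraLabel camera label.
#' @return A [FundusImage-class].
#' @export
readFundusImage <- function(path, id = basename(path),
                            cameraLabel = "") {
  img <- EBImage::readImage(path)
  d <- dim(img)
  px <- EBImage::imageData(img)
  if (length(d) == 2L) {
    px <- array(rep(px, 3L), dim = c(d, 3L))
  } else if (d[3] >= 3L) {
    px <- px[, , 1:3]
  } else {
    px <- array(rep(px[, , 1L], 3L), dim = c(d[1:2], 3L))
  }
  if (max(px) <= 1) px <- px * 255
  fundusImage(px, id = id, cameraLabel = cameraLabel)
}

#' Write a fundus photograph to disk
#'
#' @param image a [FundusImage-class].
#' @param path destination file; format from the extension (png, jpg,
#'   tiff).
#' @return Invisibly, \code{path}.
#' @export
writeFundusImage <- function(image, path) {
  EBImage::writeImage(EBImage::Image(image@pixels / 255,
                                     colormode = "Color"), path)
  invisible(path)
}

# one per-image CSV row for the offline phase
measurementRow <- function(id, cameraLabel, roi, disc) {
  data.frame(
    id = id, camera_label = cameraLabel,
    center_x = roi@center[1], center_y = roi@center[2],
    roi_diameter_px = roi@diameterPx, votes = roi@votes,
    cropped_flags = paste(ifelse(roi@cropped, "1", "0"),
                          collapse = ""),
    disc_center_x = if (is.null(disc)) NA_real_ else disc@center[1],
    disc_center_y = if (is.null(disc)) NA_real_ else disc@center[2],
    disc_diameter_px = if (is.null(disc)) NA_real_ else disc@diameterPx,
    n_edge_points = if (is.null(disc)) NA_integer_
    else nrow(disc@edgePoints),
    stringsAsFactors = FALSE)
}
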