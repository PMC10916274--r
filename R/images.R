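# Raster I/O and small image utilities.
#
# Convention throughout the package: images are numeric arrays in [0, 1],
# indexed [row, col] (grayscale matrix) or [row, col, channel] (RGB),
# 0-based pixel coordinates with x = column and y = row.

#' Read a raster image
#'
#' Supports PNG, TIFF and JPEG (8- or 16-bit, 1- or 3-channel); an alpha
#' channel, if present, is dropped. Values are scaled to `[0, 1]`.
#'
#' @param path image file path.
#' @return numeric matrix (grayscale) or `[row, col, 3]` array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format '.%s' (png/tiff/jpeg supported): %s",
                 ext, path), call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) img <- img[, , 1L]          # gray + alpha
    else if (dim(img)[3] >= 4L) img <- img[, , 1:3]    # drop alpha
    else if (dim(img)[3] == 1L) img <- img[, , 1L]
  }
  img
}

#' Write a raster image
#'
#' @param image numeric matrix or `[row, col, 3]` array in `[0, 1]`.
#' @param path output path; format chosen from the extension (png/tiff/jpeg).
#' @param bits bit depth for TIFF output (8 or 16); PNG/JPEG are written 8-bit.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 8L) {
  image[image < 0] <- 0
  image[image > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = if (bits == 16L) 16L else 8L),
    jpg = , jpeg = jpeg::writeJPEG(image, path, quality = 0.95),
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

#' Convert an image to grayscale
#'
#' Uses Rec. 601 luma weights for RGB input; grayscale input is returned as-is.
#'
#' @param image numeric matrix or `[row, col, 3]` array.
#' @return numeric matrix.
#' @export
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3L)
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' @keywords internal
as_rgb <- function(image) {
  if (is.matrix(image)) {
    array(image, dim = c(dim(image), 3L))
  } else image
}

# height/width of an image (rows, cols)
image_dims <- function(image) dim(image)[1:2]

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# linear contrast stretch to [0, 1]; constant images map to 0
stretch01 <- function(m) {
  r <- range(m)
  if (r[2] - r[1] < .Machine$double.eps) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

#' Bilinear sampling of a matrix at continuous coordinates
#'
#' Coordinates are 0-based (`x` = column, `y` = row); samples outside the
#' image return `fill`.
#'
#' @param m numeric matrix.
#' @param x,y numeric vectors of equal length.
#' @param fill value for out-of-bounds samples.
#' @return numeric vector of samples.
#' @keywords internal
bilinear_sample <- function(m, x, y, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inb <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1
  # clamp corner indices; weights zero out contributions past the border
  gx0 <- pmin(pmax(x0, 0), w - 1); gx1 <- pmin(pmax(x0 + 1, 0), w - 1)
  gy0 <- pmin(pmax(y0, 0), h - 1); gy1 <- pmin(pmax(y0 + 1, 0), h - 1)
  idx <- function(xx, yy) yy + 1 + xx * h  # column-major linear index
  v00 <- m[idx(gx0, gy0)]; v10 <- m[idx(gx1, gy0)]
  v01 <- m[idx(gx0, gy1)]; v11 <- m[idx(gx1, gy1)]
  # zero weight for the clamped side when the true neighbour is outside
  wx1 <- ifelse(x0 + 1 > w - 1 | x0 + 1 < 0, 0, fx)
  wx0 <- ifelse(x0 < 0 | x0 > w - 1, 0, 1 - fx)
  wy1 <- ifelse(y0 + 1 > h - 1 | y0 + 1 < 0, 0, fy)
  wy0 <- ifelse(y0 < 0 | y0 > h - 1, 0, 1 - fy)
  sw <- (wx0 + wx1) * (wy0 + wy1)
  val <- v00 * wx0 * wy0 + v10 * wx1 * wy0 + v01 * wx0 * wy1 + v11 * wx1 * wy1
  out <- ifelse(inb & sw > 0, val / ifelse(sw > 0, sw, 1), fill)
  out
}
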