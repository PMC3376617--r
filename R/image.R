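#' Raster image container
#'
#' A `raster_image` is an H x W x 3 integer array of 8-bit RGB values in
#' `[0, 255]`, the input type of the whole pipeline.
#'
#' @param pixels numeric or integer H x W x 3 array (RGB order), values in
#'   `[0, 255]`.
#' @return An object of class `raster_image` (the array with class attribute).
#' @export
raster_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    pp_error("pp_invalid_input", "pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    pp_error("pp_invalid_input", "image must have at least one pixel")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    pp_error("pp_invalid_input", "channel values must be in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image %d x %d, 8-bit RGB>\n", d[1], d[2]))
  invisible(x)
}

#' Read an RGB image from disk
#'
#' Supports PNG natively; JPEG and TIFF when the corresponding reader
#' packages are installed. Grayscale input is expanded to three channels,
#' an alpha channel is dropped.
#'
#' @param path file path (`.png`, `.jpg`/`.jpeg`, `.tif`/`.tiff`).
#' @return A [raster_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    pp_error("pp_io_error", sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        pp_error("pp_io_error", "JPEG support requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        pp_error("pp_io_error", "TIFF support requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    pp_error("pp_io_error", sprintf("unsupported image format: .%s", ext))
  )
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3] == 1L) arr <- array(arr, c(dim(arr)[1:2], 3L))
  raster_image(round(arr * 255))
}

#' Write an RGB image as PNG
#'
#' @param img a [raster_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Convert an RGB image to HSV channels
#'
#' Standard hexcone conversion. Hue is scaled to `[0, 1)` (red at 0, wrapping),
#' saturation and value to `[0, 1]`.
#'
#' @param img a [raster_image()].
#' @return A list of class `hsv_image` with H x W matrices `h`, `s`, `v`.
#' @export
rgb_to_hsv_image <- function(img) {
  if (!inherits(img, "raster_image")) img <- raster_image(img)
  d <- dim(img)
  m <- rbind(
    r = as.vector(img[, , 1]),
    g = as.vector(img[, , 2]),
    b = as.vector(img[, , 3])
  )
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  out <- list(
    h = matrix(hsv[1, ] %% 1, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
  class(out) <- "hsv_image"
  out
}

# Vectorized HSV -> 8-bit RGB (used by the synthetic generator).
hsv_to_rgb8 <- function(h, s, v) {
  rgb01 <- grDevices::col2rgb(grDevices::hsv(h %% 1, pmin(pmax(s, 0), 1),
                                             pmin(pmax(v, 0), 1)))
  rgb01
}
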