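#' Segmentation configuration
#'
#' @param band numeric length-2 hue band `c(low, high)` in `[0, 1]`. The mask
#'   keeps pixels with `low <= h < high`. When `low > high` the band wraps
#'   through 0 (`h >= low | h < high`), which red-hued insects need. Use
#'   `"auto"` to pick the band from the hue histogram (see Details).
#' @param connectivity 4 or 8 (default); neighbourhood used when searching the
#'   largest connected region. 8-connectivity is more robust for thin legs.
#' @param auto_bins number of hue histogram bins used by `band = "auto"`.
#'
#' @details The automatic band is a reproducible heuristic, not a value from
#' any calibration dataset: the hue histogram is binned, the two
#' highest-count bins at circular distance >= 2 are taken as the foreground
#' and background modes, and the band boundary is placed at the
#' minimum-frequency valley between them; the side of the valley carrying
#' less total pixel mass is taken as the insect (the insect is assumed
#' smaller than the background).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(band = "auto", connectivity = 8L,
                                auto_bins = 32L) {
  if (!connectivity %in% c(4L, 8L))
    pp_error("pp_invalid_input", "connectivity must be 4 or 8")
  if (!identical(band, "auto")) {
    band <- as.numeric(band)
    if (length(band) != 2L || anyNA(band) || any(band < 0) || any(band > 1))
      pp_error("pp_invalid_input", "band must be two hue values in [0, 1] or 'auto'")
  }
  structure(list(band = band, connectivity = as.integer(connectivity),
                 auto_bins = as.integer(auto_bins)),
            class = "segmentation_config")
}

#' Threshold the hue channel into a binary mask
#'
#' Static hue-band thresholding: a pixel is foreground iff its hue falls in
#' `[t_low, t_high)`; with `wrap = TRUE` and `t_low > t_high` the band wraps
#' through red (`h >= t_low | h < t_high`).
#'
#' @param hsv an `hsv_image` from [rgb_to_hsv_image()].
#' @param t_low,t_high band edges in `[0, 1]`.
#' @param wrap allow a wrapping band when `t_low > t_high`.
#' @return An integer H x W 0/1 matrix. All-zero when no pixel falls in the
#'   band (the caller decides whether that is a failure).
#' @export
threshold_h <- function(hsv, t_low, t_high, wrap = FALSE) {
  stopifnot(inherits(hsv, "hsv_image"))
  if (t_low < 0 || t_high > 1 || t_low > 1 || t_high < 0)
    pp_error("pp_invalid_input", "band edges must lie in [0, 1]")
  if (t_low > t_high && !wrap)
    pp_error("pp_invalid_input", "t_low > t_high requires wrap = TRUE")
  h <- hsv$h
  m <- if (t_low <= t_high) (h >= t_low & h < t_high)
       else (h >= t_low | h < t_high)
  storage.mode(m) <- "integer"
  m
}

#' Label connected regions of a binary mask
#'
#' Queue-based flood fill (iterative; no recursion depth limit). Labels are
#' positive integers in row-major discovery order.
#'
#' @param mask integer/logical H x W matrix, nonzero = foreground.
#' @param connectivity 4 or 8.
#' @return Integer H x W matrix of region labels, 0 = background.
#' @export
label_regions <- function(mask, connectivity = 8L) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  .cc_label(mask, as.integer(connectivity))
}

#' Keep only the largest connected region
#'
#' Implements "searching the maximum linked area": all connected regions of
#' 1-pixels are found and only the largest is retained, removing noise blobs.
#' Among equal-sized largest regions, the one containing the earliest
#' 1-pixel in row-major order wins (deterministic tie rule).
#'
#' @inheritParams label_regions
#' @return 0/1 integer matrix with a single connected region.
#' @export
keep_largest_region <- function(mask, connectivity = 8L) {
  lab <- label_regions(mask, connectivity)
  n <- max(lab)
  if (n == 0L)
    pp_error("pp_segmentation_failure", "no foreground region in mask")
  if (n > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    # which.max returns the first maximum = smallest label = earliest
    # row-major discovery among ties
    best <- which.max(sizes)
    lab[] <- as.integer(lab == best)
  } else {
    lab[] <- as.integer(lab > 0L)
  }
  lab
}

# Pick a hue band from the histogram: valley between the two largest modes.
auto_band <- function(h, bins = 32L) {
  counts <- tabulate(pmin(floor(h * bins), bins - 1L) + 1L, nbins = bins)
  p1 <- which.max(counts)
  # second mode: largest-count bin at circular distance >= 2 from the first
  circ <- pmin(abs(seq_len(bins) - p1), bins - abs(seq_len(bins) - p1))
  cand <- which(circ >= 2L)
  if (length(cand) == 0L) return(c(0, 1))
  p2 <- cand[which.max(counts[cand])]
  lo <- min(p1, p2); hi <- max(p1, p2)
  between <- seq(lo + 1L, hi - 1L)
  valley <- between[which.min(counts[between])]
  cut <- (valley - 0.5) / bins  # left edge of the valley bin
  mass_left <- sum(counts[seq_len(valley - 1L)])
  mass_right <- sum(counts) - mass_left - counts[valley]
  if (mass_left <= mass_right) c(0, cut) else c(cut, 1)
}

#' Segment the insect from a field photograph
#'
#' The full preprocessing pipeline: RGB to HSV conversion, static hue-band
#' thresholding, binarization, and denoising by keeping the largest
#' connected region.
#'
#' @param img a [raster_image()] (or H x W x 3 array).
#' @param cfg a [segmentation_config()].
#' @return A list of class `segmentation_mask` with elements `mask` (0/1
#'   integer matrix, a single connected region), `region_size`, and `band`
#'   (the hue band actually used).
#' @export
segment <- function(img, cfg = segmentation_config()) {
  if (!inherits(img, "raster_image")) img <- raster_image(img)
  hsv <- rgb_to_hsv_image(img)
  band <- cfg$band
  if (identical(band, "auto")) band <- auto_band(hsv$h, cfg$auto_bins)
  m <- threshold_h(hsv, band[1], band[2], wrap = band[1] > band[2])
  if (!any(m == 1L))
    pp_error("pp_segmentation_failure",
             sprintf("no pixel in hue band [%.3f, %.3f)", band[1], band[2]))
  m <- keep_largest_region(m, cfg$connectivity)
  structure(list(mask = m, region_size = sum(m), band = band),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask %d x %d, region of %d px, hue band [%.3f, %.3f)>\n",
              nrow(x$mask), ncol(x$mask), x$region_size, x$band[1], x$band[2]))
  invisible(x)
}

#' Write a binary mask as a PNG file
#'
#' @param mask a `segmentation_mask` or 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  png::writePNG(matrix(as.numeric(m > 0), nrow(m), ncol(m)), path)
  invisible(path)
}
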