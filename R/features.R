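#' Color moments of a channel over a masked region
#'
#' The first three color moments of the pixel values `p_j` inside the mask:
#' mean `E = (1/N) sum p_j`, population standard deviation
#' `sigma = sqrt((1/N) sum (p_j - E)^2)`, and skewness
#' `s = cbrt((1/N) sum (p_j - E)^3)` using the real signed cube root so that
#' negative skew is representable.
#'
#' @param channel numeric H x W matrix (e.g. one HSV channel).
#' @param mask 0/1 matrix of the same shape (or a `segmentation_mask`).
#' @return Named numeric vector `c(E, sigma, s)`.
#' @export
color_moments <- function(channel, mask) {
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  v <- channel[m > 0]
  if (length(v) == 0L)
    pp_error("pp_invalid_input", "empty mask in color_moments")
  e <- mean(v)
  dev <- v - e
  sigma <- sqrt(mean(dev^2))
  m3 <- mean(dev^3)
  s <- sign(m3) * abs(m3)^(1 / 3)
  c(E = e, sigma = sigma, s = s)
}

#' Binary shape moments of a region
#'
#' Raw moments `m_pq = sum x^p y^q`, central moments `mu_pq`, and normalized
#' central moments `eta_pq = mu_pq / mu00^((p+q)/2 + 1)` up to order 3,
#' computed over the coordinates of the 1-pixels (binary shape moments; the
#' region is binarized before geometric features are extracted). Coordinates
#' are pixel centers at 0-based integers, `x` = column, `y` = row.
#'
#' @param mask 0/1 matrix or `segmentation_mask`.
#' @return A list of class `moment_set` with matrices `m`, `mu`, `eta`
#'   indexed `[p + 1, q + 1]`.
#' @export
shape_moments <- function(mask) {
  msk <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  idx <- which(msk > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    pp_error("pp_invalid_input", "empty mask in shape_moments")
  x <- idx[, "col"] - 1  # 0-based pixel centers
  y <- idx[, "row"] - 1
  m <- mu <- eta <- matrix(NA_real_, 4, 4,
                           dimnames = list(p = 0:3, q = 0:3))
  xp <- outer(x, 0:3, `^`)
  yq <- outer(y, 0:3, `^`)
  for (p in 0:3) for (q in 0:3) if (p + q <= 3)
    m[p + 1, q + 1] <- sum(xp[, p + 1] * yq[, q + 1])
  xb <- m[2, 1] / m[1, 1]
  yb <- m[1, 2] / m[1, 1]
  xc <- outer(x - xb, 0:3, `^`)
  yc <- outer(y - yb, 0:3, `^`)
  for (p in 0:3) for (q in 0:3) if (p + q <= 3)
    mu[p + 1, q + 1] <- sum(xc[, p + 1] * yc[, q + 1])
  for (p in 0:3) for (q in 0:3) if (p + q >= 2 && p + q <= 3)
    eta[p + 1, q + 1] <- mu[p + 1, q + 1] / m[1, 1]^((p + q) / 2 + 1)
  structure(list(m = m, mu = mu, eta = eta), class = "moment_set")
}

#' The two Hu invariant moments used for classification
#'
#' `phi1 = eta20 + eta02` and `phi2 = (eta20 - eta02)^2 + 4 eta11^2`,
#' invariant to translation, scale and rotation of the region.
#'
#' @param ms a `moment_set` from [shape_moments()] (or a mask, which is
#'   converted first).
#' @return Named numeric vector `c(phi1, phi2)`.
#' @export
hu_features <- function(ms) {
  if (!inherits(ms, "moment_set")) ms <- shape_moments(ms)
  eta20 <- ms$eta[3, 1]; eta02 <- ms$eta[1, 3]; eta11 <- ms$eta[2, 2]
  c(phi1 = eta20 + eta02, phi2 = (eta20 - eta02)^2 + 4 * eta11^2)
}

#' Eccentricity ratio of a region
#'
#' `EC = p / q` where `p >= q` are the semi-axis lengths of the momental
#' ellipse — the ellipse with the same second central moments as the region:
#' `p, q = 2 sqrt(eigenvalues of [[mu20, mu11], [mu11, mu02]] / mu00)`.
#' Always `>= 1`; 1 for a disc.
#'
#' @param mask 0/1 matrix or `segmentation_mask`.
#' @param max_cap value returned for degenerate (collinear) regions whose
#'   smaller eigenvalue is 0; default `Inf`.
#' @return A single numeric value.
#' @export
eccentricity <- function(mask, max_cap = Inf) {
  msk <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  if (sum(msk > 0) == 1L) return(1.0)  # single pixel: EC = 1 by convention
  ms <- shape_moments(msk)
  cov <- matrix(c(ms$mu[3, 1], ms$mu[2, 2], ms$mu[2, 2], ms$mu[1, 3]),
                2, 2) / ms$m[1, 1]
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= .Machine$double.eps * max(ev[1], 1)) return(max_cap)
  sqrt(ev[1] / ev[2])
}

# Minimum enclosing circle radius of a point set (2-column matrix). The
# point set is reduced to its convex hull, then Welzl's move-to-front
# algorithm (compiled) gives the exact radius.
min_enclosing_radius <- function(pts) {
  hull <- pts[unique(grDevices::chull(pts)), , drop = FALSE]
  if (nrow(hull) == 1L) return(0)
  .mec_radius(hull)
}

#' Sphericity of a region
#'
#' `SP = r_i / r_c`: the ratio of the inscribed-circle radius to the
#' circumscribed-circle radius of the region. `r_i` is the maximum of the
#' exact Euclidean distance transform over region pixels (distance to the
#' nearest background pixel); `r_c` is the radius of the minimum enclosing
#' circle of the region treated as a union of unit pixel squares (the circle
#' is fitted over the corner points of the hull pixels). SP is clamped to
#' `(0, 1]`; raster discretization can otherwise push `r_i` marginally above
#' `r_c` for near-circular regions.
#'
#' @param mask 0/1 matrix or `segmentation_mask`.
#' @return A single numeric value in `(0, 1]`.
#' @export
sphericity <- function(mask) {
  msk <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  storage.mode(msk) <- "integer"
  if (sum(msk > 0) == 0L)
    pp_error("pp_invalid_input", "empty mask in sphericity")
  if (sum(msk > 0) == 1L) return(1.0)  # single pixel: SP = 1 by convention
  ri <- sqrt(max(.edt_sq(msk)[msk > 0]))
  idx <- which(msk > 0, arr.ind = TRUE)
  centers <- cbind(idx[, "col"] - 1, idx[, "row"] - 1)
  hull <- centers[unique(grDevices::chull(centers)), , drop = FALSE]
  corners <- rbind(
    cbind(hull[, 1] - 0.5, hull[, 2] - 0.5),
    cbind(hull[, 1] - 0.5, hull[, 2] + 0.5),
    cbind(hull[, 1] + 0.5, hull[, 2] - 0.5),
    cbind(hull[, 1] + 0.5, hull[, 2] + 0.5)
  )
  rc <- min_enclosing_radius(corners)
  min(1, ri / rc)
}

#' Names of the 13 pipeline features, in order
#' @return Character vector of length 13.
#' @export
feature_names <- function() {
  c("E_H", "sigma_H", "s_H", "E_S", "sigma_S", "s_S",
    "E_V", "sigma_V", "s_V", "EC", "SP", "phi1", "phi2")
}

#' Extract the 13-dimensional feature vector
#'
#' Assembles, in fixed order, the nine color moments (mean, standard
#' deviation, skewness of the H, S and V channels over the masked insect
#' pixels), the eccentricity ratio, the sphericity, and the two Hu invariant
#' moments of the mask.
#'
#' @param img a [raster_image()].
#' @param mask a `segmentation_mask` from [segment()] (or a 0/1 matrix).
#' @param channels `"hsv"` (default: moments over the HSV channels of masked
#'   pixels) or `"rgb"` (over raw channels scaled to `[0, 1]`), kept for
#'   experimentation.
#' @return Named numeric vector of length 13 (see [feature_names()]).
#' @export
extract_features <- function(img, mask, channels = c("hsv", "rgb")) {
  channels <- match.arg(channels)
  if (!inherits(img, "raster_image")) img <- raster_image(img)
  msk <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  chans <- if (channels == "hsv") {
    hsv <- rgb_to_hsv_image(img)
    list(hsv$h, hsv$s, hsv$v)
  } else {
    lapply(1:3, function(i) img[, , i] / 255)
  }
  cm <- unlist(lapply(chans, color_moments, mask = msk))
  ms <- shape_moments(msk)
  out <- c(cm, eccentricity(msk), sphericity(msk), hu_features(ms))
  names(out) <- feature_names()
  out
}

#' Write / read feature vectors as CSV
#'
#' One row per image: an `image_id` column, the 13 feature columns named as
#' in [feature_names()], and an optional final `label` column.
#'
#' @param x data frame or matrix of feature rows (13 columns in order), or a
#'   list of named vectors from [extract_features()].
#' @param path CSV path.
#' @param ids image identifiers (recycled from `rownames` when missing).
#' @param labels optional class labels.
#' @return `path` invisibly for the writer; a data frame for the reader.
#' @export
write_features_csv <- function(x, path, ids = NULL, labels = NULL) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.data.frame(x)
  if (ncol(x) == 14L && "label" %in% names(x)) {
    labels <- x$label
    x <- x[feature_names()]
  }
  stopifnot(ncol(x) == 13L)
  names(x) <- feature_names()
  if (is.null(ids)) ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("img%04d", seq_len(nrow(x)))
  out <- cbind(data.frame(image_id = ids), x)
  if (!is.null(labels)) out$label <- labels
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path))
    pp_error("pp_io_error", sprintf("feature file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", feature_names())
  if (!all(need %in% names(df)))
    pp_error("pp_io_error", "feature CSV lacks the required 13-feature header")
  df
}
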