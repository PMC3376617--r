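#' Class specification for the synthetic insect generator
#'
#' Describes one insect class as a distribution over elliptical bodies:
#' semi-axis ranges, a hue band, saturation/value statistics, noise blob
#' counts and the background hue. The generator renders one body per image,
#' so every geometric feature has an analytic oracle.
#'
#' @param name class label.
#' @param major,minor length-2 ranges (pixels) for the body semi-axes.
#' @param hue_center body hue center in `[0, 1)`.
#' @param hue_spread per-pixel hue standard deviation (truncated at 2.5 sd).
#' @param hue_center_sd per-individual standard deviation of the body hue:
#'   each image draws its own hue center from
#'   `N(hue_center, hue_center_sd)`. This, not the per-pixel noise, is what
#'   makes classes overlap — a per-image mean over thousands of pixels
#'   averages per-pixel noise away.
#' @param sat_mean,sat_spread body saturation mean / spread.
#' @param value_mean,value_spread body value (brightness) mean / per-pixel
#'   spread; `value_spread` also models surface texture.
#' @param value_mean_sd per-individual standard deviation of the body value.
#' @param n_noise_blobs length-2 range for the number of small hue-sharing
#'   noise blobs rendered away from the body.
#' @param background_hue background hue in `[0, 1)`.
#' @param rotate maximum absolute body rotation in radians (pose jitter).
#' @param value_jitter maximum absolute global value shift (lighting jitter).
#' @return A list of class `class_spec`.
#' @export
class_spec <- function(name, major, minor, hue_center, hue_spread = 0.01,
                       hue_center_sd = 0, sat_mean = 0.75, sat_spread = 0.04,
                       value_mean = 0.65, value_spread = 0.04,
                       value_mean_sd = 0,
                       n_noise_blobs = c(0L, 3L), background_hue = 0.83,
                       rotate = 0, value_jitter = 0) {
  stopifnot(length(major) == 2L, length(minor) == 2L,
            hue_center >= 0, hue_center < 1)
  structure(list(name = name, major = major, minor = minor,
                 hue_center = hue_center, hue_spread = hue_spread,
                 hue_center_sd = hue_center_sd,
                 sat_mean = sat_mean, sat_spread = sat_spread,
                 value_mean = value_mean, value_spread = value_spread,
                 value_mean_sd = value_mean_sd,
                 n_noise_blobs = as.integer(n_noise_blobs),
                 background_hue = background_hue, rotate = rotate,
                 value_jitter = value_jitter),
            class = "class_spec")
}

#' Default six-class specifications
#'
#' Six insect classes emulating a field pest trap collection of six common
#' rice/field pest species. In the `easy` regime the class-conditional hue
#' and shape distributions do not overlap; in the `field_like` regime hue
#' bands overlap with their neighbours, axis ranges overlap, and every image
#' gets pose jitter (free rotation) and lighting jitter (a global value
#' shift) — emulating live pests whose pose and illumination vary
#' unpredictably in the field.
#'
#' @param regime `"easy"` or `"field_like"`.
#' @return A list of six [class_spec()] objects.
#' @export
class_specs <- function(regime = c("easy", "field_like")) {
  regime <- match.arg(regime)
  nm <- c("Cnaphalocrocis medinalis", "Chilo suppressalis",
          "Sesamia inferens", "Naranga aenescens",
          "Anomala cupripes", "Prodenia litura")
  if (regime == "easy") {
    list(
      class_spec(nm[1], major = c(26, 30), minor = c(20, 23), hue_center = 0.06,
                 value_mean = 0.75),
      class_spec(nm[2], major = c(30, 34), minor = c(14, 16), hue_center = 0.17,
                 value_mean = 0.55),
      class_spec(nm[3], major = c(34, 38), minor = c(11, 13), hue_center = 0.29,
                 value_mean = 0.70),
      class_spec(nm[4], major = c(21, 24), minor = c(17, 19), hue_center = 0.41,
                 value_mean = 0.45),
      class_spec(nm[5], major = c(28, 31), minor = c(8, 10), hue_center = 0.52,
                 value_mean = 0.80),
      class_spec(nm[6], major = c(37, 41), minor = c(18, 21), hue_center = 0.63,
                 value_mean = 0.60)
    )
  } else {
    # overlapping hue bands and axis ranges + per-individual color
    # variation + pose and lighting jitter
    jit <- function(name, major, minor, hue, vm)
      class_spec(name, major = major, minor = minor, hue_center = hue,
                 hue_spread = 0.03, hue_center_sd = 0.030,
                 value_mean = vm, value_spread = 0.08, value_mean_sd = 0.08,
                 rotate = pi, value_jitter = 0.15, n_noise_blobs = c(1L, 4L))
    list(
      jit(nm[1], c(24, 32), c(16, 22), 0.10, 0.66),
      jit(nm[2], c(27, 35), c(13, 19), 0.16, 0.58),
      jit(nm[3], c(30, 38), c(11, 17), 0.22, 0.66),
      jit(nm[4], c(22, 30), c(14, 20), 0.28, 0.54),
      jit(nm[5], c(26, 34), c(9, 15), 0.34, 0.70),
      jit(nm[6], c(32, 40), c(15, 21), 0.40, 0.62)
    )
  }
}

# truncated normal noise, vectorized
rtnorm <- function(n, mean, sd, width = 2.5) {
  mean + pmin(pmax(stats::rnorm(n, 0, sd), -width * sd), width * sd)
}

#' Render one labeled synthetic insect image
#'
#' Renders a rotated filled ellipse (the body) with per-pixel HSV noise on a
#' uniform-hue background, plus small noise blobs that share the body's hue
#' but are disjoint from it. The returned ground-truth mask is the exact
#' rasterization of the body.
#'
#' @param spec a [class_spec()].
#' @param seed integer seed; the draw is deterministic given `(spec, seed)`.
#' @param height,width canvas size in pixels.
#' @return A list of class `labeled_image`: `image` (a [raster_image()]),
#'   `truth_mask` (0/1 matrix), `label`, and `truth_params` (the sampled
#'   body parameters).
#' @export
make_image <- function(spec, seed = 1L, height = 96L, width = 128L) {
  stopifnot(inherits(spec, "class_spec"))
  if (max(spec$major) * 2 + 8 > min(height, width))
    pp_error("pp_invalid_input", "body axes exceed the canvas")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  a <- runif(1, spec$major[1], spec$major[2])
  b <- runif(1, spec$minor[1], spec$minor[2])
  theta <- if (spec$rotate > 0) runif(1, -spec$rotate, spec$rotate) else 0
  margin <- a + 4
  cy <- runif(1, margin, height - 1 - margin)
  cx <- runif(1, margin, width - 1 - margin)
  row <- matrix(0:(height - 1), height, width)
  col <- matrix(0:(width - 1), height, width, byrow = TRUE)
  xr <- (col - cx) * cos(theta) + (row - cy) * sin(theta)
  yr <- -(col - cx) * sin(theta) + (row - cy) * cos(theta)
  body <- (xr / a)^2 + (yr / b)^2 <= 1
  truth <- matrix(as.integer(body), height, width)

  npx <- height * width
  h <- rtnorm(npx, spec$background_hue, 0.006)
  s <- rtnorm(npx, 0.50, 0.04)
  vshift <- if (spec$value_jitter > 0) runif(1, -spec$value_jitter, spec$value_jitter) else 0
  v <- rtnorm(npx, 0.55, 0.04)
  # per-individual draws: this insect's own hue and brightness
  hc <- rtnorm(1, spec$hue_center, spec$hue_center_sd, width = 2)
  vm <- rtnorm(1, spec$value_mean, spec$value_mean_sd, width = 2)
  nb <- sum(body)
  # foreground hue stays inside the [0, 0.72) band (no wrap through red),
  # so the truth mask is exactly recoverable by hue thresholding
  h[body] <- pmin(pmax(rtnorm(nb, hc, spec$hue_spread), 0.004), 0.712)
  s[body] <- rtnorm(nb, spec$sat_mean, spec$sat_spread)
  v[body] <- rtnorm(nb, vm, spec$value_spread)

  # noise blobs: small discs sharing the body hue, disjoint from the body
  n_blobs <- if (spec$n_noise_blobs[2] > 0)
    sample(spec$n_noise_blobs[1]:spec$n_noise_blobs[2], 1) else 0L
  blobs <- matrix(FALSE, height, width)
  placed <- 0L
  tries <- 0L
  while (placed < n_blobs && tries < 50L) {
    tries <- tries + 1L
    r <- runif(1, 1.5, 3.5)
    by <- runif(1, r + 1, height - 2 - r)
    bx <- runif(1, r + 1, width - 2 - r)
    # keep the blob clear of the body so the truth mask stays exact
    if (sqrt((by - cy)^2 + (bx - cx)^2) < a + r + 4) next
    blob <- (row - by)^2 + (col - bx)^2 <= r^2
    if (!any(blob)) next
    blobs <- blobs | blob
    placed <- placed + 1L
  }
  if (any(blobs)) {
    nbl <- sum(blobs)
    h[blobs] <- pmin(pmax(rtnorm(nbl, hc, spec$hue_spread), 0.004), 0.712)
    s[blobs] <- rtnorm(nbl, spec$sat_mean, spec$sat_spread)
    v[blobs] <- rtnorm(nbl, vm, spec$value_spread)
  }
  v <- pmin(pmax(v + vshift, 0.05), 1)
  rgb <- hsv_to_rgb8(h, s, v)
  img <- array(0L, c(height, width, 3L))
  img[, , 1] <- matrix(rgb[1, ], height, width)
  img[, , 2] <- matrix(rgb[2, ], height, width)
  img[, , 3] <- matrix(rgb[3, ], height, width)
  structure(list(image = raster_image(img), truth_mask = truth,
                 label = spec$name,
                 truth_params = list(a = a, b = b, theta = theta,
                                     center = c(cy, cx), vshift = vshift,
                                     n_blobs = placed)),
            class = "labeled_image")
}

#' Hue band that separates generator foregrounds from the background
#'
#' All default class hues lie below 0.7 and the background above 0.78, so a
#' fixed band recovers every body.
#' @return Numeric length-2 band for [segmentation_config()].
#' @export
generator_band <- function() c(0, 0.72)

#' Generate a balanced labeled dataset
#'
#' @param specs list of [class_spec()] (default: [class_specs()] for the
#'   chosen regime).
#' @param n_per_class images per class: a single count or one count per class.
#' @param regime `"easy"` or `"field_like"` (used when `specs` is NULL).
#' @param seed integer master seed; per-image seeds are drawn from it.
#' @param height,width canvas size.
#' @return A list of class `labeled_dataset`: `images` (list of
#'   `labeled_image`), `labels`, `regime`.
#' @export
make_dataset <- function(n_per_class, regime = c("easy", "field_like"),
                         seed = 1L, specs = NULL,
                         height = 96L, width = 128L) {
  regime <- match.arg(regime)
  if (is.null(specs)) specs <- class_specs(regime)
  k <- length(specs)
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, k)
  stopifnot(length(n_per_class) == k)
  if (all(n_per_class == 0L))
    pp_error("pp_invalid_input", "n_per_class must be positive")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  image_seeds <- sample.int(2^30, sum(n_per_class))
  images <- vector("list", sum(n_per_class))
  labels <- character(sum(n_per_class))
  idx <- 0L
  for (ci in seq_len(k)) {
    for (j in seq_len(n_per_class[ci])) {
      idx <- idx + 1L
      images[[idx]] <- make_image(specs[[ci]], seed = image_seeds[idx],
                                  height = height, width = width)
      labels[idx] <- specs[[ci]]$name
    }
  }
  structure(list(images = images, labels = labels, regime = regime),
            class = "labeled_dataset")
}

#' Segment and extract features for a whole dataset
#'
#' Runs [segment()] and [extract_features()] on every image.
#'
#' @param ds a `labeled_dataset` (or list of `labeled_image`).
#' @param cfg segmentation configuration; the default band is
#'   [generator_band()], which separates every generator class from the
#'   background.
#' @return A list with `features` (matrix, one row per image) and `labels`.
#' @export
dataset_features <- function(ds, cfg = segmentation_config(band = generator_band())) {
  images <- if (inherits(ds, "labeled_dataset")) ds$images else ds
  labels <- if (inherits(ds, "labeled_dataset")) ds$labels
            else vapply(images, `[[`, character(1), "label")
  feats <- t(vapply(images, function(li) {
    m <- segment(li$image, cfg)
    extract_features(li$image, m)
  }, numeric(13)))
  colnames(feats) <- feature_names()
  list(features = feats, labels = labels)
}

#' Write a dataset to disk
#'
#' Writes `imgNNNN.png`, `imgNNNN_mask.png` and a `labels.csv` into `dir`.
#'
#' @param ds a `labeled_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("img%04d", seq_along(ds$images))
  for (i in seq_along(ds$images)) {
    write_image(ds$images[[i]]$image, file.path(dir, paste0(ids[i], ".png")))
    write_mask(ds$images[[i]]$truth_mask,
               file.path(dir, paste0(ids[i], "_mask.png")))
  }
  write.csv(data.frame(image_id = ids, label = ds$labels),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' End-to-end classification benchmark
#'
#' Generates a train and a held-out test set, runs the full pipeline
#' (segmentation, feature extraction) on every image, trains the
#' back-propagation classifier on the training features, and reports
#' held-out accuracy. Default sample sizes follow the reference protocol:
#' the `field_like` regime uses the per-class training counts
#' 70/69/72/70/75/76 and test counts 23/15/18/21/25/30; the `easy` regime
#' uses 70 training and 20 test images per class.
#'
#' @param regime `"easy"` or `"field_like"`.
#' @param seed master seed for generation and training.
#' @param n_train,n_test per-class counts (scalar or length 6); `NULL` for
#'   the defaults above.
#' @param cfg a [train_config()]; seeded from `seed` when NULL.
#' @return A list: `accuracy`, `per_class` (named accuracy vector),
#'   `confusion` (table), `model`.
#' @export
run_benchmark <- function(regime = c("easy", "field_like"), seed = 1L,
                          n_train = NULL, n_test = NULL, cfg = NULL) {
  regime <- match.arg(regime)
  if (is.null(n_train))
    n_train <- if (regime == "easy") 70L else c(70L, 69L, 72L, 70L, 75L, 76L)
  if (is.null(n_test))
    n_test <- if (regime == "easy") 20L else c(23L, 15L, 18L, 21L, 25L, 30L)
  if (is.null(cfg))
    cfg <- train_config(learning_rate = 0.2, max_epochs = 300,
                        target_mse = 1e-3, seed = seed)
  train_ds <- make_dataset(n_train, regime, seed = seed)
  test_ds <- make_dataset(n_test, regime, seed = seed + 1000000L)
  tr <- dataset_features(train_ds)
  te <- dataset_features(test_ds)
  model <- ann_train(tr$features, tr$labels, cfg)
  pred <- ann_predict(model, te$features)
  acc <- mean(pred == te$labels)
  confusion <- table(truth = te$labels, predicted = pred)
  per_class <- vapply(split(pred == te$labels, te$labels), mean, numeric(1))
  list(accuracy = acc, per_class = per_class, confusion = confusion,
       model = model)
}
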