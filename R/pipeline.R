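#' Pipeline configuration
#'
#' Bundles the per-stage options of the classify pipeline.
#'
#' @param segmentation a [segmentation_config()].
#' @param model_path path to a model JSON file (or NULL when a model object
#'   is passed directly to [run_pipeline()]).
#' @param channels color space for the color moments (`"hsv"` or `"rgb"`).
#' @param link a [link_config()].
#' @param frames_out optional path: when set, the image file bytes are
#'   packetized and the frame stream written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = segmentation_config(),
                            model_path = NULL, channels = "hsv",
                            link = link_config(), frames_out = NULL) {
  structure(list(segmentation = segmentation, model_path = model_path,
                 channels = channels, link = link, frames_out = frames_out),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `band` (two numbers or `"auto"`), `connectivity`,
#' `model`, `channels`, `frames_out`, `timeout`, `max_retries_before_reset`,
#' `max_attempts_per_frame`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    pp_error("pp_io_error", sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  seg <- segmentation_config(
    band = if (is.null(y$band)) "auto" else if (identical(y$band, "auto")) "auto"
           else as.numeric(y$band),
    connectivity = if (is.null(y$connectivity)) 8L else as.integer(y$connectivity)
  )
  link <- link_config(
    timeout = if (is.null(y$timeout)) 1.0 else y$timeout,
    max_retries_before_reset = if (is.null(y$max_retries_before_reset)) 5L
                               else y$max_retries_before_reset,
    max_attempts_per_frame = if (is.null(y$max_attempts_per_frame)) 50L
                             else y$max_attempts_per_frame
  )
  pipeline_config(segmentation = seg, model_path = y$model,
                  channels = if (is.null(y$channels)) "hsv" else y$channels,
                  link = link, frames_out = y$frames_out)
}

#' Run the full classification pipeline on one image
#'
#' Load, segment, extract the 13 features, classify, and packetize the
#' image payload: the acquire-preprocess-extract-classify-transmit flow of
#' the portable classifier, with the transmit stage producing a frame
#' stream on disk instead of driving a modem. Each stage failure carries
#' the stage name in a classed condition.
#'
#' @param image path to an image file, or a [raster_image()].
#' @param cfg a [pipeline_config()].
#' @param model a trained `ann_model`; read from `cfg$model_path` when NULL.
#' @return A list of class `pipeline_report`: `label`, `scores`, `features`,
#'   `region_size`, `band`, `n_frames` (0 when no frame output requested),
#'   `timings` (seconds per stage).
#' @export
run_pipeline <- function(image, cfg = pipeline_config(), model = NULL) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  img <- if (inherits(image, "raster_image")) image else read_image(image)
  timings["acquire"] <- tic() - t0

  if (is.null(model)) {
    if (is.null(cfg$model_path))
      pp_error("pp_model_error", "no model given and no model_path configured")
    model <- load_model(cfg$model_path)
  }

  t0 <- tic()
  mask <- segment(img, cfg$segmentation)
  timings["segment"] <- tic() - t0

  t0 <- tic()
  feats <- extract_features(img, mask, channels = cfg$channels)
  timings["features"] <- tic() - t0

  if (length(feats) != model$n_in)
    pp_error("pp_model_error",
             sprintf("model expects %d inputs, got %d features",
                     model$n_in, length(feats)))
  t0 <- tic()
  pred <- ann_predict(model, feats)
  timings["classify"] <- tic() - t0

  n_frames <- 0L
  if (!is.null(cfg$frames_out)) {
    t0 <- tic()
    payload <- if (is.character(image)) readBin(image, "raw", file.info(image)$size)
               else {
                 tmp <- tempfile(fileext = ".png")
                 on.exit(unlink(tmp), add = TRUE)
                 write_image(img, tmp)
                 readBin(tmp, "raw", file.info(tmp)$size)
               }
    frames <- packetize(payload)
    write_frames(frames, cfg$frames_out)
    n_frames <- length(frames)
    timings["packetize"] <- tic() - t0
  }

  structure(list(label = pred$label, scores = pred$scores, features = feats,
                 region_size = mask$region_size, band = mask$band,
                 n_frames = n_frames, timings = timings),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("label: %s\n", x$label))
  cat(sprintf("scores: %s\n",
              paste(sprintf("%s=%.3f", names(x$scores), x$scores),
                    collapse = " ")))
  cat(sprintf("region: %d px, hue band [%.3f, %.3f)\n",
              x$region_size, x$band[1], x$band[2]))
  cat("features:\n")
  print(round(x$features, 4))
  if (x$n_frames > 0) cat(sprintf("frames written: %d\n", x$n_frames))
  invisible(x)
}

#' Report as JSON
#' @param x a `pipeline_report`.
#' @return JSON string.
#' @export
report_json <- function(x) {
  jsonlite::toJSON(list(label = x$label, scores = as.list(x$scores),
                        features = as.list(x$features),
                        region_size = x$region_size, band = x$band,
                        n_frames = x$n_frames),
                   auto_unbox = TRUE, digits = 10)
}
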