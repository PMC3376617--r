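#' Hidden-layer width heuristic
#'
#' `n1 = round(sqrt(n + m)) + a`, the classic rule of thumb for a
#' three-layer network: `n` input nodes, `m` output nodes, and an
#' experiential integer `a` between 1 and 10. With the pipeline's 13 inputs,
#' 6 classes and `a = 6` it gives the 10 hidden nodes of the reference
#' 13-10-6 architecture.
#'
#' @param n number of input nodes.
#' @param m number of output nodes.
#' @param a experiential integer in `[1, 10]`.
#' @return Integer hidden-layer width.
#' @export
hidden_size <- function(n, m, a) {
  if (n < 1 || m < 1) pp_error("pp_invalid_input", "n and m must be >= 1")
  if (a < 1 || a > 10 || a != round(a))
    pp_error("pp_invalid_input", "a must be an integer in [1, 10]")
  as.integer(round(sqrt(n + m)) + a)
}

#' Fit min-max normalization bounds
#'
#' Per-feature minimum and maximum over the training matrix; used to map
#' every feature to `[0, 1]` so that differing feature scales do not
#' dominate training. Bounds are learned from training data only and reused
#' (with clipping) at test time.
#'
#' @param x numeric matrix, rows = samples, columns = features.
#' @return A list of class `normalization_params` with vectors `min` and `max`.
#' @export
fit_normalization <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) pp_error("pp_invalid_input", "NA/NaN in feature matrix")
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "normalization_params")
}

#' Apply min-max normalization
#'
#' `x' = (x - min) / (max - min)` per feature. Constant features
#' (`max == min`) map to 0; values outside the training range are clipped
#' to `[0, 1]`.
#'
#' @param x numeric vector (one sample) or matrix (rows = samples).
#' @param p `normalization_params` from [fit_normalization()].
#' @return Same shape as `x`, values in `[0, 1]`.
#' @export
normalize_features <- function(x, p) {
  vec <- is.null(dim(x))
  x <- rbind(x)
  if (ncol(x) != length(p$min))
    pp_error("pp_invalid_input", "feature length does not match normalization params")
  rng <- p$max - p$min
  rng[rng == 0] <- Inf  # constant feature -> 0
  out <- sweep(sweep(x, 2, p$min), 2, rng, `/`)
  out <- pmin(pmax(out, 0), 1)
  if (vec) out[1, ] else out
}

# Logistic transfer function.
logistic <- function(z) 1 / (1 + exp(-z))

#' Construct an untrained network
#'
#' Weights drawn uniformly from `[-0.5, 0.5]` with the current RNG state.
#'
#' @param n_in,n_hidden,n_out layer widths.
#' @param class_names ordered class labels (length `n_out`).
#' @return A list of class `ann_model` with `W1` (`n_hidden x n_in`), `b1`,
#'   `W2` (`n_out x n_hidden`), `b2`, `norm` (filled in by training) and
#'   `class_names`.
#' @export
ann_init <- function(n_in, n_hidden, n_out, class_names = NULL) {
  if (is.null(class_names)) class_names <- sprintf("class%d", seq_len(n_out))
  if (length(class_names) != n_out)
    pp_error("pp_invalid_input", "class_names length must equal n_out")
  structure(list(
    n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
    n_out = as.integer(n_out),
    W1 = matrix(runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
    b1 = runif(n_hidden, -0.5, 0.5),
    W2 = matrix(runif(n_out * n_hidden, -0.5, 0.5), n_out, n_hidden),
    b2 = runif(n_out, -0.5, 0.5),
    norm = NULL, class_names = as.character(class_names)
  ), class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model %d-%d-%d, classes: %s%s>\n", x$n_in, x$n_hidden,
              x$n_out, paste(x$class_names, collapse = ", "),
              if (is.null(x$norm)) " (untrained)" else ""))
  invisible(x)
}

#' Forward pass of the network
#'
#' `h = logistic(W1 x + b1)`, `y = logistic(W2 h + b2)`. The input is
#' assumed already normalized to `[0, 1]`.
#'
#' @param model an `ann_model`.
#' @param x numeric vector of length `n_in`.
#' @return Numeric score vector of length `n_out`, each score in `(0, 1)`.
#' @export
ann_forward <- function(model, x) {
  if (length(x) != model$n_in)
    pp_error("pp_invalid_input", "input length does not match n_in")
  h <- logistic(drop(model$W1 %*% x) + model$b1)
  logistic(drop(model$W2 %*% h) + model$b2)
}

# Gradients of the half squared error E = 0.5 * sum((y - t)^2) for one
# sample, by the delta rule. Returns the forward activations too so the
# training loop does one pass per sample.
ann_gradients <- function(model, x, t) {
  h <- logistic(drop(model$W1 %*% x) + model$b1)
  y <- logistic(drop(model$W2 %*% h) + model$b2)
  d2 <- (y - t) * y * (1 - y)
  d1 <- drop(crossprod(model$W2, d2)) * h * (1 - h)
  list(W1 = tcrossprod(d1, x), b1 = d1,
       W2 = tcrossprod(d2, h), b2 = d2, y = y, h = h)
}

#' Training configuration
#'
#' @param learning_rate gradient-descent step size (default 0.1).
#' @param max_epochs maximum number of passes over the training set.
#' @param target_mse stop once the epoch mean squared error (averaged over
#'   samples and output nodes) drops below this value.
#' @param seed integer seed driving weight initialization and the per-epoch
#'   sample shuffle; identical seed + data give identical final weights.
#' @param a_heuristic experiential integer for [hidden_size()] when
#'   `n_hidden` is not given explicitly.
#' @param n_hidden hidden-layer width; `NULL` (default) uses the heuristic.
#' @param soft_targets use 0.1/0.9 one-hot encoding instead of hard 0/1.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, max_epochs = 5000,
                         target_mse = 1e-3, seed = 1L, a_heuristic = 6L,
                         n_hidden = NULL, soft_targets = FALSE) {
  stopifnot(learning_rate > 0, max_epochs >= 1, target_mse >= 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 target_mse = target_mse, seed = as.integer(seed),
                 a_heuristic = as.integer(a_heuristic),
                 n_hidden = if (!is.null(n_hidden)) as.integer(n_hidden),
                 soft_targets = isTRUE(soft_targets)),
            class = "train_config")
}

#' Train the back-propagation classifier
#'
#' Fits min-max normalization bounds on the training matrix, builds a
#' three-layer network (hidden width from [hidden_size()] unless given),
#' and trains it by online (per-sample) gradient descent on the squared
#' error of one-hot targets — the general delta rule. Samples are visited in
#' a freshly shuffled order each epoch; all randomness is driven by
#' `cfg$seed`, so training is reproducible.
#'
#' @param x numeric matrix of raw (unnormalized) feature rows.
#' @param labels class label per row (factor or character).
#' @param cfg a [train_config()].
#' @return A trained `ann_model` with an attached `history` attribute: the
#'   per-epoch MSE trace.
#' @export
ann_train <- function(x, labels, cfg = train_config()) {
  x <- as.matrix(x)
  if (anyNA(x)) pp_error("pp_invalid_input", "NA/NaN in feature matrix")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    pp_error("pp_invalid_input", "training needs at least 2 classes")
  if (nrow(x) != length(labels))
    pp_error("pp_invalid_input", "one label per feature row required")
  norm <- fit_normalization(x)
  xn <- normalize_features(x, norm)
  n_in <- ncol(x); n_out <- length(classes)
  n_hidden <- if (!is.null(cfg$n_hidden)) cfg$n_hidden
              else hidden_size(n_in, n_out, cfg$a_heuristic)
  lo <- if (cfg$soft_targets) 0.1 else 0
  hi <- if (cfg$soft_targets) 0.9 else 1
  targets <- matrix(lo, nrow(x), n_out)
  targets[cbind(seq_len(nrow(x)), match(labels, classes))] <- hi
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  model <- ann_init(n_in, n_hidden, n_out, classes)
  lr <- cfg$learning_rate
  history <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(nrow(xn))
    sse <- 0
    for (i in ord) {
      g <- ann_gradients(model, xn[i, ], targets[i, ])
      model$W1 <- model$W1 - lr * g$W1
      model$b1 <- model$b1 - lr * g$b1
      model$W2 <- model$W2 - lr * g$W2
      model$b2 <- model$b2 - lr * g$b2
      sse <- sse + sum((g$y - targets[i, ])^2)
    }
    mse <- sse / (nrow(xn) * n_out)
    history <- c(history, mse)
    if (mse <= cfg$target_mse) break
  }
  model$norm <- norm
  attr(model, "history") <- history
  model
}

#' Classify a feature vector
#'
#' Normalizes with the bounds stored at training time, runs the forward
#' pass, and returns the argmax class (ties broken toward the lowest class
#' index).
#'
#' @param model a trained `ann_model`.
#' @param x raw feature vector (length `n_in`) or matrix of rows.
#' @return For a single vector, a list with `label` and `scores`; for a
#'   matrix, a character vector of labels with a `scores` matrix attribute.
#' @export
ann_predict <- function(model, x) {
  if (is.null(model$norm))
    pp_error("pp_model_error", "model has no normalization bounds (untrained?)")
  if (is.null(dim(x))) {
    xn <- normalize_features(x, model$norm)
    scores <- ann_forward(model, xn)
    k <- which.max(scores)  # first maximum: lowest index wins ties
    list(label = model$class_names[k],
         scores = setNames(scores, model$class_names))
  } else {
    xn <- normalize_features(as.matrix(x), model$norm)
    scores <- t(apply(xn, 1, function(r) ann_forward(model, r)))
    colnames(scores) <- model$class_names
    labels <- model$class_names[max.col(scores, ties.method = "first")]
    attr(labels, "scores") <- scores
    labels
  }
}

MODEL_MAGIC <- "pestpipe-ann"
MODEL_VERSION <- 1L

#' Save / load a trained model
#'
#' The model file is versioned JSON carrying a magic string, layer shapes,
#' all weights and thresholds as nested arrays, the normalization bounds and
#' the ordered class names; `load_model(save_model(m))` reproduces the model
#' bit-exactly (numbers are serialized at full precision).
#'
#' @param model a trained `ann_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` an `ann_model`.
#' @export
save_model <- function(model, path) {
  obj <- list(
    magic = MODEL_MAGIC, version = MODEL_VERSION,
    shape = c(model$n_in, model$n_hidden, model$n_out),
    class_names = model$class_names,
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    norm_min = model$norm$min, norm_max = model$norm$max
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    pp_error("pp_model_error", sprintf("model file not found: %s", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    pp_error("pp_model_error",
                             sprintf("cannot parse model file: %s",
                                     conditionMessage(e))))
  if (!identical(obj$magic, MODEL_MAGIC))
    pp_error("pp_model_error", "not a pestpipe model file (bad magic)")
  if (!identical(as.integer(obj$version), MODEL_VERSION))
    pp_error("pp_model_error", sprintf("unsupported model version %s", obj$version))
  shape <- as.integer(obj$shape)
  model <- structure(list(
    n_in = shape[1], n_hidden = shape[2], n_out = shape[3],
    W1 = matrix(as.numeric(t(obj$W1)), shape[2], shape[1], byrow = TRUE),
    b1 = as.numeric(obj$b1),
    W2 = matrix(as.numeric(t(obj$W2)), shape[3], shape[2], byrow = TRUE),
    b2 = as.numeric(obj$b2),
    norm = structure(list(min = unlist(obj$norm_min),
                          max = unlist(obj$norm_max)),
                     class = "normalization_params"),
    class_names = as.character(obj$class_names)
  ), class = "ann_model")
  if (!all(dim(model$W1) == c(model$n_hidden, model$n_in)) ||
      !all(dim(model$W2) == c(model$n_out, model$n_hidden)) ||
      length(model$class_names) != model$n_out)
    pp_error("pp_model_error", "inconsistent shapes in model file")
  model
}
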