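test_that("hidden-size heuristic rounds sqrt(n+m) then adds a", {
  expect_identical(hidden_size(13, 6, 6), 10L)
  expect_identical(hidden_size(3, 1, 1), 3L)
  expect_identical(vapply(1:10, function(a) hidden_size(13, 6, a), integer(1)),
                   4L + 1:10)
  expect_error(hidden_size(13, 6, 11), class = "pp_invalid_input")
  expect_error(hidden_size(13, 6, 0), class = "pp_invalid_input")
})

test_that("min-max normalization maps the training matrix onto [0, 1]", {
  x <- cbind(c(2, 4, 6), c(-1, 0, 3), c(5, 5, 5))
  p <- fit_normalization(x)
  xn <- normalize_features(x, p)
  expect_equal(xn[, 1], c(0, 0.5, 1))
  expect_equal(range(xn[, 2]), c(0, 1))
  expect_equal(xn[, 3], c(0, 0, 0))  # constant feature maps to 0
  # endpoints and midpoint
  expect_equal(unname(normalize_features(c(2, -1, 5), p)), c(0, 0, 0))
  expect_equal(unname(normalize_features(c(6, 3, 5), p)), c(1, 1, 0))
  expect_equal(normalize_features(c(4, 1, 5), p)[1], 0.5)
  # out-of-range test values are clipped, not extrapolated
  expect_equal(unname(normalize_features(c(100, -100, 9), p)), c(1, 0, 0))
  expect_error(normalize_features(c(1, 2), p), class = "pp_invalid_input")
})

test_that("forward pass computes the two-layer logistic composition", {
  m <- ann_init(1, 1, 1)
  m$W1[] <- 1; m$b1[] <- 0; m$W2[] <- 1; m$b2[] <- 0
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(ann_forward(m, 0), sig(sig(0)))
  z <- ann_init(3, 4, 2)
  z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2[] <- 0
  expect_equal(ann_forward(z, c(0.2, 0.9, 0.1)), c(0.5, 0.5))
  set.seed(5)
  r <- ann_init(13, 10, 6)
  y <- ann_forward(r, runif(13))
  expect_length(y, 6)
  expect_true(all(y > 0 & y < 1))
  expect_error(ann_forward(r, runif(5)), class = "pp_invalid_input")
})

test_that("backprop gradients match central finite differences", {
  set.seed(17)
  for (rep in 1:5) {
    m <- ann_init(3, 4, 2)
    x <- runif(3); t <- c(1, 0)
    g <- pestpipe:::ann_gradients(m, x, t)
    loss <- function(model) 0.5 * sum((ann_forward(model, x) - t)^2)
    eps <- 1e-6
    for (nm in c("W1", "b1", "W2", "b2")) {
      num <- m[[nm]]
      for (i in seq_along(num)) {
        mp <- m; mp[[nm]][i] <- mp[[nm]][i] + eps
        mm <- m; mm[[nm]][i] <- mm[[nm]][i] - eps
        num[i] <- (loss(mp) - loss(mm)) / (2 * eps)
      }
      expect_lt(max(abs(num - g[[nm]])), 1e-6)
    }
  }
})

test_that("training reduces the error and is bit-reproducible under a seed", {
  # three well-separated gaussian clusters in 2-d
  set.seed(2)
  n <- 30
  x <- rbind(cbind(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5)),
             cbind(rnorm(n, 3, 0.5), rnorm(n, 3, 0.5)),
             cbind(rnorm(n, 0, 0.5), rnorm(n, 3, 0.5)))
  lab <- rep(c("a", "b", "c"), each = n)
  cfg <- train_config(learning_rate = 0.5, max_epochs = 200, seed = 9,
                      n_hidden = 6)
  m1 <- ann_train(x, lab, cfg)
  h <- attr(m1, "history")
  expect_lt(tail(h, 1), head(h, 1) / 10)  # error falls by >= an order of magnitude
  m2 <- ann_train(x, lab, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_identical(m1$b1, m2$b1)
  expect_identical(m1$b2, m2$b2)
  # a different seed gives different weights
  m3 <- ann_train(x, lab, train_config(learning_rate = 0.5, max_epochs = 150,
                                       seed = 10, n_hidden = 6))
  expect_false(identical(m1$W1, m3$W1))
  # training resolves most of the labels it saw
  pred <- ann_predict(m1, x)
  expect_gte(mean(pred == lab), 0.9)
  expect_error(ann_train(x, rep("a", nrow(x))), class = "pp_invalid_input")
  expect_error(ann_train(x * NA, lab), class = "pp_invalid_input")
})

test_that("prediction takes the argmax with lowest-index tie-breaking", {
  m <- ann_init(2, 3, 3, class_names = c("u", "v", "w"))
  m$norm <- fit_normalization(rbind(c(0, 0), c(1, 1)))
  fake <- m
  # craft outputs via b2 with zero weights: y = logistic(b2)
  fake$W1[] <- 0; fake$b1[] <- 0; fake$W2[] <- 0
  fake$b2 <- c(-2, 2, -1)
  p <- ann_predict(fake, c(0.5, 0.5))
  expect_equal(p$label, "v")
  expect_named(p$scores, c("u", "v", "w"))
  fake$b2 <- c(1, 1, 1)  # exact tie -> first class
  expect_equal(ann_predict(fake, c(0.5, 0.5))$label, "u")
  expect_error(ann_predict(ann_init(2, 3, 3), c(0.5, 0.5)),
               class = "pp_model_error")
})

test_that("model files round-trip bit-exactly and reject corruption", {
  set.seed(4)
  x <- matrix(runif(40 * 13), 40, 13)
  lab <- rep(c("p", "q"), 20)
  m <- ann_train(x, lab, train_config(max_epochs = 20, seed = 3))
  p <- withr::local_tempfile(fileext = ".json")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(m2$W1, m$W1)
  expect_identical(m2$W2, m$W2)
  expect_identical(m2$b1, m$b1)
  expect_identical(m2$b2, m$b2)
  expect_identical(m2$norm$min, m$norm$min)
  expect_identical(m2$class_names, m$class_names)
  for (i in 1:100) {
    xi <- runif(13)
    expect_identical(ann_predict(m, xi), ann_predict(m2, xi))
  }
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"magic": "something-else", "version": 1}', bad)
  expect_error(load_model(bad), class = "pp_model_error")
  expect_error(load_model(withr::local_tempfile()), class = "pp_model_error")
})
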