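test_that("color moments match hand-evaluated mean, sd and skew", {
  mask3 <- matrix(1L, 1, 3)
  expect_equal(color_moments(matrix(c(0.7, 0.7, 0.7), 1), mask3),
               c(E = 0.7, sigma = 0, s = 0))
  expect_equal(color_moments(matrix(c(0, 1), 1), matrix(1L, 1, 2)),
               c(E = 0.5, sigma = 0.5, s = 0))
  # {0, 0, 1}: E = 1/3, sigma = sqrt(2)/3, s = cbrt(mean of cubed deviations)
  s_expected <- (((-1 / 3)^3 * 2 + (2 / 3)^3) / 3)^(1 / 3)
  expect_equal(color_moments(matrix(c(0, 0, 1), 1), mask3),
               c(E = 1 / 3, sigma = sqrt(2) / 3, s = s_expected))
  # negative skew uses the real signed cube root
  neg <- color_moments(matrix(c(0, 1, 1), 1), mask3)
  expect_lt(neg[["s"]], 0)
  # moments ignore pixel positions inside the mask
  set.seed(1)
  ch <- matrix(runif(64), 8, 8)
  msk <- matrix(rbinom(64, 1, 0.5), 8, 8)
  perm <- sample(64)
  expect_equal(color_moments(ch, msk),
               color_moments(matrix(ch[perm], 8, 8),
                             matrix(msk[perm], 8, 8)))
  expect_error(color_moments(ch, msk * 0L), class = "pp_invalid_input")
})

test_that("shape moments match hand-enumerated and analytic values", {
  one <- matrix(0L, 5, 5); one[3, 4] <- 1L
  ms1 <- shape_moments(one)
  expect_equal(ms1$mu[1, 1], 1)
  expect_equal(ms1$mu[2, 1], 0)
  expect_equal(ms1$mu[3, 1], 0)
  blk <- matrix(0L, 4, 4); blk[2:3, 2:3] <- 1L
  ms2 <- shape_moments(blk)
  expect_equal(ms2$m[1, 1], 4)
  expect_equal(ms2$mu[3, 1], 1)  # mu20 = 4 * 0.5^2
  expect_equal(ms2$mu[1, 3], 1)
  expect_equal(ms2$eta[3, 1], 1 / 16)
  expect_equal(ms2$eta[1, 3], 1 / 16)
  # rasterized disc: eta20 -> 1/(4*pi) in the continuum limit
  ms3 <- shape_moments(raster_disc(50L))
  expect_equal(ms3$eta[3, 1], 1 / (4 * pi), tolerance = 0.01)
})

test_that("shape moments agree exactly with the per-pixel loop oracle", {
  set.seed(7)
  for (i in 1:60) {
    m <- matrix(rbinom(256, 1, 0.4), 16, 16)
    if (sum(m) == 0) next
    got <- shape_moments(m)
    want <- moments_oracle(m)
    keep <- !is.na(got$eta)
    expect_identical(got$m[keep], want$m[keep])  # integer sums: exact
    # central moments cancel large summands; compare at the summand scale
    expect_lt(max(abs(got$mu[keep] - want$mu[keep])),
              1e-10 * want$m[1, 1] * 15^3)
    expect_lt(max(abs(got$eta[keep] - want$eta[keep])), 1e-11)
  }
})

test_that("Hu invariants behave as invariants", {
  disc <- raster_disc(50L)
  hu <- hu_features(disc)
  expect_equal(hu[["phi1"]], 1 / (2 * pi), tolerance = 0.01)
  expect_equal(hu[["phi2"]], 0, tolerance = 1e-3)
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(rbinom(14 * 10, 1, 0.4), 14, 10)
    if (sum(m) < 2) next
    hu0 <- hu_features(m)
    # translation: embed with offset
    big <- matrix(0L, 30, 30); big[9:22, 13:22] <- m
    expect_equal(hu_features(big), hu0)
    # 90 and 180 degree rotations are exact lattice symmetries
    expect_equal(hu_features(t(m[nrow(m):1, ])), hu0)
    expect_equal(hu_features(m[nrow(m):1, ncol(m):1]), hu0)
    # 2x nearest-neighbour upscale: scale invariance within raster error
    up <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
    expect_equal(hu_features(up), hu0, tolerance = 0.02)
    # phi2 <= phi1^2 always
    expect_lte(hu0[["phi2"]], hu0[["phi1"]]^2 + 1e-12)
  }
})

test_that("eccentricity matches the momental-ellipse oracle", {
  expect_equal(eccentricity(raster_disc(50L)), 1.0, tolerance = 0.02)
  ell <- raster_ellipse(40, 20)
  expect_equal(eccentricity(ell), 2.0, tolerance = 0.03)
  expect_equal(eccentricity(ell), eccentricity_oracle(ell), tolerance = 1e-10)
  rot <- raster_ellipse(40, 20, theta = pi / 6)
  expect_equal(eccentricity(rot), eccentricity(ell), tolerance = 0.03)
  # degenerate collinear region hits the cap
  line <- matrix(0L, 5, 9); line[3, 2:8] <- 1L
  expect_identical(eccentricity(line), Inf)
  expect_equal(eccentricity(line, max_cap = 100), 100)
})

test_that("sphericity matches analytic inscribed/circumscribed radii", {
  expect_equal(sphericity(raster_disc(50L)), 1.0, tolerance = 0.03)
  sq <- matrix(0L, 100, 100); sq[11:90, 11:90] <- 1L
  expect_equal(sphericity(sq), 1 / sqrt(2), tolerance = 0.03)
  rect <- matrix(0L, 60, 80); rect[21:40, 21:60] <- 1L
  expect_equal(sphericity(rect), 10 / sqrt(500), tolerance = 0.03)
  # brute-force check of both radii on a small random blob
  set.seed(3)
  blob <- keep_largest_region(matrix(rbinom(144, 1, 0.62), 12, 12))
  idx <- which(blob > 0, arr.ind = TRUE)
  bg <- which(blob == 0, arr.ind = TRUE)
  bg <- rbind(bg, cbind(rep(c(0, 13), each = 14), rep(0:13, 2)),
              cbind(rep(0:13, 2), rep(c(0, 13), each = 14)))
  ri_bf <- max(apply(idx, 1, function(p)
    min(sqrt((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2))))
  corners <- rbind(cbind(idx[, 2] - 0.5, idx[, 1] - 0.5),
                   cbind(idx[, 2] - 0.5, idx[, 1] + 0.5),
                   cbind(idx[, 2] + 0.5, idx[, 1] - 0.5),
                   cbind(idx[, 2] + 0.5, idx[, 1] + 0.5))
  hull <- corners[unique(grDevices::chull(corners)), , drop = FALSE]
  nh <- nrow(hull)
  covers <- function(cx, cy, r)
    max((corners[, 1] - cx)^2 + (corners[, 2] - cy)^2) <= r^2 + 1e-7
  best <- Inf
  for (i in seq_len(nh - 1)) for (j in seq(i + 1, nh)) {
    cx <- (hull[i, 1] + hull[j, 1]) / 2; cy <- (hull[i, 2] + hull[j, 2]) / 2
    r <- sqrt((hull[i, 1] - cx)^2 + (hull[i, 2] - cy)^2)
    if (r < best && covers(cx, cy, r)) best <- r
  }
  for (i in seq_len(nh - 2)) for (j in seq(i + 1, nh - 1)) for (k in seq(j + 1, nh)) {
    a <- hull[i, ]; b <- hull[j, ]; ccc <- hull[k, ]
    d <- 2 * (a[1] * (b[2] - ccc[2]) + b[1] * (ccc[2] - a[2]) + ccc[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    ux <- (sum(a^2) * (b[2] - ccc[2]) + sum(b^2) * (ccc[2] - a[2]) + sum(ccc^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (ccc[1] - b[1]) + sum(b^2) * (a[1] - ccc[1]) + sum(ccc^2) * (b[1] - a[1])) / d
    r <- sqrt(sum((a - c(ux, uy))^2))
    if (r < best && covers(ux, uy, r)) best <- r
  }
  expect_equal(sphericity(blob), min(1, ri_bf / best), tolerance = 1e-7)
  expect_error(sphericity(matrix(0L, 3, 3)), class = "pp_invalid_input")
})

test_that("the assembled feature vector has the documented layout", {
  li <- make_image(class_specs("easy")[[4]], seed = 21)
  m <- segment(li$image, segmentation_config(band = generator_band()))
  f <- extract_features(li$image, m)
  expect_length(f, 13)
  expect_named(f, feature_names())
  expect_gte(f[["EC"]], 1)
  expect_gt(f[["SP"]], 0)
  expect_lte(f[["SP"]], 1)
  expect_gte(f[["phi1"]], 0)
  expect_true(all(f[c("sigma_H", "sigma_S", "sigma_V")] >= 0))
  # constant-color disc: zero spread/skew in every channel, EC = SP = 1
  disc <- raster_disc(30L)
  img <- array(0L, c(dim(disc), 3L))
  img[, , 1][disc == 1] <- 60L; img[, , 2][disc == 1] <- 200L
  img[, , 1][disc == 0] <- 220L; img[, , 3][disc == 0] <- 230L
  fd <- extract_features(raster_image(img), disc)
  expect_equal(unname(fd[c("sigma_H", "s_H", "sigma_S", "s_S", "sigma_V", "s_V")]),
               rep(0, 6))
  expect_equal(fd[["EC"]], 1, tolerance = 0.02)
  expect_equal(fd[["SP"]], 1, tolerance = 0.03)
})

test_that("feature CSV round-trips with the fixed header", {
  li <- make_image(class_specs("easy")[[1]], seed = 8)
  m <- segment(li$image, segmentation_config(band = generator_band()))
  f <- extract_features(li$image, m)
  p <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(list(f, f + 0.01), p, ids = c("a", "b"),
                     labels = c("x", "y"))
  back <- read_features_csv(p)
  expect_equal(names(back), c("image_id", feature_names(), "label"))
  expect_equal(unlist(back[1, feature_names()]), f, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$label, c("x", "y"))
  expect_error(read_features_csv(withr::local_tempfile()), class = "pp_io_error")
})
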