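# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals.

# neighbour indices (1-based, column-major cell index) for an nr x nc grid
grid_neighbors <- function(nr, nc, connectivity) {
  off <- if (connectivity == 8) {
    g <- expand.grid(dr = -1:1, dc = -1:1)
    g[!(g$dr == 0 & g$dc == 0), ]
  } else data.frame(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  lapply(seq_len(nr * nc), function(i) {
    r <- (i - 1) %% nr
    c <- (i - 1) %/% nr
    rr <- r + off$dr
    cc <- c + off$dc
    ok <- rr >= 0 & rr < nr & cc >= 0 & cc < nc
    cc[ok] * nr + rr[ok] + 1
  })
}

# flood-fill labeling oracle; labels assigned in row-major discovery order
flood_label <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  nb <- grid_neighbors(nr, nc, connectivity)
  cells <- as.logical(mask)
  lab <- integer(nr * nc)
  nxt <- 0L
  for (r in 0:(nr - 1)) for (c in 0:(nc - 1)) {
    i <- c * nr + r + 1
    if (cells[i] && lab[i] == 0L) {
      nxt <- nxt + 1L
      lab[i] <- nxt
      q <- i
      while (length(q)) {
        cur <- q[1]; q <- q[-1]
        for (n in nb[[cur]]) if (cells[n] && lab[n] == 0L) {
          lab[n] <- nxt
          q <- c(q, n)
        }
      }
    }
  }
  matrix(lab, nr, nc)
}

# naive per-pixel loop oracle for raw/central/normalized shape moments
moments_oracle <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  m <- matrix(0, 4, 4)
  for (p in 0:3) for (q in 0:3) if (p + q <= 3) {
    acc <- 0
    for (k in seq_along(x)) acc <- acc + x[k]^p * y[k]^q
    m[p + 1, q + 1] <- acc
  }
  xb <- m[2, 1] / m[1, 1]; yb <- m[1, 2] / m[1, 1]
  mu <- matrix(0, 4, 4); eta <- matrix(NA_real_, 4, 4)
  for (p in 0:3) for (q in 0:3) if (p + q <= 3) {
    acc <- 0
    for (k in seq_along(x)) acc <- acc + (x[k] - xb)^p * (y[k] - yb)^q
    mu[p + 1, q + 1] <- acc
    if (p + q >= 2) eta[p + 1, q + 1] <- acc / m[1, 1]^((p + q) / 2 + 1)
  }
  list(m = m, mu = mu, eta = eta)
}

# brute-force covariance eigen oracle for eccentricity
eccentricity_oracle <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  xy <- cbind(idx[, 2], idx[, 1]) - 1
  n <- nrow(xy)
  cv <- cov(xy) * (n - 1) / n  # population covariance
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  sqrt(ev[1] / ev[2])
}

jaccard <- function(a, b) sum(a > 0 & b > 0) / sum(a > 0 | b > 0)

# filled shapes on a 0-based pixel-center lattice
raster_disc <- function(R, pad = 6L) {
  n <- 2L * (R + pad) + 1L
  ctr <- R + pad
  g <- expand.grid(r = 0:(n - 1), c = 0:(n - 1))
  matrix(as.integer((g$r - ctr)^2 + (g$c - ctr)^2 <= R^2), n, n)
}

raster_ellipse <- function(a, b, theta = 0, pad = 6L) {
  n <- 2L * (max(a, b) + pad) + 1L
  ctr <- max(a, b) + pad
  g <- expand.grid(r = 0:(n - 1), c = 0:(n - 1))
  xr <- (g$c - ctr) * cos(theta) + (g$r - ctr) * sin(theta)
  yr <- -(g$c - ctr) * sin(theta) + (g$r - ctr) * cos(theta)
  matrix(as.integer((xr / a)^2 + (yr / b)^2 <= 1), n, n)
}
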