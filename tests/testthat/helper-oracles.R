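# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# modified Bessel function of the first kind by its power series,
# truncated when terms fall below 1e-16 relative
bessel_series <- function(x, nu) {
  total <- 0
  for (m in 0:200) {
    term <- (x / 2)^(2 * m + nu) / (gamma(m + 1) * gamma(m + nu + 1))
    total <- total + term
    if (m > 2 && term < 1e-16 * total) break
  }
  total
}
bessel_ratio_series <- function(kappa) {
  bessel_series(kappa, 1) / bessel_series(kappa, 0)
}

# explicit finite-difference diffusion of the half-width step with
# no-flux walls, on an n-point grid
fd_profile <- function(width, D, tau, n = 64, safety = 0.25) {
  dy <- width / (n - 1)
  y <- seq(0, width, length.out = n)
  c0 <- as.numeric(y < width / 2)
  c0[y == width / 2] <- 0.5
  dt <- safety * dy^2 / D
  steps <- ceiling(tau / dt)
  dt <- tau / steps
  lam <- D * dt / dy^2
  u <- c0
  for (s in seq_len(steps)) {
    lap <- c(2 * (u[2] - u[1]),
             u[c(3:n)] - 2 * u[2:(n - 1)] + u[1:(n - 2)],
             2 * (u[n - 1] - u[n]))
    u <- u + lam * lap
  }
  list(y = y, c = u)
}

# chemotactic index by explicit segment loop
ci_brute <- function(x, y, axis) {
  axis <- axis / sqrt(sum(axis^2))
  path <- 0
  for (i in 2:length(x)) {
    path <- path + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  }
  if (path == 0) return(NA_real_)
  ((x[length(x)] - x[1]) * axis[1] + (y[length(y)] - y[1]) * axis[2]) / path
}

# second-order central moments of a mask by double loop
moments_brute <- function(mask) {
  sx <- 0; sy <- 0; n <- 0
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c]) { n <- n + 1; sx <- sx + (c - 1); sy <- sy + (r - 1) }
  }
  cx <- sx / n; cy <- sy / n
  m20 <- 0; m02 <- 0; m11 <- 0
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c]) {
      m20 <- m20 + ((c - 1) - cx)^2
      m02 <- m02 + ((r - 1) - cy)^2
      m11 <- m11 + ((c - 1) - cx) * ((r - 1) - cy)
    }
  }
  list(n = n, mu20 = m20 / n, mu02 = m02 / n, mu11 = m11 / n)
}
moments_brute_ar <- function(mask) {
  m <- moments_brute(mask)
  common <- sqrt(((m$mu20 - m$mu02) / 2)^2 + m$mu11^2)
  l1 <- (m$mu20 + m$mu02) / 2 + common
  l2 <- (m$mu20 + m$mu02) / 2 - common
  sqrt(l1 / l2)
}

# two-sided permutation p-value for a difference in means
perm_ttest_p <- function(a, b, n_perm = 10000, seed = 42) {
  withr::with_seed(seed, {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    na <- length(a)
    hits <- 0
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      d <- abs(mean(pool[idx]) - mean(pool[-idx]))
      if (d >= obs - 1e-12) hits <- hits + 1
    }
    hits / n_perm
  })
}

# solid rasterized ellipse mask (axis-aligned then rotated by angle)
raster_ellipse <- function(a_px, b_px, angle = 0, pad = 4) {
  r <- ceiling(max(a_px, b_px)) + pad
  grid <- seq(-r, r)
  X <- matrix(grid, length(grid), length(grid), byrow = TRUE)
  Y <- matrix(grid, length(grid), length(grid))
  u <- X * cos(angle) + Y * sin(angle)
  v <- -X * sin(angle) + Y * cos(angle)
  (u / a_px)^2 + (v / b_px)^2 <= 1
}
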