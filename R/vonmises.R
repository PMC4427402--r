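#' Draw from the von Mises distribution
#'
#' Best–Fisher rejection sampler. `kappa = 0` reduces to the uniform
#' circular distribution; `kappa = Inf` returns `mu` exactly.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration, >= 0.
#' @return Angles in `(-pi, pi]` (shifted by `mu`).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) abort("`kappa` must be >= 0.")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa < 1e-10) {
    return(((stats::runif(n, -pi, pi) + mu + pi) %% (2 * pi)) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.6) + 8L
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, theta)
  }
  ((out[seq_len(n)] + mu + pi) %% (2 * pi)) - pi
}

#' Asymptotic chemotactic index of the biased walk
#'
#' For i.i.d. von Mises step directions with concentration `kappa` and step
#' lengths independent of direction, the chemotactic index of a long track
#' converges to the mean resultant length `A(kappa) = I1(kappa) / I0(kappa)`
#' (a ratio of modified Bessel functions).
#'
#' @param kappa Concentration, >= 0 (vectorized).
#' @return Values in `[0, 1)`; 0 at `kappa = 0`, approaching 1 as
#'   `kappa -> Inf`.
#' @export
#' @examples
#' expected_ci(c(0, 1, 2, 10))
expected_ci <- function(kappa) {
  if (any(kappa < 0)) abort("`kappa` must be >= 0.")
  out <- ifelse(is.infinite(kappa), 1,
                besselI(kappa, 1, expon.scaled = TRUE) /
                  besselI(kappa, 0, expon.scaled = TRUE))
  # the scaled ratio underflows to NaN only at kappa = 0/0 edge; guard
  out[kappa == 0] <- 0
  out
}

#' Calibrate the directional concentration to a target chemotactic index
#'
#' Inverts [expected_ci()] by bisection so that a simulated population of
#' long unbiased-speed tracks has asymptotic mean chemotactic index equal to
#' `target_ci`.
#'
#' @param target_ci Target chemotactic index in `[0, 1)`.
#' @param tol Inversion tolerance on the chemotactic index. Default 1e-8.
#' @return The concentration `kappa` with `expected_ci(kappa) == target_ci`
#'   to within `tol`.
#' @export
#' @examples
#' kappa <- calibrate_kappa(0.5)
#' expected_ci(kappa)
calibrate_kappa <- function(target_ci, tol = 1e-8) {
  if (!is.numeric(target_ci) || length(target_ci) != 1 ||
      target_ci < 0 || target_ci >= 1) {
    abort("`target_ci` must be in [0, 1).")
  }
  if (target_ci == 0) return(0)
  # A(kappa) ~ 1 - 1/(2 kappa) for large kappa: safe upper bracket
  upper <- max(10, 1 / (1 - target_ci))
  while (expected_ci(upper) < target_ci) upper <- upper * 2
  stats::uniroot(function(k) expected_ci(k) - target_ci,
                 lower = 0, upper = upper, tol = tol)$root
}
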