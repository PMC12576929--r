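#' von Mises density
#'
#' Density of the von Mises distribution on (-pi, pi]. The log of the
#' modified Bessel function I0 is evaluated with the exponentially
#' scaled base [besselI()] so large concentrations stay finite.
#'
#' @param x Angle(s) in radians.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0; 0 gives the circular uniform).
#' @param log Return log density?
#' @export
dvonmises <- function(x, mu, kappa, log = FALSE) {
  stopifnot(kappa >= 0)
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  ld <- kappa * cos(x - mu) - log(2 * pi) - log_i0
  if (log) ld else exp(ld)
}

#' von Mises random deviates
#'
#' Best & Fisher (1979) rejection sampler, driven by R's RNG stream so
#' results are reproducible under [set.seed()]. kappa = 0 falls back to
#' the circular uniform.
#'
#' @param n Number of deviates.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.5 * (n - length(out))))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, (sign(u3 - 0.5) * acos(f))[ok])
  }
  wrap_angle(out[seq_len(n)] + mu)
}

#' Wrap angles into (-pi, pi]
#'
#' @param x Angle(s) in radians.
#' @export
wrap_angle <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  # the modulus puts exactly-pi at pi, which already lies in (-pi, pi]
  w
}
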