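#' Wrapped Cauchy density
#'
#' Density of the wrapped Cauchy distribution on the circle,
#' \deqn{f(\phi) = \frac{1}{2\pi}\,\frac{1 - \rho^2}{1 + \rho^2 - 2\rho\cos(\phi - \mu)},}
#' with mean direction \code{mu} and concentration \code{rho} in \[0, 1).
#' At \code{rho = 0} the distribution is uniform on the circle with constant
#' density \eqn{1/2\pi}; as \code{rho} approaches 1 it converges to a point
#' mass at \code{mu}.
#'
#' @param phi angles in radians (any real value; the density is periodic).
#' @param mu mean direction in radians.
#' @param rho concentration in \[0, 1).
#' @param log if TRUE, return the log density.
#' @return numeric vector of (log) densities.
#' @examples
#' dwrpcauchy(0, mu = 0, rho = 0.5)   # 3 / (2 * pi)
#' dwrpcauchy(1, rho = 0)             # uniform: 1 / (2 * pi)
#' @export
dwrpcauchy <- function(phi, mu = 0, rho = 0, log = FALSE) {
  if (any(!is.finite(mu)) || any(!is.finite(rho)))
    stop("mu and rho must be finite")
  if (any(rho < 0 | rho >= 1))
    stop("rho must lie in [0, 1)")
  d <- (1 - rho^2) / ((2 * pi) * (1 + rho^2 - 2 * rho * cos(phi - mu)))
  if (log) base::log(d) else d
}

#' Sample from a wrapped Cauchy distribution
#'
#' Draws are generated exactly by wrapping a linear Cauchy variate with
#' scale \eqn{-\log\rho} (the wrapped Cauchy with concentration \eqn{\rho}
#' is the wrapping of Cauchy(\eqn{\mu}, \eqn{-\log\rho})).
#'
#' @param n number of draws.
#' @inheritParams dwrpcauchy
#' @return angles in (-pi, pi].
#' @export
rwrpcauchy <- function(n, mu = 0, rho = 0) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (rho == 0) return(runif(n, -pi, pi))
  wrap_angle(mu + stats::rcauchy(n, location = 0, scale = -base::log(rho)))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. The von Mises distribution is used only by
#' the trajectory generator (turning angles of the simulated regimes); the
#' inference model uses the wrapped Cauchy.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration, >= 0; kappa = 0 gives the circular uniform.
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (!is.finite(mu) || !is.finite(kappa) || kappa < 0)
    stop("mu must be finite and kappa a finite non-negative number")
  if (kappa < 1e-10) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- wrap_angle(sign(u[3] - 0.5) * acos(f) + mu)
    }
  }
  out
}

#' Mean of a Weibull distribution
#'
#' \eqn{b\,\Gamma(1 + 1/a)} for shape \code{a} and scale \code{b}; the
#' quantity reported as the mean movement rate of a behavioural state.
#'
#' @param shape Weibull shape parameter a > 0.
#' @param scale Weibull scale parameter b > 0 (rate units).
#' @return the distribution mean, in the units of \code{scale}.
#' @examples
#' weibull_mean(1, 2)  # exponential with mean 2
#' @export
weibull_mean <- function(shape, scale) {
  if (any(shape <= 0) || any(scale <= 0)) stop("shape and scale must be > 0")
  scale * gamma(1 + 1 / shape)
}

#' Mean (resultant) vector of a wrapped Cauchy distribution
#'
#' Returns \eqn{(\rho\cos\mu, \rho\sin\mu)}; its norm equals the
#' concentration \eqn{\rho}, so the arrow length measures how peaked the
#' turning-angle distribution is (1 would be a point distribution, 0 the
#' circular uniform).
#'
#' @inheritParams dwrpcauchy
#' @return numeric length-2 vector (x, y).
#' @examples
#' mean_vector(pi, 0.8)  # (-0.8, 0)
#' @export
mean_vector <- function(mu, rho) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  c(rho * cos(mu), rho * sin(mu))
}

# log Weibull density computed directly in log space: finite (or -Inf/+Inf
# at the x = 0 boundary) for every finite positive shape/scale, where
# stats::dweibull(log = TRUE) returns NaN once (x/b)^a overflows
ldweibull <- function(x, shape, scale) {
  lr <- log(x) - log(scale)
  out <- log(shape) - log(scale) + (shape - 1) * lr - exp(shape * lr)
  if (any(x == 0))
    out[x == 0] <- if (shape < 1) Inf else if (shape == 1) -log(scale) else -Inf
  out
}

# Method-of-moments Weibull fit: solve the coefficient of variation for the
# shape, then the scale from the mean. Used only to initialise MCMC chains.
fit_weibull_moments <- function(x) {
  x <- x[is.finite(x) & x > 0]
  m <- mean(x)
  s <- stats::sd(x)
  if (length(x) < 2 || !is.finite(s) || s <= 0)
    return(list(shape = 1, scale = max(m, 1e-8)))
  cv <- s / m
  f <- function(a) sqrt(gamma(1 + 2 / a) / gamma(1 + 1 / a)^2 - 1) - cv
  a <- tryCatch(
    stats::uniroot(f, lower = 0.1, upper = 50, tol = 1e-8)$root,
    error = function(e) 1
  )
  list(shape = a, scale = m / gamma(1 + 1 / a))
}
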