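#' Per-state random-walk parameters
#'
#' One behavioural state of the mixture: a Weibull distribution (shape,
#' scale) for movement rates and a wrapped Cauchy (mean direction mu,
#' concentration rho) for turning angles.
#'
#' @param shape,scale Weibull parameters, both > 0.
#' @param mu wrapped Cauchy mean direction, radians.
#' @param rho wrapped Cauchy concentration in \[0, rho_max\].
#' @param rho_max upper bound on rho (default 0.99); the bound keeps the
#'   angle density proper and matches the uniform prior support used in
#'   fitting.
#' @return an object of class \code{state_params}.
#' @export
state_params <- function(shape, scale, mu = 0, rho = 0, rho_max = 0.99) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be > 0")
  if (rho < 0 || rho > rho_max) stop("rho must lie in [0, rho_max]")
  structure(list(shape = shape, scale = scale, mu = wrap_angle(mu),
                 rho = rho, rho_max = rho_max),
            class = "state_params")
}

#' N-state mixture random-walk model
#'
#' @param states list of [state_params()] (1 to 3 states).
#' @param weights mixing weights; a simplex of the same length as
#'   \code{states} (default uniform).
#' @return an object of class \code{mixture_model}.
#' @export
mixture_model <- function(states, weights = NULL) {
  if (!length(states) %in% 1:3) stop("the model supports 1 to 3 states")
  if (!all(vapply(states, inherits, TRUE, "state_params")))
    stop("states must be a list of state_params objects")
  n <- length(states)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("weights must be a length-N simplex")
  structure(list(n_states = n, states = states, weights = weights),
            class = "mixture_model")
}

# T x N matrix of per-state log densities log f_j(r_t, phi_t).
# phi may contain NA (rate-only observations contribute the Weibull term).
state_logdens <- function(r, phi, shape, scale, mu, rho) {
  n_states <- length(shape)
  out <- matrix(0, length(r), n_states)
  has_phi <- !is.na(phi)
  for (j in seq_len(n_states)) {
    out[, j] <- ldweibull(r, shape[j], scale[j])
    if (any(has_phi))
      out[has_phi, j] <- out[has_phi, j] +
        dwrpcauchy(phi[has_phi], mu[j], rho[j], log = TRUE)
  }
  out
}

#' Complete-data log likelihood of the mixture model
#'
#' Sums, over every step with a valid movement rate, the log Weibull density
#' of the rate under the step's assigned state, plus the log wrapped Cauchy
#' density of the turning angle where the angle is valid. Steps with a valid
#' rate but no valid angle contribute the rate term only (the likelihood
#' factorises over independent per-step terms).
#'
#' @param steps a \code{step_series} from [to_step_series()].
#' @param z integer state labels, one per valid-rate step, each in 1..N.
#' @param model a [mixture_model()]. Weights are not part of this
#'   complete-data term; they enter the label full conditionals.
#' @return the log likelihood (scalar).
#' @export
mixture_loglik <- function(steps, z, model) {
  stopifnot(inherits(model, "mixture_model"))
  dat <- step_data(steps)
  if (length(z) != dat$n)
    stop("z must have one label per valid-rate step (", dat$n, ")")
  z <- as.integer(z)
  if (any(z < 1 | z > model$n_states)) stop("state label out of range 1..N")
  shape <- vapply(model$states, `[[`, 0, "shape")
  scale <- vapply(model$states, `[[`, 0, "scale")
  mu <- vapply(model$states, `[[`, 0, "mu")
  rho <- vapply(model$states, `[[`, 0, "rho")
  ld <- state_logdens(dat$r, dat$phi, shape, scale, mu, rho)
  sum(ld[cbind(seq_len(dat$n), z)])
}
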