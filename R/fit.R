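#' Prior specification
#'
#' Vague priors for the mixture parameters: the Weibull shape and scale of
#' every state get Gamma priors with mean 30 and variance 3000 (shape 0.3,
#' rate 0.01), the wrapped Cauchy mean direction a uniform prior on
#' (-pi, pi], the concentration a uniform prior on (0, rho_max), and the
#' mixing weights a symmetric Dirichlet(1).
#'
#' @param gamma_shape,gamma_rate Gamma hyper-parameters for the Weibull
#'   shape and scale (defaults 0.3 and 0.01: mean shape/rate = 30,
#'   variance shape/rate^2 = 3000).
#' @param rho_max upper bound of the uniform prior on the wrapped Cauchy
#'   concentration (default 0.99, keeping the density proper).
#' @return an object of class \code{prior_spec}.
#' @export
prior_spec <- function(gamma_shape = 0.3, gamma_rate = 0.01, rho_max = 0.99) {
  if (gamma_shape <= 0 || gamma_rate <= 0)
    stop("gamma_shape and gamma_rate must be > 0")
  if (rho_max <= 0 || rho_max >= 1) stop("rho_max must lie in (0, 1)")
  structure(list(gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 rho_max = rho_max),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param n_iter sampling iterations after burn-in (default 100000).
#' @param burn_in burn-in iterations (default 2000).
#' @param thin keep every \code{thin}-th sweep (default 10), giving
#'   \code{floor(n_iter / thin)} kept samples.
#' @param proposal_sd named numeric vector of initial random-walk proposal
#'   SDs for the blocks \code{log_shape}, \code{log_scale}, \code{mu},
#'   \code{rho}.
#' @param adapt_during_burnin adapt the proposal SDs towards an acceptance
#'   rate of ~0.3 during burn-in (Robbins-Monro on the log SD); adaptation
#'   is frozen afterwards so the sampling phase keeps detailed balance.
#' @param seed integer RNG seed.
#' @return an object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iter = 100000L, burn_in = 2000L, thin = 10L,
                        proposal_sd = c(log_shape = 0.3, log_scale = 0.3,
                                        mu = 0.4, rho = 0.1),
                        adapt_during_burnin = TRUE, seed = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (!(n_iter > burn_in) || burn_in < 0) stop("need n_iter > burn_in >= 0")
  if (thin < 1) stop("thin must be >= 1")
  need <- c("log_shape", "log_scale", "mu", "rho")
  if (!all(need %in% names(proposal_sd)) || any(proposal_sd <= 0))
    stop("proposal_sd must name positive SDs for ",
         paste(need, collapse = ", "))
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 proposal_sd = proposal_sd[need],
                 adapt_during_burnin = isTRUE(adapt_during_burnin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Initialise a chain state
#'
#' Weibull shape/scale start at method-of-moments fits on a random N-way
#' split of the sorted rates (contiguous blocks at random cut points, so a
#' bimodal rate distribution yields distinct initial state means); mu starts
#' at 0, rho at 0.5, weights uniform and labels random. Deterministic given
#' the RNG state.
#'
#' @param steps a \code{step_series}.
#' @param n_states number of states, 1 to 3.
#' @param prior a [prior_spec()].
#' @return list with elements \code{shape}, \code{scale}, \code{mu},
#'   \code{rho} (length N), \code{w} (length N) and \code{z} (per step).
#' @export
init_chain <- function(steps, n_states, prior = prior_spec()) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!n_states %in% 1:3) stop("n_states must be 1, 2 or 3")
  dat <- step_data(steps)
  if (dat$n < 5 * n_states)
    stop("too little data: need at least ", 5 * n_states,
         " valid steps for ", n_states, " states")
  r_sorted <- sort(dat$r)
  n <- length(r_sorted)
  if (n_states == 1) {
    blocks <- list(r_sorted)
  } else {
    repeat {
      cuts <- sort(sample(seq_len(n - 1L), n_states - 1L))
      sizes <- diff(c(0L, cuts, n))
      if (all(sizes >= 2L)) break
    }
    blocks <- split(r_sorted, rep(seq_len(n_states), sizes))
  }
  fits <- lapply(blocks, fit_weibull_moments)
  list(shape = vapply(fits, `[[`, 0, "shape"),
       scale = vapply(fits, `[[`, 0, "scale"),
       mu = rep(0, n_states),
       rho = rep(0.5, n_states),
       w = rep(1 / n_states, n_states),
       z = sample.int(n_states, dat$n, replace = TRUE))
}

#' Gibbs update of the state labels
#'
#' Each label is drawn from its exact full conditional
#' \eqn{P(z_t = j) \propto w_j f_j(r_t, \phi_t)}, independently across
#' steps given the parameters; the normalisation is done in log space.
#'
#' @param state chain state as produced by [init_chain()].
#' @param dat list with elements \code{r} and \code{phi} (NA where the
#'   angle is invalid), as returned by the internal step extractor; a
#'   \code{step_series} is also accepted.
#' @return integer vector of new labels.
#' @export
update_labels <- function(state, dat) {
  if (inherits(dat, "step_series")) dat <- step_data(dat)
  if (any(!is.finite(state$shape)) || any(!is.finite(state$scale)))
    stop("non-finite state parameters")
  lw <- state_logdens(dat$r, dat$phi, state$shape, state$scale,
                      state$mu, state$rho)
  n_states <- length(state$w)
  lw <- sweep(lw, 2, log(state$w), "+")
  p <- softmax_rows(lw)
  u <- runif(nrow(p))
  z <- rep(1L, nrow(p))
  if (n_states > 1) {
    cum <- p[, 1]
    for (j in seq_len(n_states - 1L)) {
      z <- z + (u > cum)
      if (j < n_states - 1L) cum <- cum + p[, j + 1]
    }
  }
  z
}

#' Gibbs update of the mixing weights
#'
#' Conjugate Dirichlet-multinomial step: with a symmetric Dirichlet(1)
#' prior, \eqn{w \sim Dirichlet(1 + n_1, ..., 1 + n_N)} where \eqn{n_j}
#' counts the labels currently in state j.
#'
#' @param state chain state (uses \code{state$z} and the number of states).
#' @return numeric simplex of new weights.
#' @export
update_weights <- function(state) {
  n_states <- length(state$w)
  counts <- tabulate(state$z, nbins = n_states)
  g <- stats::rgamma(n_states, shape = 1 + counts, rate = 1)
  g / sum(g)
}

# reflect a proposal into (lo, hi)
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  lo + y
}

#' Metropolis update of the per-state continuous parameters
#'
#' For each state: random-walk Metropolis on log shape and log scale
#' (Gamma priors, log-scale Jacobian included), a wrapped random walk on mu
#' (uniform circular prior) and a reflected random walk on rho inside
#' (0, rho_max) (uniform prior). Acceptance uses the likelihood of the
#' steps currently labelled with that state; a state holding no steps
#' samples from its prior. Each block is a detailed-balance-preserving
#' Metropolis step.
#'
#' @param state chain state.
#' @param dat step data (as in [update_labels()]).
#' @param prior a [prior_spec()].
#' @param proposal_sd 4 x N matrix of proposal SDs (rows log_shape,
#'   log_scale, mu, rho) or a named length-4 vector recycled across states.
#' @return list: the new \code{state} plus an \code{accept} 4 x N 0/1
#'   matrix.
#' @export
update_state_params <- function(state, dat, prior = prior_spec(),
                                proposal_sd = c(log_shape = 0.3,
                                                log_scale = 0.3,
                                                mu = 0.4, rho = 0.1)) {
  if (inherits(dat, "step_series")) dat <- step_data(dat)
  n_states <- length(state$w)
  psd <- if (is.matrix(proposal_sd)) proposal_sd else
    matrix(proposal_sd, 4, n_states,
           dimnames = list(c("log_shape", "log_scale", "mu", "rho"), NULL))
  accept <- matrix(0, 4, n_states,
                   dimnames = list(c("log_shape", "log_scale", "mu", "rho"),
                                   NULL))
  for (j in seq_len(n_states)) {
    in_j <- state$z == j
    r_j <- dat$r[in_j]
    phi_j <- dat$phi[in_j]
    phi_j <- phi_j[!is.na(phi_j)]

    # shape (log-scale walk)
    a <- state$shape[j]
    a_new <- exp(log(a) + stats::rnorm(1, 0, psd["log_shape", j]))
    if (is.finite(a_new) && a_new > 0) {
      delta <- sum(ldweibull(r_j, a_new, state$scale[j])) -
        sum(ldweibull(r_j, a, state$scale[j])) +
        stats::dgamma(a_new, prior$gamma_shape, prior$gamma_rate, log = TRUE) -
        stats::dgamma(a, prior$gamma_shape, prior$gamma_rate, log = TRUE) +
        log(a_new) - log(a)
      if (is.finite(delta) && log(runif(1)) < delta) {
        state$shape[j] <- a_new
        accept["log_shape", j] <- 1
      }
    }

    # scale (log-scale walk)
    b <- state$scale[j]
    b_new <- exp(log(b) + stats::rnorm(1, 0, psd["log_scale", j]))
    if (is.finite(b_new) && b_new > 0) {
      delta <- sum(ldweibull(r_j, state$shape[j], b_new)) -
        sum(ldweibull(r_j, state$shape[j], b)) +
        stats::dgamma(b_new, prior$gamma_shape, prior$gamma_rate, log = TRUE) -
        stats::dgamma(b, prior$gamma_shape, prior$gamma_rate, log = TRUE) +
        log(b_new) - log(b)
      if (is.finite(delta) && log(runif(1)) < delta) {
        state$scale[j] <- b_new
        accept["log_scale", j] <- 1
      }
    }

    # mu (wrapped walk; uniform circular prior cancels)
    mu <- state$mu[j]
    mu_new <- wrap_angle(mu + stats::rnorm(1, 0, psd["mu", j]))
    delta <- sum(dwrpcauchy(phi_j, mu_new, state$rho[j], log = TRUE)) -
      sum(dwrpcauchy(phi_j, mu, state$rho[j], log = TRUE))
    if (is.finite(delta) && log(runif(1)) < delta) {
      state$mu[j] <- mu_new
      accept["mu", j] <- 1
    }

    # rho (reflected walk in (0, rho_max); uniform prior cancels)
    rho <- state$rho[j]
    rho_new <- reflect_into(rho + stats::rnorm(1, 0, psd["rho", j]),
                            0, prior$rho_max)
    delta <- sum(dwrpcauchy(phi_j, state$mu[j], rho_new, log = TRUE)) -
      sum(dwrpcauchy(phi_j, state$mu[j], rho, log = TRUE))
    if (is.finite(delta) && log(runif(1)) < delta) {
      state$rho[j] <- rho_new
      accept["rho", j] <- 1
    }
  }
  list(state = state, accept = accept)
}

#' Run a Metropolis-within-Gibbs chain
#'
#' A single chain following the protocol: burn-in (with optional proposal
#' adaptation towards ~0.3 acceptance, frozen afterwards), then
#' \code{n_iter} sweeps of label update, weight update and per-state
#' parameter updates, keeping every \code{thin}-th sweep. Reproducible
#' given \code{cfg$seed}.
#'
#' @param steps a \code{step_series}.
#' @param n_states number of behavioural states, 1 to 3.
#' @param prior a [prior_spec()].
#' @param cfg an [mcmc_config()].
#' @return a \code{chain_samples} object: matrices \code{shape},
#'   \code{scale}, \code{mu}, \code{rho}, \code{w} (kept samples x states),
#'   integer matrix \code{z} (kept samples x steps), acceptance rates, the
#'   step data and a config echo.
#' @export
run_chain <- function(steps, n_states, prior = prior_spec(),
                      cfg = mcmc_config()) {
  stopifnot(inherits(prior, "prior_spec"), inherits(cfg, "mcmc_config"))
  set.seed(cfg$seed)
  dat <- step_data(steps)
  state <- init_chain(steps, n_states, prior)
  psd <- matrix(cfg$proposal_sd, 4, n_states,
                dimnames = list(names(cfg$proposal_sd), NULL))
  lpsd <- log(psd)

  for (i in seq_len(cfg$burn_in)) {
    state$z <- update_labels(state, dat)
    state$w <- update_weights(state)
    up <- update_state_params(state, dat, prior, exp(lpsd))
    state <- up$state
    if (cfg$adapt_during_burnin) {
      lpsd <- lpsd + i^(-0.6) * (up$accept - 0.3)
      lpsd[lpsd < log(1e-3)] <- log(1e-3)
      lpsd[lpsd > log(10)] <- log(10)
    }
  }
  psd <- exp(lpsd)

  n_keep <- cfg$n_iter %/% cfg$thin
  shape <- scale <- mu <- rho <- w <- matrix(NA_real_, n_keep, n_states)
  z <- matrix(NA_integer_, n_keep, dat$n)
  acc_tot <- matrix(0, 4, n_states,
                    dimnames = list(names(cfg$proposal_sd), NULL))
  k <- 0L
  for (i in seq_len(cfg$n_iter)) {
    state$z <- update_labels(state, dat)
    state$w <- update_weights(state)
    up <- update_state_params(state, dat, prior, psd)
    state <- up$state
    acc_tot <- acc_tot + up$accept
    if (i %% cfg$thin == 0L) {
      k <- k + 1L
      shape[k, ] <- state$shape
      scale[k, ] <- state$scale
      mu[k, ] <- state$mu
      rho[k, ] <- state$rho
      w[k, ] <- state$w
      z[k, ] <- state$z
    }
  }
  structure(
    list(shape = shape, scale = scale, mu = mu, rho = rho, w = w, z = z,
         n_states = n_states, n_kept = n_keep,
         accept_rate = acc_tot / cfg$n_iter,
         data = list(r = dat$r, phi = dat$phi, from = dat$from),
         prior = prior, config = cfg, proposal_sd = psd,
         relabeled = FALSE),
    class = "chain_samples"
  )
}

#' @export
print.chain_samples <- function(x, ...) {
  cat("MCMC chain:", x$n_kept, "kept samples,", x$n_states, "state(s),",
      length(x$data$r), "steps", if (x$relabeled) "(relabeled)" else "", "\n")
  cat("  acceptance rates:\n")
  print(round(x$accept_rate, 3))
  invisible(x)
}

#' Split-chain potential scale reduction factor
#'
#' Simple convergence diagnostic: splits each parameter's kept draws in two
#' halves and computes the between/within variance ratio statistic. Values
#' near 1 indicate the chain has mixed.
#'
#' @param draws numeric vector of kept draws of one parameter.
#' @return the split-chain R-hat.
#' @export
split_rhat <- function(draws) {
  m <- length(draws) %/% 2
  halves <- list(draws[seq_len(m)], draws[m + seq_len(m)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- m * stats::var(means)
  sqrt(((m - 1) / m * W + B / m) / W)
}
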