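# Shared fixture builders: everything is generated in code at test time.

# build a step_series directly from positions on a unit-interval grid
steps_from_xy <- function(x, y, interval = 1) {
  to_step_series(x, y, seq_along(x) - 1, interval = interval)
}

# hand-build a step_series from rate/angle vectors (grid-complete)
make_steps <- function(r, phi = rep(NA_real_, length(r)), interval = 1) {
  m <- length(r)
  out <- data.frame(t = seq_len(m) - 1, r = r, phi = phi,
                    valid_r = rep(TRUE, m),
                    valid_phi = !is.na(phi),
                    from = seq_len(m))
  class(out) <- c("step_series", "data.frame")
  attr(out, "interval") <- interval
  attr(out, "n_r") <- m
  attr(out, "n_phi") <- sum(!is.na(phi))
  out
}

# hand-build a chain_samples object from per-sample parameter matrices
make_chain <- function(shape, scale, mu, rho, w, z, r, phi) {
  M <- nrow(shape)
  structure(
    list(shape = shape, scale = scale, mu = mu, rho = rho, w = w, z = z,
         n_states = ncol(shape), n_kept = M,
         accept_rate = matrix(0, 4, ncol(shape)),
         data = list(r = r, phi = phi, from = seq_along(r)),
         prior = prior_spec(), config = NULL, relabeled = TRUE),
    class = "chain_samples"
  )
}

# short MCMC settings for unit tests
quick_mcmc <- function(seed = 1, n_iter = 3000, burn_in = 500, thin = 5) {
  mcmc_config(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)
}

# batch-means Monte-Carlo standard error for an autocorrelated chain
batch_se <- function(x, n_batch = 20) {
  m <- length(x) %/% n_batch
  means <- vapply(seq_len(n_batch),
                  function(b) mean(x[((b - 1) * m + 1):(b * m)]), 0)
  stats::sd(means) / sqrt(n_batch)
}

# mixture model from parameter vectors
model_from <- function(shape, scale, mu, rho, w = NULL) {
  states <- lapply(seq_along(shape), function(j)
    state_params(shape[j], scale[j], mu[j], rho[j]))
  mixture_model(states, w)
}
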