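# classification-probability array: kept samples x steps x states,
# entry (m, t, j) = P(z_t = j | theta^(m)) ~ w_j f_j(r_t, phi_t)
classification_probs <- function(chain) {
  M <- chain$n_kept
  Tn <- length(chain$data$r)
  N <- chain$n_states
  P <- array(NA_real_, c(M, Tn, N))
  for (m in seq_len(M)) {
    lw <- state_logdens(chain$data$r, chain$data$phi,
                        chain$shape[m, ], chain$scale[m, ],
                        chain$mu[m, ], chain$rho[m, ])
    lw <- sweep(lw, 2, log(chain$w[m, ]), "+")
    P[m, , ] <- softmax_rows(lw)
  }
  P
}

#' Resolve label switching with the Stephens relabeling algorithm
#'
#' The mixture posterior is symmetric under permutation of the state
#' labels, so a chain can swap state identities mid-run. Per kept sample
#' this computes the classification-probability matrix
#' \eqn{P^{(m)}_{tj} \propto w_j f_j(r_t, \phi_t)} and, by coordinate
#' descent, selects one permutation per sample minimising the
#' Kullback-Leibler divergence from the permuted matrix to the across-sample
#' average, enumerating all N! permutations (at most 6 here). The chosen
#' permutations are applied to every per-state parameter, the weights and
#' the labels, leaving each sample's likelihood exactly unchanged.
#'
#' After relabeling the states are put in a canonical presentation order:
#' state 1 is the state with the smaller posterior Weibull mean (the slow,
#' area-restricted mode).
#'
#' @param chain a \code{chain_samples} object.
#' @param max_iter outer coordinate-descent iterations (default 100); on
#'   non-convergence a warning is issued and the best labelling found is
#'   returned.
#' @param canonical also order states by posterior mean movement rate
#'   (default TRUE).
#' @return the relabeled \code{chain_samples} object.
#' @export
relabel_stephens <- function(chain, max_iter = 100, canonical = TRUE) {
  stopifnot(inherits(chain, "chain_samples"))
  N <- chain$n_states
  if (N == 1) {
    chain$relabeled <- TRUE
    return(chain)
  }
  M <- chain$n_kept
  P <- classification_probs(chain)
  perms <- all_permutations(N)
  n_perm <- nrow(perms)
  nu <- rep(1L, M)                       # row index into perms, 1 = identity
  Tn <- dim(P)[2]
  # online first pass: align each sample to the running average so far.
  # (a symmetric batch start - e.g. a chain that spends half its time in
  # each labelling - would otherwise be a fixed point of the descent)
  Q <- P[1, , ]
  for (m in seq_len(M)[-1]) {
    logQ <- log(pmax(Q, 1e-300))
    Pm <- P[m, , ]
    C <- crossprod(Pm, logQ)
    scores <- vapply(seq_len(n_perm), function(p)
      sum(C[cbind(perms[p, ], seq_len(N))]), 0)
    nu[m] <- which.max(scores)
    Q <- Q * ((m - 1) / m) + Pm[, perms[nu[m], ], drop = FALSE] / m
  }
  for (iter in seq_len(max_iter)) {
    # running average Q of the currently permuted matrices
    Q <- matrix(0, Tn, N)
    for (p in seq_len(n_perm)) {
      idx <- which(nu == p)
      if (!length(idx)) next
      S <- colSums(P[idx, , , drop = FALSE])   # T x N sum over those samples
      Q <- Q + S[, perms[p, ], drop = FALSE]
    }
    Q <- Q / M
    logQ <- log(pmax(Q, 1e-300))
    # best permutation per sample: maximise sum_tj P[t, sigma(j)] logQ[t, j]
    nu_new <- integer(M)
    for (m in seq_len(M)) {
      C <- crossprod(P[m, , ], logQ)           # N_old x N_new
      scores <- vapply(seq_len(n_perm), function(p)
        sum(C[cbind(perms[p, ], seq_len(N))]), 0)
      nu_new[m] <- which.max(scores)
    }
    if (identical(nu_new, nu)) break
    nu <- nu_new
    if (iter == max_iter)
      warning("Stephens relabeling did not converge in ", max_iter,
              " iterations; returning best labelling found")
  }
  chain <- apply_permutations(chain, perms, nu)
  chain$relabeled <- TRUE
  if (canonical) chain <- canonical_state_order(chain)
  chain
}

# apply per-sample permutations: new state j of sample m = old state
# perms[nu[m], j]
apply_permutations <- function(chain, perms, nu) {
  for (p in seq_len(nrow(perms))) {
    sigma <- perms[p, ]
    if (all(sigma == seq_along(sigma))) next
    idx <- which(nu == p)
    if (!length(idx)) next
    for (f in c("shape", "scale", "mu", "rho", "w"))
      chain[[f]][idx, ] <- chain[[f]][idx, sigma, drop = FALSE]
    zb <- chain$z[idx, , drop = FALSE]
    chain$z[idx, ] <- matrix(match(zb, sigma), nrow = length(idx))
  }
  chain
}

#' Order states canonically by posterior mean movement rate
#'
#' Applies one global permutation so that state 1 has the smallest
#' posterior Weibull mean (slow, area-restricted) and the last state the
#' largest (fast transiting), matching the usual presentation convention.
#'
#' @param chain a \code{chain_samples} object.
#' @return the reordered chain.
#' @export
canonical_state_order <- function(chain) {
  N <- chain$n_states
  if (N == 1) return(chain)
  means <- vapply(seq_len(N), function(j)
    mean(chain$scale[, j] * gamma(1 + 1 / chain$shape[, j])), 0)
  ord <- order(means)
  if (all(ord == seq_len(N))) return(chain)
  perms <- matrix(ord, 1)
  apply_permutations(chain, perms, rep(1L, chain$n_kept))
}

#' Posterior mean density with SD band
#'
#' Averages the per-sample parametric density over the kept MCMC samples:
#' \eqn{\bar f(x) = M^{-1} \sum_m f(x; \theta^{(m)})}, with the pointwise
#' sample SD across the draws. Being a mean of densities, the mean curve
#' integrates to one.
#'
#' @param chain a relabeled \code{chain_samples}.
#' @param which \code{"rate"} (Weibull) or \code{"angle"} (wrapped Cauchy).
#' @param state state index.
#' @param grid abscissae; defaults to 512 points spanning the data range
#'   (rates) or (-pi, pi] (angles).
#' @return a \code{posterior_density} list: \code{grid},
#'   \code{mean_curve}, \code{sd_curve}.
#' @export
posterior_density <- function(chain, which = c("rate", "angle"), state = 1,
                              grid = NULL) {
  stopifnot(inherits(chain, "chain_samples"))
  which <- match.arg(which)
  M <- chain$n_kept
  if (M < 1) stop("empty chain")
  if (state < 1 || state > chain$n_states) stop("state index out of range")
  if (is.null(grid)) {
    grid <- if (which == "rate")
      seq(1e-9, max(chain$data$r) * 2.5, length.out = 512)
    else seq(-pi, pi, length.out = 512)
  }
  s1 <- s2 <- numeric(length(grid))
  for (m in seq_len(M)) {
    f <- if (which == "rate")
      exp(ldweibull(grid, chain$shape[m, state], chain$scale[m, state]))
    else dwrpcauchy(grid, chain$mu[m, state], chain$rho[m, state])
    s1 <- s1 + f
    s2 <- s2 + f^2
  }
  mean_curve <- s1 / M
  var_curve <- pmax(0, (s2 - s1^2 / M) / max(M - 1, 1))
  structure(list(grid = grid, mean_curve = mean_curve,
                 sd_curve = sqrt(var_curve), which = which, state = state),
            class = "posterior_density")
}

#' Posterior mean movement rate of a state
#'
#' The posterior mean of the Weibull mean \eqn{b\,\Gamma(1 + 1/a)} across
#' kept samples, with its SD across samples.
#'
#' @param chain a relabeled \code{chain_samples}.
#' @param state state index.
#' @return named numeric: \code{mean}, \code{sd} (rate units).
#' @export
posterior_weibull_mean <- function(chain, state = 1) {
  stopifnot(inherits(chain, "chain_samples"))
  m_s <- chain$scale[, state] * gamma(1 + 1 / chain$shape[, state])
  c(mean = mean(m_s), sd = stats::sd(m_s))
}

#' Posterior mean turn vector of a state
#'
#' The across-sample average of the wrapped Cauchy mean vector
#' \eqn{(\rho\cos\mu, \rho\sin\mu)}, with a scalar SD defined as the
#' root-mean-square planar deviation of the sample vectors from their mean
#' (the radius of the circle drawn around the arrow head).
#'
#' @param chain a relabeled \code{chain_samples}.
#' @param state state index.
#' @return list: \code{vector} (length 2), \code{sd} (scalar).
#' @export
posterior_mean_vector <- function(chain, state = 1) {
  stopifnot(inherits(chain, "chain_samples"))
  vx <- chain$rho[, state] * cos(chain$mu[, state])
  vy <- chain$rho[, state] * sin(chain$mu[, state])
  v <- c(mean(vx), mean(vy))
  list(vector = v, sd = sqrt(mean((vx - v[1])^2 + (vy - v[2])^2)))
}

#' Per-step posterior state probabilities
#'
#' For every step, the fraction of kept samples assigning it to each state
#' (no discretisation: the full posterior membership is retained).
#'
#' @param chain a relabeled \code{chain_samples}.
#' @return matrix (steps x states) of probabilities; rows sum to 1.
#'   The attribute \code{from} maps rows to the step's first fix.
#' @export
state_probabilities <- function(chain) {
  stopifnot(inherits(chain, "chain_samples"))
  N <- chain$n_states
  P <- vapply(seq_len(N), function(j) colMeans(chain$z == j),
              numeric(ncol(chain$z)))
  P <- matrix(P, ncol = N)
  attr(P, "from") <- chain$data$from
  P
}

#' Classification accuracy against known regimes
#'
#' Assigns each step to its maximum-probability state (ties to the lower
#' index) and returns the maximum, over all permutations of the state
#' labels, of the fraction of steps whose assigned state matches the true
#' generating regime. The permutation maximisation makes the score
#' invariant to how the mixture happened to label its states.
#'
#' @param probs steps x states probability matrix
#'   (from [state_probabilities()]).
#' @param truth true labels, one per step: integers in 1..N or a
#'   factor/character vector with at most N distinct values.
#' @return fraction correct in \[0, 1\].
#' @export
classification_accuracy <- function(probs, truth) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(truth))
    stop("probs and truth must have the same number of steps")
  N <- ncol(probs)
  truth_i <- as.integer(factor(truth))
  if (max(truth_i) > N) stop("more true classes than model states")
  pred <- max.col(probs, ties.method = "first")
  perms <- all_permutations(N)
  best <- 0
  for (p in seq_len(nrow(perms)))
    best <- max(best, mean(perms[p, pred] == truth_i))
  best
}

#' Full posterior summary of a fitted chain
#'
#' Convenience wrapper collecting, per state, the posterior mean movement
#' rate, the mean turn vector and the mean density curves, plus the
#' per-step state probabilities.
#'
#' @param chain a relabeled \code{chain_samples}.
#' @param rate_grid,angle_grid optional abscissae passed to
#'   [posterior_density()].
#' @return a \code{posterior_summary} list.
#' @export
posterior_summary <- function(chain, rate_grid = NULL, angle_grid = NULL) {
  stopifnot(inherits(chain, "chain_samples"))
  states <- lapply(seq_len(chain$n_states), function(j) {
    wm <- posterior_weibull_mean(chain, j)
    list(state = j,
         weibull_mean = wm[["mean"]], weibull_mean_sd = wm[["sd"]],
         mean_vector = posterior_mean_vector(chain, j),
         rate_density = posterior_density(chain, "rate", j, rate_grid),
         angle_density = posterior_density(chain, "angle", j, angle_grid))
  })
  structure(list(states = states, probs = state_probabilities(chain),
                 n_states = chain$n_states),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary,", x$n_states, "state(s):\n")
  for (s in x$states) {
    v <- s$mean_vector
    cat(sprintf(
      "  state %d: mean rate %.4g (sd %.3g); mean vector (%.3f, %.3f), |v| = %.3f (sd %.3f)\n",
      s$state, s$weibull_mean, s$weibull_mean_sd,
      v$vector[1], v$vector[2], sqrt(sum(v$vector^2)), v$sd))
  }
  invisible(x)
}
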