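test_that("chain initialisation is deterministic and moment-based", {
  set.seed(51)
  r <- c(rweibull(150, 8, 0.3), rweibull(150, 8, 2.0))  # bimodal rates
  s <- make_steps(sample(r))
  set.seed(1); st1 <- init_chain(s, 2)
  set.seed(1); st2 <- init_chain(s, 2)
  expect_identical(st1, st2)
  # the sorted-block moment split separates the two modes
  means <- weibull_mean(st1$shape, st1$scale)
  expect_gt(max(means) / min(means), 1.5)

  set.seed(2)
  st <- init_chain(s, 1)
  expect_equal(st$z, rep(1L, 300))
  expect_equal(st$w, 1)

  expect_error(init_chain(make_steps(c(1, 2, 3)), 1), "too little data")
})

test_that("label full conditionals match brute-force enumeration", {
  dat <- list(r = c(0.2, 0.9, 1.6, 2.4),
              phi = c(0.1, NA, 3.0, -1.2), n = 4)
  state <- list(shape = c(1.2, 2.5), scale = c(0.4, 1.8),
                mu = c(3.0, 0.0), rho = c(0.6, 0.3),
                w = c(0.35, 0.65), z = c(1L, 1L, 2L, 2L))
  # brute-force per-step conditionals
  f <- function(t, j) {
    d <- dweibull(dat$r[t], state$shape[j], state$scale[j])
    if (!is.na(dat$phi[t]))
      d <- d * dwrpcauchy(dat$phi[t], state$mu[j], state$rho[j])
    d
  }
  cond <- t(vapply(1:4, function(t) {
    u <- state$w * c(f(t, 1), f(t, 2))
    u / sum(u)
  }, numeric(2)))

  set.seed(52)
  n_draws <- 20000
  draws <- matrix(0L, n_draws, 4)
  for (i in seq_len(n_draws)) draws[i, ] <- update_labels(state, dat)

  # joint distribution over the 2^4 label patterns vs the product law
  pat <- draws %*% c(1L, 2L, 4L, 8L)   # codes 15..30 for labels in {1,2}^4
  emp <- tabulate(pat - 14L, nbins = 16) / n_draws
  exact <- numeric(16)
  for (code in 0:15) {
    zz <- 1L + as.integer(intToBits(code)[1:4])
    exact[code + 1] <- prod(cond[cbind(1:4, zz)])
  }
  tv <- sum(abs(emp - exact)) / 2
  expect_lt(tv, 0.01)

  # dominant-likelihood limit: probability ~ 1 - 1e-6 for the favoured state
  st2 <- state
  st2$scale <- c(0.4, 0.4); st2$shape <- c(1.2, 1.2)
  st2$mu <- c(0, 0); st2$rho <- c(0.98, 0.0); st2$w <- c(0.5, 0.5)
  dat2 <- list(r = 0.4, phi = 0.0, n = 1)
  p1 <- dwrpcauchy(0, 0, 0.98) / (dwrpcauchy(0, 0, 0.98) + dwrpcauchy(0, 0, 0))
  hits <- mean(vapply(1:4000, function(i) update_labels(st2, dat2), 0L) == 1L)
  expect_lt(abs(hits - p1), 3 * sqrt(p1 * (1 - p1) / 4000) + 1e-3)

  # identical states: conditional equals the weights
  st3 <- state
  st3$shape <- c(1, 1); st3$scale <- c(1, 1); st3$mu <- c(0, 0)
  st3$rho <- c(0.3, 0.3); st3$w <- c(0.8, 0.2)
  freqs <- rowMeans(vapply(1:20000, function(i) update_labels(st3, dat),
                           integer(4)) == 1L)
  expect_true(all(abs(freqs - 0.8) < 3 * sqrt(0.8 * 0.2 / 20000)))
})

test_that("weight updates are conjugate Dirichlet draws", {
  state <- list(w = c(0.5, 0.5), z = rep(1L, 10))   # counts (10, 0)
  set.seed(53)
  w1 <- vapply(1:20000, function(i) update_weights(state)[1], 0)
  # Dirichlet(11, 1): mean 11/12, var 11/(12^2*13)
  se <- sqrt(11 / (144 * 13) / 20000)
  expect_lt(abs(mean(w1) - 11 / 12), 3 * se)
  expect_true(all(w1 > 0 & w1 < 1))

  s1 <- list(w = 1, z = rep(1L, 5))
  expect_equal(update_weights(s1), 1)

  s3 <- list(w = rep(1 / 3, 3), z = c(1L, 2L, 3L, 3L))
  w <- update_weights(s3)
  expect_equal(sum(w), 1)
})

test_that("vanishing proposals keep the chain in place", {
  dat <- list(r = c(0.5, 1), phi = c(0.2, -0.4), n = 2)
  state <- list(shape = c(1.5), scale = c(0.8), mu = 0.3, rho = 0.4,
                w = 1, z = c(1L, 1L))
  set.seed(54)
  tiny <- c(log_shape = 1e-12, log_scale = 1e-12, mu = 1e-12, rho = 1e-12)
  out <- update_state_params(state, dat, prior_spec(), tiny)$state
  expect_equal(out$shape, state$shape, tolerance = 1e-9)
  expect_equal(out$scale, state$scale, tolerance = 1e-9)
  expect_equal(out$mu, state$mu, tolerance = 1e-9)
  expect_equal(out$rho, state$rho, tolerance = 1e-9)
})

test_that("prior-only Metropolis updates recover the stated priors", {
  # no data in the state: the target is the prior itself
  dat <- list(r = numeric(0), phi = numeric(0), n = 0)
  prior <- prior_spec()
  psd <- c(log_shape = 3, log_scale = 3, mu = 1.5, rho = 0.3)
  state <- list(shape = 1, scale = 1, mu = 0, rho = 0.5, w = 1, z = integer(0))
  set.seed(55)
  n <- 60000
  a <- b <- rho <- numeric(n)
  for (i in seq_len(n)) {
    state <- update_state_params(state, dat, prior, psd)$state
    a[i] <- state$shape; b[i] <- state$scale; rho[i] <- state$rho
  }
  # Gamma(0.3, 0.01): mean 30, variance 3000 (moment-matched)
  expect_lt(abs(mean(a) - 30), 3 * batch_se(a))
  expect_lt(abs(mean(b) - 30), 3 * batch_se(b))
  v <- (a - 30)^2
  expect_lt(abs(mean(v) - 3000), 3 * batch_se(v))
  # rho uniform on (0, rho_max): mean rho_max/2, all draws inside
  expect_true(all(rho > 0 & rho < prior$rho_max))
  expect_lt(abs(mean(rho) - prior$rho_max / 2), 3 * batch_se(rho))
})

test_that("single-state posterior matches dense-grid quadrature", {
  r <- c(0.6, 1.1, 1.9, 0.8, 1.4)
  phi <- c(0.4, 0.1, 0.9, -0.3, 0.6)
  s <- make_steps(r, phi)
  ch <- run_chain(s, 1, cfg = mcmc_config(n_iter = 60000, burn_in = 2000,
                                          thin = 5, seed = 56))

  # (shape, scale) posterior by 2D quadrature on a log grid
  lg <- seq(log(1e-3), log(400), length.out = 400)
  gr <- exp(lg)
  lweib <- function(x, a, b)          # log density, safe at extreme shapes
    sum(log(a) - log(b) + (a - 1) * (log(x) - log(b)) -
          exp(a * (log(x) - log(b))))
  post <- outer(gr, gr, function(a, b) {
    ll <- vapply(seq_along(a), function(i) lweib(r, a[i], b[i]), 0)
    ll + dgamma(a, 0.3, 0.01, log = TRUE) + dgamma(b, 0.3, 0.01, log = TRUE) +
      log(a) + log(b)      # log-grid Jacobian
  })
  post[!is.finite(post)] <- -Inf
  w <- exp(post - max(post))
  w <- w / sum(w)
  qa <- sum(rowSums(w) * gr)
  qb <- sum(colSums(w) * gr)
  expect_lt(abs(mean(ch$shape) - qa), 3 * batch_se(ch$shape[, 1]))
  expect_lt(abs(mean(ch$scale) - qb), 3 * batch_se(ch$scale[, 1]))

  # (mu, rho) posterior by 2D quadrature
  mus <- seq(-pi, pi, length.out = 361)[-1]
  rhos <- seq(1e-4, 0.99 - 1e-4, length.out = 250)
  post2 <- outer(mus, rhos, function(m, rr)
    vapply(seq_along(m), function(i)
      sum(dwrpcauchy(phi, m[i], rr[i], log = TRUE)), 0))
  w2 <- exp(post2 - max(post2))
  w2 <- w2 / sum(w2)
  qmu <- sum(rowSums(w2) * mus)
  qrho <- sum(colSums(w2) * rhos)
  expect_lt(abs(mean(ch$mu) - qmu), 3 * batch_se(ch$mu[, 1]))
  expect_lt(abs(mean(ch$rho) - qrho), 3 * batch_se(ch$rho[, 1]))
})

test_that("run_chain bookkeeping: kept count, reproducibility, mixing", {
  traj <- simulate_trajectory(generator_config(seed = 57))
  steps <- steps_from_xy(traj$x, traj$y)
  cfg <- quick_mcmc(seed = 58, n_iter = 4000, burn_in = 800, thin = 10)
  ch <- run_chain(steps, 2, cfg = cfg)
  expect_equal(ch$n_kept, 400)
  expect_equal(dim(ch$z), c(400, attr(steps, "n_r")))
  expect_true(all(ch$rho >= 0 & ch$rho <= prior_spec()$rho_max))
  expect_true(all(ch$z %in% 1:2))
  expect_equal(abs(rowSums(ch$w) - 1), rep(0, 400), tolerance = 1e-12)

  ch2 <- run_chain(steps, 2, cfg = cfg)
  expect_identical(ch, ch2)

  # split-chain scale-reduction on the continuous parameters
  ch3 <- run_chain(steps, 2, cfg = quick_mcmc(seed = 59, n_iter = 8000,
                                              burn_in = 1500, thin = 4))
  ch3 <- relabel_stephens(ch3)
  for (j in 1:2) {
    expect_lt(split_rhat(ch3$shape[, j]), 1.1)
    expect_lt(split_rhat(ch3$scale[, j]), 1.1)
    expect_lt(split_rhat(ch3$rho[, j]), 1.1)
  }
})
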