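test_that("relabeling restores an artificially swapped chain exactly", {
  set.seed(61)
  # well-separated two-state chain with jittered parameters
  M <- 60
  r <- c(rweibull(40, 6, 0.3), rweibull(40, 6, 2))
  phi <- c(rwrpcauchy(40, pi, 0.6), rwrpcauchy(40, 0, 0.6))
  shape <- cbind(rnorm(M, 6, 0.1), rnorm(M, 6, 0.1))
  scale <- cbind(rnorm(M, 0.3, 0.01), rnorm(M, 2, 0.05))
  mu <- cbind(rnorm(M, pi - 0.05, 0.02), rnorm(M, 0, 0.02))
  rho <- matrix(0.6, M, 2)
  w <- matrix(0.5, M, 2)
  z <- matrix(rep(rep(1:2, each = 40), M), M, 80, byrow = TRUE)
  ch <- make_chain(shape, scale, mu, rho, w, z, r, phi)

  # a chain with no switching gets identity permutations everywhere
  unswitched <- relabel_stephens(ch, canonical = FALSE)
  expect_equal(unswitched$shape, ch$shape)
  expect_equal(unswitched$z, ch$z)

  # duplicate the chain with states 1 <-> 2 swapped in the copy
  sw <- ch
  for (f in c("shape", "scale", "mu", "rho", "w"))
    sw[[f]] <- sw[[f]][, 2:1]
  sw$z <- matrix(3L - sw$z, M)
  both <- make_chain(rbind(ch$shape, sw$shape), rbind(ch$scale, sw$scale),
                     rbind(ch$mu, sw$mu), rbind(ch$rho, sw$rho),
                     rbind(ch$w, sw$w), rbind(ch$z, sw$z), r, phi)
  fixed <- relabel_stephens(both, canonical = FALSE)
  # the two halves agree exactly after relabeling
  expect_equal(fixed$shape[1:M, ], fixed$shape[M + (1:M), ])
  expect_equal(fixed$mu[1:M, ], fixed$mu[M + (1:M), ])
  expect_equal(fixed$z[1:M, ], fixed$z[M + (1:M), ])

  # relabeling leaves every sample's likelihood exactly unchanged
  s <- make_steps(r, phi)
  for (m in c(1, M, M + 1, 2 * M)) {
    mod_before <- model_from(both$shape[m, ], both$scale[m, ],
                             both$mu[m, ], both$rho[m, ], both$w[m, ])
    mod_after <- model_from(fixed$shape[m, ], fixed$scale[m, ],
                            fixed$mu[m, ], fixed$rho[m, ], fixed$w[m, ])
    expect_equal(mixture_loglik(s, fixed$z[m, ], mod_after),
                 mixture_loglik(s, both$z[m, ], mod_before))
  }

  # idempotence: relabeling a relabeled chain changes nothing
  again <- relabel_stephens(fixed, canonical = FALSE)
  expect_equal(state_probabilities(again), state_probabilities(fixed))
})

test_that("canonical ordering puts the slow state first", {
  set.seed(62)
  M <- 30
  shape <- matrix(2, M, 2)
  scale <- cbind(rnorm(M, 3, 0.1), rnorm(M, 0.5, 0.02))  # state 1 is fast
  ch <- make_chain(shape, scale, matrix(0, M, 2), matrix(0.5, M, 2),
                   matrix(0.5, M, 2),
                   matrix(sample(1:2, M * 10, TRUE), M, 10),
                   r = rweibull(10, 2, 1), phi = rep(NA_real_, 10))
  ord <- canonical_state_order(ch)
  m1 <- posterior_weibull_mean(ord, 1)[["mean"]]
  m2 <- posterior_weibull_mean(ord, 2)[["mean"]]
  expect_lt(m1, m2)
})

test_that("posterior mean densities average the sampled pdfs and integrate to one", {
  r <- rweibull(20, 2, 1)
  phi <- rwrpcauchy(20, 0, 0.4)
  one <- make_chain(matrix(1.7, 1, 1), matrix(0.9, 1, 1),
                    matrix(0.2, 1, 1), matrix(0.5, 1, 1),
                    matrix(1, 1, 1), matrix(1L, 1, 20), r, phi)
  d <- posterior_density(one, "rate", 1, grid = seq(1e-9, 8, length.out = 300))
  expect_equal(d$mean_curve, dweibull(d$grid, 1.7, 0.9))
  expect_equal(d$sd_curve, rep(0, 300))

  # identical samples: zero SD band
  many <- make_chain(matrix(1.7, 50, 1), matrix(0.9, 50, 1),
                     matrix(0.2, 50, 1), matrix(0.5, 50, 1),
                     matrix(1, 50, 1), matrix(1L, 50, 20), r, phi)
  d2 <- posterior_density(many, "angle", 1)
  expect_lt(max(d2$sd_curve), 1e-6)   # identically-parameterised samples

  # heterogeneous samples on a fine grid still integrate to 1 +- 1e-3
  set.seed(63)
  M <- 200
  het <- make_chain(matrix(runif(M, 1, 4), M, 1),
                    matrix(runif(M, 0.5, 2), M, 1),
                    matrix(runif(M, -3, 3), M, 1),
                    matrix(runif(M, 0, 0.95), M, 1),
                    matrix(1, M, 1), matrix(1L, M, 20), r, phi)
  grid_r <- seq(1e-9, 30, length.out = 2048)
  dr <- posterior_density(het, "rate", 1, grid = grid_r)
  ir <- sum(diff(grid_r) * (dr$mean_curve[-1] + dr$mean_curve[-2048]) / 2)
  expect_lt(abs(ir - 1), 1e-3)
  grid_a <- seq(-pi, pi, length.out = 2048)
  da <- posterior_density(het, "angle", 1, grid = grid_a)
  ia <- sum(diff(grid_a) * (da$mean_curve[-1] + da$mean_curve[-2048]) / 2)
  expect_lt(abs(ia - 1), 1e-3)

  expect_error(posterior_density(het, "rate", 3), "out of range")
})

test_that("posterior Weibull mean and mean vector follow hand arithmetic", {
  r <- c(0.5, 1); phi <- c(0.1, -0.1)
  # all samples a = 1, b = 2: mean 2, SD 0
  ch <- make_chain(matrix(1, 5, 1), matrix(2, 5, 1), matrix(0, 5, 1),
                   matrix(0.3, 5, 1), matrix(1, 5, 1),
                   matrix(1L, 5, 2), r, phi)
  wm <- posterior_weibull_mean(ch, 1)
  expect_equal(unname(wm), c(2, 0))

  # two samples with means 1 and 3: mean 2, sample SD sqrt(2)
  ch2 <- make_chain(matrix(1, 2, 1), matrix(c(1, 3), 2, 1),
                    matrix(0, 2, 1), matrix(0.3, 2, 1), matrix(1, 2, 1),
                    matrix(1L, 2, 2), r, phi)
  wm2 <- posterior_weibull_mean(ch2, 1)
  expect_equal(unname(wm2), c(2, sqrt(2)))

  # posterior Weibull mean agrees with simulating from each sampled Weibull
  set.seed(64)
  M <- 40
  ch3 <- make_chain(matrix(runif(M, 1, 3), M, 1),
                    matrix(runif(M, 0.5, 2), M, 1),
                    matrix(0, M, 1), matrix(0.3, M, 1), matrix(1, M, 1),
                    matrix(1L, M, 2), r, phi)
  draws <- unlist(lapply(seq_len(M), function(m)
    rweibull(20000, ch3$shape[m, 1], ch3$scale[m, 1])))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(posterior_weibull_mean(ch3, 1)[["mean"]] - mean(draws)),
            3 * se)

  # opposed mean vectors cancel; SD is the planar RMS radius
  ch4 <- make_chain(matrix(1, 2, 1), matrix(1, 2, 1),
                    matrix(c(0, pi), 2, 1), matrix(0.8, 2, 1),
                    matrix(1, 2, 1), matrix(1L, 2, 2), r, phi)
  mv <- posterior_mean_vector(ch4, 1)
  expect_equal(mv$vector, c(0, 0))
  expect_equal(mv$sd, 0.8)

  # all-uniform chain: zero vector, zero SD
  ch5 <- make_chain(matrix(1, 3, 1), matrix(1, 3, 1), matrix(1, 3, 1),
                    matrix(0, 3, 1), matrix(1, 3, 1),
                    matrix(1L, 3, 2), r, phi)
  mv5 <- posterior_mean_vector(ch5, 1)
  expect_equal(mv5$vector, c(0, 0))
  expect_equal(mv5$sd, 0)

  # Jensen: |posterior mean vector| <= mean of sample norms
  set.seed(65)
  ch6 <- make_chain(matrix(1, 20, 1), matrix(1, 20, 1),
                    matrix(runif(20, -pi, pi), 20, 1),
                    matrix(runif(20, 0, 0.9), 20, 1),
                    matrix(1, 20, 1), matrix(1L, 20, 2), r, phi)
  mv6 <- posterior_mean_vector(ch6, 1)
  expect_lte(sqrt(sum(mv6$vector^2)), mean(ch6$rho[, 1]))
})

test_that("state probabilities are sample frequencies with unit row sums", {
  r <- c(0.5, 1, 2); phi <- c(0.1, 0.2, 0.3)
  z <- rbind(c(1L, 1L, 2L), c(1L, 2L, 2L), c(1L, 1L, 2L), c(1L, 2L, 2L))
  ch <- make_chain(matrix(1, 4, 2), matrix(1:2, 4, 2, byrow = TRUE),
                   matrix(0, 4, 2), matrix(0.3, 4, 2),
                   matrix(0.5, 4, 2), z, r, phi)
  P <- state_probabilities(ch)
  expect_equal(P[, 1], c(1, 0.5, 0))
  expect_equal(rowSums(P), rep(1, 3))
})

test_that("classification accuracy maximises over label permutations", {
  agree <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(classification_accuracy(agree, c(1, 1, 2, 2)), 1)
  # globally swapped assignment is still perfect under permutation
  expect_equal(classification_accuracy(agree, c(2, 2, 1, 1)), 1)
  # alternating mismatch: 0.5 under either permutation
  alt <- cbind(c(0.9, 0.1, 0.9, 0.1), c(0.1, 0.9, 0.1, 0.9))
  expect_equal(classification_accuracy(alt, c(1, 1, 2, 2)), 0.5)
  # ties break to the lower state index
  tie <- cbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(classification_accuracy(tie, c(1, 1)), 1)
  expect_error(classification_accuracy(agree, c(1, 2)), "same number")
})
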