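sched2 <- noise_schedule(2, beta_start = 0.1, beta_end = 0.2)

test_that("closed-form forward marginal matches hand arithmetic", {
  # noiseless limit
  x0 <- matrix(c(0.2, -0.5, 0.9, 0), 2, 2)
  z <- matrix(0, 2, 2)
  expect_equal(forward_sample(x0, 1, z, sched2), sqrt(0.9) * x0)
  # scalar example: x0 = 1, t = 2, eps = 0 -> sqrt(0.72)
  expect_equal(forward_sample(1, 2, 0, sched2), sqrt(0.72))
  expect_equal(sqrt(0.72), 0.8485281, tolerance = 1e-6)
  expect_error(forward_sample(x0, 3, z, sched2), "range")
})

test_that("iterating single steps reproduces the closed form deterministic part", {
  # two applications of the one-step map with eps = 0 give sqrt(a2*a1)*x0
  x0 <- matrix(runif(9), 3, 3)
  z <- matrix(0, 3, 3)
  x1 <- single_step_forward(x0, 1, z, sched2)
  x2 <- single_step_forward(x1, 2, z, sched2)
  expect_equal(x2, sqrt(sched2$alpha[2] * sched2$alpha[1]) * x0)
  expect_equal(x2, forward_sample(x0, 2, z, sched2))
  # merged-noise variance: Var(x_t | x_0) = 1 - alpha_bar_t when composing
  # two independent per-step noises (checked in closed form)
  a1 <- sched2$alpha[1]; a2 <- sched2$alpha[2]
  expect_equal(a2 * (1 - a1) + (1 - a2), 1 - sched2$alpha_bar[2])
})

test_that("one-step map has the stated mean and variance", {
  expect_equal(single_step_forward(0, 1, 1,
                                   noise_schedule(1, beta_start = 0.25,
                                                  beta_end = 0.25)), 0.5)
  # Monte-Carlo moment check at x_prev = 0
  s <- noise_schedule(3, beta_start = 0.1, beta_end = 0.3)
  set.seed(99)
  draws <- vapply(seq_len(1e5), function(i)
    single_step_forward(0, 2, rnorm(1), s), 0)
  se <- sqrt(2 / (1e5 - 1)) * s$beta[2]     # se of a sample variance
  expect_lt(abs(var(draws) - s$beta[2]), 3 * se)
})

test_that("posterior mean and variance follow the Gaussian-conditional formulas", {
  expect_equal(posterior_variance(2, sched2), 0.0714285714, tolerance = 1e-9)
  expect_equal(posterior_variance(1, sched2), 0)
  # t = 1: mean reduces to the x0 term only (alpha_bar_0 = 1)
  x_t <- matrix(rnorm(4), 2, 2)
  x0 <- matrix(rnorm(4), 2, 2)
  expect_equal(posterior_mean(x_t, x0, 1, sched2), x0)
})

test_that("the two posterior-mean forms agree on random inputs", {
  s <- noise_schedule(10, beta_start = 0.01, beta_end = 0.2)
  set.seed(7)
  for (t in 1:10) {
    x0 <- matrix(rnorm(16), 4, 4)
    eps <- matrix(rnorm(16), 4, 4)
    x_t <- forward_sample(x0, t, eps, s)
    x0_rec <- predict_x0(x_t, eps, t, s)
    expect_equal(posterior_mean(x_t, x0_rec, t, s),
                 posterior_mean_from_eps(x_t, eps, t, s),
                 tolerance = 1e-10)
  }
})

test_that("clean-image recovery inverts the forward marginal at every t", {
  s <- noise_schedule(10, beta_start = 0.01, beta_end = 0.2)
  set.seed(11)
  worst <- 0
  for (t in 1:10) {
    x0 <- matrix(rnorm(25), 5, 5)
    eps <- matrix(rnorm(25), 5, 5)
    x0_rec <- predict_x0(forward_sample(x0, t, eps, s), eps, t, s)
    worst <- max(worst, max(abs(x0_rec - x0)))
  }
  expect_lt(worst, 1e-6)
  # eps = 0 special case
  x_t <- matrix(2, 2, 2)
  expect_equal(predict_x0(x_t, matrix(0, 2, 2), 2, sched2),
               x_t / sqrt(0.72))
})

test_that("training loss is a mean of squared differences", {
  e <- array(rnorm(24), dim = c(2, 3, 4))
  expect_equal(diffusion_loss(e, e), 0)
  expect_equal(diffusion_loss(array(0, dim = c(2, 2)),
                              array(0.3, dim = c(2, 2))), 0.09)
  f <- array(rnorm(24), dim = c(2, 3, 4))
  brute <- sum((as.vector(e) - as.vector(f))^2) / 24
  expect_equal(diffusion_loss(e, f), brute)
  expect_error(diffusion_loss(e, array(0, dim = c(2, 3))), "shape")
})

test_that("forward marginal has the stated mean and variance empirically", {
  s <- noise_schedule(5, beta_start = 0.05, beta_end = 0.4)
  x0 <- 0.7
  set.seed(123)
  n <- 2e4
  draws <- sqrt(s$alpha_bar[4]) * x0 + sqrt(1 - s$alpha_bar[4]) * rnorm(n)
  expect_lt(abs(mean(draws) - sqrt(s$alpha_bar[4]) * x0),
            4 * sqrt((1 - s$alpha_bar[4]) / n))
  expect_lt(abs(var(draws) - (1 - s$alpha_bar[4])),
            4 * sqrt(2 / (n - 1)) * (1 - s$alpha_bar[4]))
})

test_that("one-step reverse with the exact noise recovers x0 exactly", {
  s1 <- noise_schedule(1, beta_start = 0.3, beta_end = 0.3)
  x0 <- matrix(seq(-0.8, 0.8, length.out = 9), 3, 3)
  set.seed(5)
  eps_used <- matrix(rnorm(9), 3, 3)
  x1 <- forward_sample(x0, 1, eps_used, s1)
  # oracle denoiser returning the exact noise used; z = 0 at t = 1 so the
  # sigma term vanishes and alpha_bar_1 = alpha_1
  rec <- posterior_mean_from_eps(x1, eps_used, 1, s1)
  expect_equal(rec, x0, tolerance = 1e-12)
})

test_that("deterministic sampler trajectory converges to the oracle target", {
  s <- noise_schedule(50, beta_start = 0.004, beta_end = 0.18)
  x0_star <- matrix(seq(-0.9, 0.9, length.out = 16), 4, 4)
  oracle <- function(x, t, tau)
    (x - sqrt(s$alpha_bar[t]) * x0_star) / sqrt(1 - s$alpha_bar[t])
  out <- ddpm_sample(oracle, s, c(4, 4), seed = 1, sigma_scale = 0,
                     clip = NULL)
  expect_lt(max(abs(out - x0_star)), 1e-3)
})

test_that("sampling is reproducible under a fixed seed and denoiser", {
  s <- noise_schedule(8, beta_start = 0.02, beta_end = 0.3)
  den <- function(x, t, tau) 0.5 * x
  a <- ddpm_sample(den, s, c(4, 4), seed = 42)
  b <- ddpm_sample(den, s, c(4, 4), seed = 42)
  expect_identical(a, b)
  c2 <- ddpm_sample(den, s, c(4, 4), seed = 43)
  expect_false(identical(a, c2))
  expect_true(all(a >= -1 & a <= 1))
})

test_that("a train step with an oracle denoiser yields zero loss and no update", {
  cfg <- denoiser_config(n = 8, R = 2, depth = 1, base_channels = 4,
                         ch_mult = 1, time_dim = 8, n_tokens = 2, d_k = 4)
  par <- init_denoiser(cfg, seed = 1)
  model <- list(config = cfg, params = par)
  s <- noise_schedule(10, beta_start = 0.02, beta_end = 0.3)
  opt <- cpdm:::adam_init(par)
  x0 <- array(rnorm(4 * 64), dim = c(4, 8, 8))
  tau <- matrix(rnorm(8), 4, 2)

  # oracle: recompute the exact drawn eps from (x_t, t) and the known x0.
  # The stub sees items in batch order, matching the internal draw order.
  batch_x0 <- list(); k <- 0
  oracle <- function(xt, t, tv) {
    k <<- k + 1
    (xt - sqrt(s$alpha_bar[t]) * matrix(x0[k, , ], 8, 8)) /
      sqrt(1 - s$alpha_bar[t])
  }
  set.seed(10)
  st <- train_step(model, x0, tau, s, opt, denoiser_fn = oracle)
  expect_equal(st$loss, 0, tolerance = 1e-20)
  expect_identical(st$model$params, par)

  # determinism of the internal path: identical seed, identical loss
  set.seed(77)
  l1 <- train_step(model, x0, tau, s, opt)$loss
  set.seed(77)
  l2 <- train_step(model, x0, tau, s, opt)$loss
  expect_identical(l1, l2)
})
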