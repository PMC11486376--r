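cfg_small <- denoiser_config(n = 8, R = 3, depth = 2, base_channels = 4,
                             ch_mult = c(1, 2), time_dim = 8, n_tokens = 2,
                             d_k = 4)

test_that("time embedding is deterministic, injective and sinusoidal", {
  e1 <- time_embedding(7, 16)
  expect_identical(e1, time_embedding(7, 16))
  # distinct over a 50-step range
  E <- time_embedding(1:50, 16)
  expect_equal(nrow(unique(round(E, 12))), 50)
  # first pair is (sin(t * w0), cos(t * w0)) with w0 = 1
  expect_equal(e1[1], sin(7))
  expect_equal(e1[2], cos(7))
  expect_error(time_embedding(0, 16), ">= 1")
  expect_error(time_embedding(3, 7), "even")
})

test_that("denoiser output matches input shape and is reproducible", {
  for (n in c(8, 16)) {
    cfg <- denoiser_config(n = n, R = 3, depth = 2, base_channels = 4,
                           ch_mult = c(1, 2), time_dim = 8, n_tokens = 2,
                           d_k = 4)
    par <- init_denoiser(cfg, seed = 2)
    m <- list(config = cfg, params = par)
    x <- matrix(rnorm(n * n), n, n)
    e1 <- denoiser_forward(m, x, 3, c(1, 0, -1))
    expect_equal(dim(e1), c(n, n))
    expect_identical(e1, denoiser_forward(m, x, 3, c(1, 0, -1)))
  }
  # indivisible size fails at build time
  expect_error(denoiser_config(n = 12, R = 2, depth = 3), "divisible")
})

test_that("zero-initialized heads make the untrained model unconditional", {
  par <- init_denoiser(cfg_small, seed = 5)
  m <- list(config = cfg_small, params = par)
  x <- matrix(rnorm(64), 8, 8)
  # final conv is zero-initialized: the raw output is exactly zero
  expect_equal(denoiser_forward(m, x, 2, c(0, 0, 0)), matrix(0, 8, 8))

  # with gate = 0, W_OB = 0 and the auxiliary projection zeroed, the output
  # is invariant to tau even after perturbing interior weights
  par2 <- par
  par2[["out.W"]][] <- rnorm(length(par2[["out.W"]]), sd = 0.1)
  par2[["aux.W"]][] <- 0
  m2 <- list(config = cfg_small, params = par2)
  ea <- denoiser_forward(m2, x, 2, c(5, -5, 2))
  eb <- denoiser_forward(m2, x, 2, c(0, 0, 0))
  expect_equal(ea, eb, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  cfg <- denoiser_config(n = 8, R = 3, depth = 2, base_channels = 4,
                         ch_mult = c(1, 2), time_dim = 8, n_tokens = 2,
                         d_k = 4, aux_cond = TRUE)
  par <- init_denoiser(cfg, seed = 3)
  # perturb the zero-initialized heads so every pathway carries gradient
  par[["out.W"]][] <- rnorm(length(par[["out.W"]]), sd = 0.05)
  par[["attn.W_OB"]][] <- rnorm(length(par[["attn.W_OB"]]), sd = 0.1)
  par[["gate"]] <- 0.1
  model <- list(config = cfg, params = par)
  B <- 2
  x <- array(rnorm(B * 64), dim = c(B, 8, 8))
  t <- c(2L, 6L)
  tau <- matrix(rnorm(B * 3), B, 3)
  eps <- array(rnorm(B * 64), dim = c(B, 8, 8))
  lossfn <- function(m) mean((denoiser_forward(m, x, t, tau) - eps)^2)

  eh <- denoiser_forward(model, x, t, tau, keep_cache = TRUE)
  cache <- attr(eh, "cache")
  dout <- 2 * (unclass(eh) - eps) / length(eps)
  grads <- denoiser_backward(model, cache, dout)

  h <- 1e-5
  for (nm in names(par)) {
    expect_false(is.null(grads[[nm]]), info = paste("missing grad for", nm))
    # every parameter group influences the loss (no dead branch)
    i <- which.max(abs(grads[[nm]]))
    m_p <- model; m_p$params[[nm]][i] <- m_p$params[[nm]][i] + h
    m_m <- model; m_m$params[[nm]][i] <- m_m$params[[nm]][i] - h
    fd <- (lossfn(m_p) - lossfn(m_m)) / (2 * h)
    an <- grads[[nm]][i]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-4)
    expect_gt(abs(an), 0)
  }
})

test_that("checkpoints reproduce outputs bit-identically", {
  env <- get_tiny_fit()
  fit <- env$fit
  fp <- tempfile(fileext = ".rds")
  save_checkpoint(fit, fp)
  back <- load_checkpoint(fp)
  x <- matrix(rnorm(64), 8, 8)
  expect_identical(
    denoiser_forward(list(config = fit$config, params = fit$params), x, 4,
                     c(1, 0, 0, -1)),
    denoiser_forward(list(config = back$config, params = back$params), x, 4,
                     c(1, 0, 0, -1)))
})

test_that("the fitted model exposes the standard S3 surface", {
  env <- get_tiny_fit()
  fit <- env$fit
  expect_s3_class(fit, "cpdm")
  expect_output(print(fit), "diffusion")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.cpdm")
  expect_output(print(sm), "loss")
  expect_type(coef(fit), "list")

  # predict returns eps or the implied clean image, consistently
  x0 <- env$fx$images[, , 1] * 2 - 1
  set.seed(8)
  eps <- matrix(rnorm(64), 8, 8)
  xt <- forward_sample(x0, 5, eps, fit$schedule)
  eh <- predict(fit, xt, 5, condition_scores(env$fx$factors)[1, ])
  x0h <- predict(fit, xt, 5, condition_scores(env$fx$factors)[1, ],
                 type = "x0")
  expect_equal(x0h, predict_x0(xt, eh, 5, fit$schedule))

  r <- residuals(fit, t = 5, seed = 2)
  expect_equal(dim(r), c(8, 8, fit$N))

  # simulate: deterministic given seed, shaped, in range
  g1 <- simulate(fit, 2, seed = 9, tau = matrix(0, 2, 4))
  g2 <- simulate(fit, 2, seed = 9, tau = matrix(0, 2, 4))
  expect_identical(g1, g2)
  expect_equal(dim(g1), c(8, 8, 2))
  expect_true(all(g1 >= -1 & g1 <= 1))
})

test_that("batched simulation matches the single-image ancestral sampler", {
  env <- get_tiny_fit()
  fit <- env$fit
  tau <- matrix(rnorm(8), 2, 4)
  gb <- simulate(fit, 2, seed = 31, tau = tau)
  den <- function(x, t, tv)
    denoiser_forward(list(config = fit$config, params = fit$params), x, t, tv)
  for (i in 1:2) {
    gi <- ddpm_sample(den, fit$schedule, c(8, 8), tau = tau[i, ],
                      seed = cpdm:::derive_seed(31, 100 + i))
    expect_equal(gb[, , i], gi, tolerance = 1e-12)
  }
})
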