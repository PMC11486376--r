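#' Forward diffusion in closed form
#'
#' Jumps directly from a clean image to its noised state at timestep `t`
#' using the closed-form marginal of the forward Markov chain,
#' \deqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1 - \bar\alpha_t}\, \epsilon,}
#' where \eqn{\epsilon} is a standard Gaussian noise field of the same shape
#' as `x0`.
#'
#' @param x0 numeric array (any shape), the clean data in roughly unit scale.
#' @param t integer timestep in `[1, T]` (scalar).
#' @param eps noise field, same shape as `x0`.
#' @param schedule a [noise_schedule()].
#' @return Array of the same shape as `x0`.
#' @seealso [single_step_forward()] for one transition of the chain,
#'   [predict_x0()] for the algebraic inverse.
#' @export
forward_sample <- function(x0, t, eps, schedule) {
  t <- check_t(t, schedule)
  if (!identical(dim_or_len(x0), dim_or_len(eps)))
    stop("`x0` and `eps` must have identical shapes", call. = FALSE)
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' One step of the forward chain
#'
#' A single transition \eqn{q(x_t | x_{t-1})}:
#' \deqn{x_t = \sqrt{1-\beta_t}\, x_{t-1} + \sqrt{\beta_t}\, \epsilon.}
#'
#' @param x_prev state at timestep `t - 1`.
#' @param t integer timestep in `[1, T]`.
#' @param eps standard Gaussian noise field, same shape as `x_prev`.
#' @param schedule a [noise_schedule()].
#' @return Array of the same shape as `x_prev`.
#' @export
single_step_forward <- function(x_prev, t, eps, schedule) {
  t <- check_t(t, schedule)
  b <- schedule$beta[t]
  sqrt(1 - b) * x_prev + sqrt(b) * eps
}

#' Reverse-process posterior mean and variance
#'
#' Mean and variance of the true reverse conditional
#' \eqn{q(x_{t-1} | x_t, x_0)}:
#' \deqn{\tilde\mu_t = \frac{\sqrt{\alpha_t}(1-\bar\alpha_{t-1})}
#'   {1-\bar\alpha_t} x_t + \frac{\sqrt{\bar\alpha_{t-1}}\,\beta_t}
#'   {1-\bar\alpha_t} x_0, \qquad
#'   \tilde\beta_t = \frac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t}\beta_t,}
#' with \eqn{\bar\alpha_0 = 1} so both are defined at `t = 1`
#' (\eqn{\tilde\beta_1 = 0}).
#'
#' @param x_t noised state at timestep `t`.
#' @param x0 clean data.
#' @param t integer timestep in `[1, T]`.
#' @param schedule a [noise_schedule()].
#' @return `posterior_mean()`: array shaped like `x_t`;
#'   `posterior_variance()`: scalar \eqn{\tilde\beta_t}.
#' @export
posterior_mean <- function(x_t, x0, t, schedule) {
  t <- check_t(t, schedule)
  ab <- schedule$alpha_bar[t]
  abp <- schedule$alpha_bar_prev[t]
  a <- schedule$alpha[t]
  (sqrt(a) * (1 - abp) * x_t + sqrt(abp) * schedule$beta[t] * x0) / (1 - ab)
}

#' @rdname posterior_mean
#' @export
posterior_variance <- function(t, schedule) {
  t <- check_t(t, schedule)
  schedule$beta_tilde[t]
}

#' Posterior mean parameterized by the noise
#'
#' The equivalent noise-parameterized form of the reverse posterior mean,
#' obtained by substituting the recovered \eqn{x_0} into [posterior_mean()]:
#' \deqn{\tilde\mu_t = \frac{1}{\sqrt{\alpha_t}}\left(x_t -
#'   \frac{1-\alpha_t}{\sqrt{1-\bar\alpha_t}}\,\epsilon\right).}
#' This is the update the ancestral sampler applies with the predicted noise.
#'
#' @param x_t noised state at timestep `t`.
#' @param eps the noise field (true or predicted).
#' @inheritParams posterior_mean
#' @return Array shaped like `x_t`.
#' @export
posterior_mean_from_eps <- function(x_t, eps, t, schedule) {
  t <- check_t(t, schedule)
  a <- schedule$alpha[t]
  ab <- schedule$alpha_bar[t]
  (x_t - (1 - a) / sqrt(1 - ab) * eps) / sqrt(a)
}

#' Recover the clean image from a noised state
#'
#' Algebraic inverse of the closed-form forward marginal:
#' \deqn{\hat x_0 = (x_t - \sqrt{1-\bar\alpha_t}\,\epsilon)/\sqrt{\bar\alpha_t}.}
#'
#' @inheritParams posterior_mean_from_eps
#' @return Array shaped like `x_t`.
#' @export
predict_x0 <- function(x_t, eps, t, schedule) {
  t <- check_t(t, schedule)
  ab <- schedule$alpha_bar[t]
  (x_t - sqrt(1 - ab) * eps) / sqrt(ab)
}

#' Denoising training loss
#'
#' The simplified diffusion objective: mean squared error between the true
#' and predicted noise fields, \eqn{\|\epsilon - \hat\epsilon\|^2 / n}.
#'
#' @param eps,eps_hat numeric arrays of identical shape.
#' @return Non-negative scalar; exactly 0 iff the fields are equal.
#' @export
diffusion_loss <- function(eps, eps_hat) {
  if (!identical(dim_or_len(eps), dim_or_len(eps_hat)))
    stop("`eps` and `eps_hat` must have identical shapes", call. = FALSE)
  mean((eps - eps_hat)^2)
}

#' Ancestral sampling from a diffusion model
#'
#' Runs the reverse chain: starts from \eqn{x_T \sim N(0, I)} and iterates
#' \deqn{x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\left(x_t -
#'   \frac{1-\alpha_t}{\sqrt{1-\bar\alpha_t}}\,
#'   \epsilon_\theta(x_t, t, \tau)\right) + \sigma_t z,}
#' with \eqn{z \sim N(0, I)} for \eqn{t > 1} and \eqn{z = 0} at \eqn{t = 1}.
#' The result is clipped to `clip` (the training value range).
#'
#' @param denoiser function `(x, t, tau) -> eps_hat` predicting the noise
#'   field; `x` is an `n x n` matrix.
#' @param schedule a [noise_schedule()].
#' @param shape integer vector, the sample dimensions (e.g. `c(16, 16)`).
#' @param tau condition vector passed through to the denoiser (may be NULL
#'   for unconditional models).
#' @param seed integer seed for \eqn{x_T} and the per-step noise `z`; `NULL`
#'   leaves the RNG state alone.
#' @param sigma_scale multiplier on \eqn{\sigma_t}; `0` gives the
#'   deterministic mean trajectory.
#' @param clip length-2 numeric or NULL, range to clip the final sample to.
#' @return Matrix of dimension `shape`, the generated sample in `clip` units.
#' @export
ddpm_sample <- function(denoiser, schedule, shape, tau = NULL, seed = NULL,
                        sigma_scale = 1, clip = c(-1, 1)) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- array(stats::rnorm(prod(shape)), dim = shape)
  for (t in seq(schedule$T, 1L)) {
    eps_hat <- denoiser(x, t, tau)
    if (!all(is.finite(eps_hat)))
      stop(sprintf("non-finite noise prediction at t = %d", t), call. = FALSE)
    x <- posterior_mean_from_eps(x, eps_hat, t, schedule)
    if (t > 1L) {
      z <- array(stats::rnorm(prod(shape)), dim = shape)
      x <- x + sigma_scale * schedule$sigma[t] * z
    }
    if (!all(is.finite(x)))
      stop(sprintf("non-finite sample state at t = %d", t), call. = FALSE)
  }
  if (!is.null(clip)) x[] <- pmin(pmax(x, clip[1]), clip[2])
  x
}

# shape helper: dim() for arrays, length() for bare vectors
dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)
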