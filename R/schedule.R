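#' Construct a diffusion noise schedule
#'
#' Builds the per-timestep scalars of a denoising diffusion process: the
#' variance schedule \eqn{\beta_t}, \eqn{\alpha_t = 1 - \beta_t}, the running
#' product \eqn{\bar\alpha_t = \prod_{i \le t} \alpha_i}, the reverse-process
#' posterior variance
#' \eqn{\tilde\beta_t = \beta_t (1 - \bar\alpha_{t-1}) / (1 - \bar\alpha_t)}
#' (with the boundary convention \eqn{\bar\alpha_0 = 1}, so
#' \eqn{\tilde\beta_1 = 0}), and the ancestral-sampler noise scale
#' \eqn{\sigma_t}.
#'
#' The linear schedule interpolates \eqn{\beta} evenly from `beta_start` to
#' `beta_end`; the cosine schedule derives \eqn{\beta_t} from a squared-cosine
#' decay of \eqn{\bar\alpha_t}, clipped into (0, 0.999]. In both cases
#' \eqn{\beta_1} is the smallest and \eqn{\beta_T} the largest value, and
#' \eqn{\bar\alpha_t} is strictly decreasing.
#'
#' @param T_steps integer, total number of diffusion steps (\eqn{T \ge 1}).
#' @param kind `"linear"` or `"cosine"`.
#' @param beta_start,beta_end endpoints of the linear variance schedule,
#'   `0 < beta_start <= beta_end < 1`. Ignored for `kind = "cosine"`.
#' @param sigma_mode `"beta"` (sampler variance \eqn{\sigma_t^2 = \beta_t},
#'   the default) or `"beta_tilde"` (\eqn{\sigma_t^2 = \tilde\beta_t}).
#'
#' @return An object of class `"noise_schedule"`: a list with elements
#'   `T`, `kind`, `beta`, `alpha`, `alpha_bar`, `beta_tilde`, `sigma`,
#'   `sigma_mode`.
#' @examples
#' s <- noise_schedule(2, beta_start = 0.1, beta_end = 0.2)
#' s$alpha_bar  # 0.9, 0.72
#' @export
noise_schedule <- function(T_steps, kind = c("linear", "cosine"),
                           beta_start = 1e-4, beta_end = 0.02,
                           sigma_mode = c("beta", "beta_tilde")) {
  kind <- match.arg(kind)
  sigma_mode <- match.arg(sigma_mode)
  if (length(T_steps) != 1L || !is.finite(T_steps) || T_steps < 1 ||
      T_steps != round(T_steps))
    stop("`T_steps` must be a single integer >= 1", call. = FALSE)
  T_steps <- as.integer(T_steps)

  if (kind == "linear") {
    if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1))
      stop("need 0 < beta_start <= beta_end < 1", call. = FALSE)
    beta <- if (T_steps == 1L) beta_start else
      seq(beta_start, beta_end, length.out = T_steps)
  } else {
    # squared-cosine alpha_bar decay (offset 0.008), betas derived by ratio
    s <- 0.008
    f <- function(t) cos((t / T_steps + s) / (1 + s) * pi / 2)^2
    ab <- f(0:T_steps) / f(0)
    beta <- pmin(pmax(1 - ab[-1] / ab[-(T_steps + 1L)], 1e-8), 0.999)
  }

  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  alpha_bar_prev <- c(1, alpha_bar[-T_steps])      # alpha_bar_0 := 1
  beta_tilde <- (1 - alpha_bar_prev) / (1 - alpha_bar) * beta
  sigma <- if (sigma_mode == "beta") sqrt(beta) else sqrt(beta_tilde)

  structure(
    list(T = T_steps, kind = kind, beta = beta, alpha = alpha,
         alpha_bar = alpha_bar, alpha_bar_prev = alpha_bar_prev,
         beta_tilde = beta_tilde, sigma = sigma, sigma_mode = sigma_mode),
    class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("Noise schedule (%s), T = %d, sigma^2 = %s\n", x$kind, x$T,
              if (x$sigma_mode == "beta") "beta_t" else "beta_tilde_t"))
  cat(sprintf("  beta in [%.3g, %.3g]; terminal alpha_bar = %.4g\n",
              x$beta[1], x$beta[x$T], x$alpha_bar[x$T]))
  invisible(x)
}

check_t <- function(t, s) {
  if (any(t < 1 | t > s$T | t != round(t)))
    stop(sprintf("timestep out of range [1, %d]", s$T), call. = FALSE)
  as.integer(t)
}
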