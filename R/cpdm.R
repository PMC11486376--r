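#' One training step of the diffusion objective
#'
#' Implements one stochastic-gradient step of the simplified denoising
#' objective: per batch item draw \eqn{t \sim U\{1..T\}} and
#' \eqn{\epsilon \sim N(0, I)}, form \eqn{x_t} by the closed-form forward
#' marginal, predict the noise with the conditioned U-Net, evaluate the mean
#' squared error against the drawn noise, and apply one Adam update.
#'
#' @param model list with `config` and `params`.
#' @param x0 `(B, n, n)` array of clean images in `[-1, 1]`.
#' @param tau `B x R` condition matrix (or NULL).
#' @param schedule a [noise_schedule()].
#' @param opt Adam state from `adam_init` (internal); pass the one stored in
#'   a fit or create with [cpdm()].
#' @param denoiser_fn optional external denoiser `(x, t, tau) -> eps_hat`
#'   used instead of the model (e.g. a test oracle); no parameter update is
#'   applied in that case.
#' @return List with `loss`, updated `model`, updated `opt`.
#' @export
train_step <- function(model, x0, tau, schedule, opt, denoiser_fn = NULL) {
  B <- dim(x0)[1]; n <- dim(x0)[2]
  t <- sample.int(schedule$T, B, replace = TRUE)
  eps <- array(stats::rnorm(length(x0)), dim = dim(x0))
  ab <- schedule$alpha_bar[t]
  xt <- sqrt(ab) * x0 + sqrt(1 - ab) * eps   # recycling over (b) fastest dim

  if (!is.null(denoiser_fn)) {
    eps_hat <- array(0, dim = dim(x0))
    for (b in seq_len(B))
      eps_hat[b, , ] <- denoiser_fn(matrix(xt[b, , ], n, n), t[b],
                                    if (is.null(tau)) NULL else tau[b, ])
    loss <- diffusion_loss(eps, eps_hat)
    return(list(loss = loss, model = model, opt = opt))
  }

  eps_hat <- denoiser_forward(model, xt, t, tau, keep_cache = TRUE)
  cache <- attr(eps_hat, "cache")
  attr(eps_hat, "cache") <- NULL
  loss <- mean((eps_hat - eps)^2)
  if (!is.finite(loss))
    stop("non-finite training loss; check input scaling and learning rate",
         call. = FALSE)
  dout <- 2 * (eps_hat - eps) / length(eps)
  grads <- denoiser_backward(model, cache, dout)
  st <- adam_step(model$params, grads, opt)
  model$params <- st$params
  list(loss = loss, model = model, opt = st$opt)
}

# deterministic fan-out of one root seed into per-purpose streams
derive_seed <- function(seed, purpose) {
  (as.numeric(seed) * 48271 + purpose * 16807) %% 2147483563 + 1
}

#' Fit a conditional probabilistic diffusion model
#'
#' Trains a denoising diffusion model that generates square grayscale images
#' conditioned on per-patient latent factor vectors (e.g. scores from an
#' omics tensor factorization, see [cp_als()] and [condition_scores()]).
#' The forward process corrupts each image with scheduled Gaussian noise;
#' the fitted U-Net learns to predict the injected noise from the noised
#' image, the timestep and the condition, minimizing
#' \eqn{E\|\epsilon - \epsilon_\theta(x_t, t, \tau)\|^2} by Adam.
#'
#' @param x training images: an `n x n x N` array or a list of `n x n`
#'   matrices, values in `[-1, 1]` (see [normalize_range()]).
#' @param tau `N x R` matrix of condition vectors, rows aligned with `x`;
#'   NULL fits an unconditional model.
#' @param schedule a [noise_schedule()]; default is the 1000-step linear
#'   schedule with `beta` from 1e-4 to 0.02.
#' @param epochs number of passes over the data.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param config a [denoiser_config()]; defaults to a small architecture
#'   sized for the data (`depth` 2 at n <= 32, else 3).
#' @param seed root seed; parameter init and minibatch/noise draws use
#'   deterministic sub-streams derived from it.
#' @param verbose print per-epoch loss.
#' @return An object of class `"cpdm"`: list with `config`, `params`,
#'   `schedule`, `loss_history` (per epoch), `n`, `R`, `N`, `seed`, the
#'   stored training data (`x`, `tau`), Adam state `opt`, and `call`.
#' @seealso [simulate.cpdm()] to generate images, [predict.cpdm()] for noise
#'   or clean-image prediction, [evaluate_images()] for metrics.
#' @export
cpdm <- function(x, tau = NULL, schedule = NULL, epochs = 30,
                 batch_size = 16, lr = 2e-3, config = NULL, seed = 1,
                 verbose = FALSE) {
  if (is.list(x)) {
    n <- nrow(x[[1]])
    x <- array(unlist(x), dim = c(n, n, length(x)))
  }
  if (length(dim(x)) != 3L || dim(x)[1] != dim(x)[2])
    stop("`x` must be an n x n x N array or list of square matrices",
         call. = FALSE)
  n <- dim(x)[1]; N <- dim(x)[3]
  if (!is.null(tau)) {
    tau <- as.matrix(tau)
    if (nrow(tau) != N)
      stop("`tau` must have one row per training image", call. = FALSE)
  }
  R <- if (is.null(tau)) 1L else ncol(tau)
  if (is.null(schedule)) schedule <- noise_schedule(1000)
  if (is.null(config))
    config <- denoiser_config(n = n, R = R, depth = if (n <= 32) 2L else 3L)
  if (config$n != n || config$R != R)
    stop("`config` does not match the data dimensions", call. = FALSE)

  params <- init_denoiser(config, seed = derive_seed(seed, 1))
  model <- list(config = config, params = params)
  opt <- adam_init(params, lr = lr)

  # batch-major copy: (N, n, n) so row b of a batch is one image
  xb <- aperm(x, c(3, 1, 2))
  set.seed(derive_seed(seed, 2))
  loss_hist <- numeric(epochs)
  step_losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(N)
    ep_losses <- numeric(0)
    for (start in seq(1, N, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, N)]
      st <- train_step(model,
                       xb[idx, , , drop = FALSE],
                       if (is.null(tau)) NULL else tau[idx, , drop = FALSE],
                       schedule, opt)
      model <- st$model; opt <- st$opt
      ep_losses <- c(ep_losses, st$loss)
    }
    loss_hist[ep] <- mean(ep_losses)
    step_losses <- c(step_losses, ep_losses)
    if (verbose)
      message(sprintf("epoch %3d/%d  loss %.4f", ep, epochs, loss_hist[ep]))
  }

  structure(
    list(config = config, params = model$params, schedule = schedule,
         loss_history = loss_hist, step_losses = step_losses,
         n = n, R = R, N = N, seed = seed, x = x, tau = tau, opt = opt,
         call = match.call()),
    class = "cpdm")
}

#' @export
print.cpdm <- function(x, ...) {
  cat("Conditional probabilistic diffusion model\n")
  cat(sprintf("  images: %d of %dx%d;  condition dim R = %d\n",
              x$N, x$n, x$n, x$R))
  cat(sprintf("  schedule: %s, T = %d;  denoiser: depth %d, channels %s\n",
              x$schedule$kind, x$schedule$T, x$config$depth,
              paste(x$config$channels, collapse = "/")))
  L <- length(x$loss_history)
  cat(sprintf("  training: %d epochs, loss %.4f -> %.4f\n",
              L, x$loss_history[1], x$loss_history[L]))
  invisible(x)
}

#' @export
summary.cpdm <- function(object, ...) {
  npar <- sum(vapply(object$params, length, 0L))
  out <- list(n = object$n, R = object$R, N = object$N,
              T = object$schedule$T, epochs = length(object$loss_history),
              n_params = npar,
              loss_first = object$loss_history[1],
              loss_last = object$loss_history[length(object$loss_history)],
              loss_reduction = 1 - object$loss_history[length(object$loss_history)] /
                object$loss_history[1],
              gate = object$params[["gate"]])
  class(out) <- "summary.cpdm"
  out
}

#' @export
print.summary.cpdm <- function(x, ...) {
  cat("CPDM fit summary\n")
  cat(sprintf("  data: %d images (%dx%d), condition dim %d\n", x$N, x$n, x$n, x$R))
  cat(sprintf("  denoiser parameters: %d;  diffusion steps T = %d\n",
              x$n_params, x$T))
  cat(sprintf("  loss: %.4f (epoch 1) -> %.4f (epoch %d), reduction %.1f%%\n",
              x$loss_first, x$loss_last, x$epochs, 100 * x$loss_reduction))
  cat(sprintf("  fusion gate: %.4f\n", x$gate))
  invisible(x)
}

#' @export
coef.cpdm <- function(object, ...) object$params

#' Predict noise or clean image from a noised state
#'
#' @param object a fitted [cpdm()].
#' @param x noised image (`n x n` matrix or `(B, n, n)` array).
#' @param t integer timestep.
#' @param tau condition vector/matrix.
#' @param type `"eps"` for the predicted noise field, `"x0"` for the
#'   implied clean image via the closed-form inversion.
#' @param ... unused.
#' @return Array shaped like `x`.
#' @export
predict.cpdm <- function(object, x, t, tau = NULL, type = c("eps", "x0"), ...) {
  type <- match.arg(type)
  eps_hat <- denoiser_forward(list(config = object$config,
                                   params = object$params), x, t, tau)
  if (type == "eps") eps_hat
  else predict_x0(x, eps_hat, t, object$schedule)
}

#' Generate images from a fitted diffusion model
#'
#' Runs the ancestral sampler once per requested draw. Draw `i` uses a
#' sub-seed derived from `seed`, and all draws are advanced through the
#' reverse chain together (one batched denoiser call per timestep), which
#' produces bit-identical output to running [ddpm_sample()] separately per
#' image with the same sub-seeds.
#'
#' @param object a fitted [cpdm()].
#' @param nsim number of images.
#' @param seed integer root seed; draw `i` uses a derived sub-seed so the
#'   set is reproducible and draws are independent.
#' @param tau a single condition vector (recycled) or an `nsim x R` matrix.
#' @param sigma_scale multiplier on the sampler noise scale.
#' @param output `"training"` for `[-1, 1]` values, `"unit"` to map onto
#'   `[0, 1]` for storage and metrics.
#' @param ... unused.
#' @return `n x n x nsim` array.
#' @export
simulate.cpdm <- function(object, nsim = 1, seed = NULL, tau = NULL,
                          sigma_scale = 1, output = c("training", "unit"),
                          ...) {
  output <- match.arg(output)
  if (is.null(seed)) seed <- object$seed
  if (!is.null(tau) && is.matrix(tau) && nrow(tau) != nsim)
    stop("`tau` matrix must have `nsim` rows", call. = FALSE)
  model <- list(config = object$config, params = object$params)
  n <- object$n
  sched <- object$schedule
  Tn <- sched$T
  taumat <- if (is.null(tau)) NULL
            else if (is.matrix(tau)) tau
            else matrix(tau, nsim, length(tau), byrow = TRUE)

  # pre-draw each item's noise stream in ddpm_sample order: x_T, z_T .. z_2
  X <- array(0, dim = c(nsim, n, n))
  Z <- if (Tn > 1) array(0, dim = c(nsim, n, n, Tn - 1L))
  for (i in seq_len(nsim)) {
    set.seed(as.integer(derive_seed(seed, 100 + i)))
    X[i, , ] <- matrix(stats::rnorm(n * n), n, n)
    for (t in seq(Tn, 2L))
      Z[i, , , t - 1L] <- matrix(stats::rnorm(n * n), n, n)
  }

  for (t in seq(Tn, 1L)) {
    eps_hat <- denoiser_forward(model, X, t, taumat)
    if (!all(is.finite(eps_hat)))
      stop(sprintf("non-finite noise prediction at t = %d", t), call. = FALSE)
    X <- posterior_mean_from_eps(X, eps_hat, t, sched)
    if (t > 1L)
      X <- X + sigma_scale * sched$sigma[t] * Z[, , , t - 1L]
  }
  X[] <- pmin(pmax(X, -1), 1)
  out <- aperm(X, c(2, 3, 1))
  if (output == "unit") out <- (out + 1) / 2
  out
}

#' Noise-prediction residuals on the training data
#'
#' For each stored training image, draws a seeded noise field at timestep
#' `t`, forms the noised state, and returns the residual
#' \eqn{\epsilon - \hat\epsilon}. Residual magnitudes near zero indicate
#' the denoiser has captured the conditional noise structure at that
#' timestep.
#'
#' @param object a fitted [cpdm()].
#' @param t timestep (default: `T %/% 2`).
#' @param seed seed for the residual noise draws.
#' @param ... unused.
#' @return `n x n x N` array of residual fields.
#' @export
residuals.cpdm <- function(object, t = NULL, seed = 1, ...) {
  if (is.null(t)) t <- max(1L, object$schedule$T %/% 2L)
  set.seed(as.integer(seed))
  N <- object$N
  out <- array(0, dim = c(object$n, object$n, N))
  model <- list(config = object$config, params = object$params)
  for (i in seq_len(N)) {
    x0 <- object$x[, , i]
    eps <- matrix(stats::rnorm(length(x0)), object$n, object$n)
    xt <- forward_sample(x0, t, eps, object$schedule)
    tau_i <- if (is.null(object$tau)) NULL else object$tau[i, ]
    out[, , i] <- eps - denoiser_forward(model, xt, t, tau_i)
  }
  out
}

#' @export
plot.cpdm <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "CPDM training loss", ...)
  invisible(x)
}
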