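#' Embed a set of images for distributional comparison
#'
#' Maps each image to a feature vector and returns the sufficient statistics
#' for the Fréchet distance: the `N x D` feature matrix, its mean and its
#' covariance (denominator `N - 1`). Backends: `"pixels"` (flattened pixel
#' values — download-free and exact for the metric identities),
#' `"pca"` (flattened pixels projected onto the leading `pca_dim`
#' principal components of the set).
#'
#' An inception-style pretrained extractor can be plugged in through
#' `extractor_fn`; grayscale images would be channel-triplicated by such a
#' backend. None is bundled, since it requires external weights.
#'
#' @param images `n x n x N` array or list of equally sized matrices.
#' @param extractor `"pixels"` or `"pca"`, or any label when `extractor_fn`
#'   is supplied.
#' @param pca_dim dimensionality for the PCA backend (default
#'   `min(N - 1, 8)`).
#' @param extractor_fn optional function mapping an image matrix to a
#'   feature vector.
#' @return Object of class `"embedding_set"`: list with `features`
#'   (`N x D`), `mu`, `Sigma`, `extractor_id`, `N`, `D`.
#' @export
embed_images <- function(images, extractor = c("pixels", "pca"),
                         pca_dim = NULL, extractor_fn = NULL) {
  if (is.list(images)) {
    n <- nrow(images[[1]])
    images <- array(unlist(images), dim = c(n, n, length(images)))
  }
  N <- dim(images)[3]
  if (N < 2) stop("need at least 2 images for covariance", call. = FALSE)
  if (!is.null(extractor_fn)) {
    extractor_id <- if (is.character(extractor)) extractor[1] else "custom"
    feats <- t(vapply(seq_len(N),
                      function(i) as.numeric(extractor_fn(images[, , i])),
                      numeric(length(extractor_fn(images[, , 1])))))
  } else {
    extractor_id <- match.arg(extractor)
    feats <- t(apply(images, 3, as.numeric))
    if (extractor_id == "pca") {
      if (is.null(pca_dim)) pca_dim <- min(N - 1, 8)
      ctr <- scale(feats, center = TRUE, scale = FALSE)
      sv <- svd(ctr, nu = 0, nv = pca_dim)
      feats <- ctr %*% sv$v
      extractor_id <- sprintf("pca%d", pca_dim)
    }
  }
  structure(list(features = feats, mu = colMeans(feats),
                 Sigma = stats::cov(feats), extractor_id = extractor_id,
                 N = N, D = ncol(feats)),
            class = "embedding_set")
}

# symmetric PSD matrix square root by eigendecomposition, with small
# negative eigenvalues clipped at 0 (tolerance `tol`)
sym_sqrtm <- function(S, tol = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  lam[lam < 0 & lam > -tol * max(abs(lam), 1)] <- 0
  lam[lam < 0] <- 0
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' Fréchet distance between two embedding sets
#'
#' The Fréchet distance between the Gaussian fits to two embedding sets:
#' \deqn{\|\mu_1-\mu_2\|^2 + \mathrm{Tr}\left(\Sigma_1 + \Sigma_2 -
#'   2(\Sigma_1\Sigma_2)^{1/2}\right).}
#' The cross term is computed through the symmetric stabilization
#' \eqn{\mathrm{Tr}(\Sigma_1\Sigma_2)^{1/2} =
#'   \mathrm{Tr}(\Sigma_1^{1/2}\Sigma_2\Sigma_1^{1/2})^{1/2}} with tiny
#' negative eigenvalues clipped at zero. A value of 0.00 means the two sets
#' have identical embedding statistics.
#'
#' @param e1,e2 [embed_images()] results with matching dimension and
#'   extractor.
#' @return Non-negative scalar (within numerical tolerance).
#' @export
fid <- function(e1, e2) {
  if (!identical(e1$extractor_id, e2$extractor_id))
    stop("embedding sets come from different extractors", call. = FALSE)
  if (e1$D != e2$D) stop("embedding dimensions differ", call. = FALSE)
  d <- e1$mu - e2$mu
  s1h <- sym_sqrtm(e1$Sigma)
  cross <- sym_sqrtm(s1h %*% e2$Sigma %*% s1h)
  sum(d^2) + sum(diag(e1$Sigma)) + sum(diag(e2$Sigma)) - 2 * sum(diag(cross))
}

#' Batch standard deviation of the Fréchet distance
#'
#' Stability companion to [fid()]: the sample standard deviation of the
#' per-batch Fréchet distances between a fixed real embedding set and each
#' generated batch. Lower values mean more consistent generation quality
#' across batches.
#'
#' @param real an [embed_images()] result for the real set.
#' @param gen_batches list (length >= 2) of [embed_images()] results.
#' @return Non-negative scalar; also carries attribute `"fids"` with the
#'   per-batch distances.
#' @export
fid_std <- function(real, gen_batches) {
  if (length(gen_batches) < 2)
    stop("need at least 2 generated batches", call. = FALSE)
  f <- vapply(gen_batches, function(g) fid(real, g), 0)
  structure(stats::sd(f), fids = f)
}

#' Mean squared error between two images
#'
#' \eqn{(1/n)\sum_i (I_i - \hat I_i)^2} over all pixels.
#'
#' @param I,I_hat numeric arrays of identical shape.
#' @return Non-negative scalar; 0 iff the images are identical.
#' @export
img_mse <- function(I, I_hat) {
  if (!identical(dim_or_len(I), dim_or_len(I_hat)))
    stop("images must have identical shapes", call. = FALSE)
  mean((I - I_hat)^2)
}

ssim_formula <- function(mu1, mu2, v1, v2, cv, c1, c2) {
  ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
}

#' Structural similarity index
#'
#' SSIM between two images:
#' \deqn{\frac{(2\mu_I\mu_{\hat I} + c_1)(2\sigma_{I\hat I} + c_2)}
#'   {(\mu_I^2 + \mu_{\hat I}^2 + c_1)(\sigma_I^2 + \sigma_{\hat I}^2 + c_2)},}
#' with \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2} for dynamic range `L`.
#' `mode = "global"` uses whole-image moments; `mode = "windowed"` averages
#' the index over all sliding `window x window` patches (moments with
#' denominator `N`). The result lies in `[-1, 1]`, with 1 for identical
#' images.
#'
#' @param I,I_hat numeric matrices of identical shape.
#' @param L dynamic range of the data (1 for unit-scaled images).
#' @param k1,k2 stability constants (defaults 0.01, 0.03).
#' @param mode `"global"` or `"windowed"`.
#' @param window window side for `"windowed"` mode (default 7).
#' @return Scalar in `[-1, 1]`.
#' @export
img_ssim <- function(I, I_hat, L = 1, k1 = 0.01, k2 = 0.03,
                     mode = c("global", "windowed"), window = 7) {
  mode <- match.arg(mode)
  if (!identical(dim_or_len(I), dim_or_len(I_hat)))
    stop("images must have identical shapes", call. = FALSE)
  if (L <= 0) stop("`L` must be positive", call. = FALSE)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  if (mode == "global") {
    n <- length(I)
    mu1 <- mean(I); mu2 <- mean(I_hat)
    v1 <- sum((I - mu1)^2) / n
    v2 <- sum((I_hat - mu2)^2) / n
    cv <- sum((I - mu1) * (I_hat - mu2)) / n
    return(ssim_formula(mu1, mu2, v1, v2, cv, c1, c2))
  }
  if (window > min(dim(I)))
    stop("window larger than the image", call. = FALSE)
  # sliding-window moments by offset accumulation over valid windows
  H <- nrow(I); W <- ncol(I); w <- window
  Ho <- H - w + 1L; Wo <- W - w + 1L
  s1 <- s2 <- s11 <- s22 <- s12 <- matrix(0, Ho, Wo)
  for (dh in 0:(w - 1L)) for (dw in 0:(w - 1L)) {
    a <- I[(1L + dh):(Ho + dh), (1L + dw):(Wo + dw)]
    b <- I_hat[(1L + dh):(Ho + dh), (1L + dw):(Wo + dw)]
    s1 <- s1 + a; s2 <- s2 + b
    s11 <- s11 + a * a; s22 <- s22 + b * b; s12 <- s12 + a * b
  }
  nw <- w * w
  mu1 <- s1 / nw; mu2 <- s2 / nw
  v1 <- s11 / nw - mu1^2
  v2 <- s22 / nw - mu2^2
  cv <- s12 / nw - mu1 * mu2
  mean(ssim_formula(mu1, mu2, v1, v2, cv, c1, c2))
}

#' Evaluate generated images against a real set
#'
#' Computes the full metric report: Fréchet distance of the pooled generated
#' set against the real set, its batch standard deviation, and mean
#' per-pair MSE and SSIM (images are compared pairwise in order when the
#' sets have equal size, otherwise against the real mean image).
#'
#' @param real,generated `n x n x N` arrays (or lists of matrices) on a
#'   common value range (use `[0, 1]`; see [normalize_range()]).
#' @param extractor embedding backend for [embed_images()].
#' @param n_batches number of equal batches for the FID spread (default 2;
#'   more gives a steadier estimate when the generated set is large).
#' @param ssim_mode `"global"` or `"windowed"`.
#' @param L dynamic range for SSIM (default 1).
#' @return Object of class `"metrics_report"`: list with `fid`, `fid_std`,
#'   `mse`, `ssim` and the settings used.
#' @export
evaluate_images <- function(real, generated, extractor = "pixels",
                            n_batches = 2, ssim_mode = "global", L = 1) {
  as_stack <- function(im) {
    if (is.list(im)) array(unlist(im), dim = c(nrow(im[[1]]), ncol(im[[1]]),
                                               length(im)))
    else im
  }
  real <- as_stack(real); generated <- as_stack(generated)
  e_real <- embed_images(real, extractor)
  e_gen <- embed_images(generated, extractor)
  fid_val <- fid(e_real, e_gen)

  Ng <- dim(generated)[3]
  fstd <- NA_real_
  if (Ng >= 2 * n_batches && n_batches >= 2) {
    cut_id <- rep(seq_len(n_batches), length.out = Ng)
    batches <- lapply(seq_len(n_batches), function(k)
      embed_images(generated[, , cut_id == k, drop = FALSE], extractor))
    fstd <- as.numeric(fid_std(e_real, batches))
  }

  Nr <- dim(real)[3]
  if (Nr == Ng) {
    mse_v <- vapply(seq_len(Ng), function(i)
      img_mse(real[, , i], generated[, , i]), 0)
    ssim_v <- vapply(seq_len(Ng), function(i)
      img_ssim(real[, , i], generated[, , i], L = L, mode = ssim_mode), 0)
  } else {
    ref <- apply(real, c(1, 2), mean)
    mse_v <- vapply(seq_len(Ng), function(i) img_mse(ref, generated[, , i]), 0)
    ssim_v <- vapply(seq_len(Ng), function(i)
      img_ssim(ref, generated[, , i], L = L, mode = ssim_mode), 0)
  }

  structure(list(fid = fid_val, fid_std = fstd, mse = mean(mse_v),
                 ssim = mean(ssim_v),
                 settings = list(extractor = extractor, ssim_mode = ssim_mode,
                                 L = L, n_real = Nr, n_gen = Ng,
                                 n_batches = n_batches)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Generative image metrics\n")
  cat(sprintf("  FID     %.4f   (extractor: %s)\n", x$fid,
              x$settings$extractor))
  if (is.finite(x$fid_std)) cat(sprintf("  FID-STD %.4f\n", x$fid_std))
  cat(sprintf("  MSE     %.4f\n", x$mse))
  cat(sprintf("  SSIM    %.4f   (%s)\n", x$ssim, x$settings$ssim_mode))
  invisible(x)
}
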