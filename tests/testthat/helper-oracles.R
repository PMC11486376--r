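# Independent brute-force oracles used to freeze expected values.

# projection by exhaustive ray enumeration
oracle_project <- function(vol, axis, mode) {
  d <- dim(vol)
  keep <- setdiff(1:3, axis)
  out <- matrix(0, d[keep[1]], d[keep[2]])
  f <- if (mode == "max") max else mean
  for (i in seq_len(d[keep[1]])) for (j in seq_len(d[keep[2]])) {
    ray <- vapply(seq_len(d[axis]), function(k) {
      idx <- integer(3)
      idx[axis] <- k; idx[keep[1]] <- i; idx[keep[2]] <- j
      vol[idx[1], idx[2], idx[3]]
    }, 0)
    out[i, j] <- f(ray)
  }
  out
}

# nearest-neighbour resize by enumerating all source-center distances;
# exact distance ties resolve to the higher index (the declared convention)
oracle_resize <- function(img, size) {
  nearest <- function(center, src) {
    d <- abs(seq_len(src) - 0.5 - center)
    max(which(d <= min(d) + 1e-12))
  }
  src_h <- nrow(img); src_w <- ncol(img)
  out <- matrix(0, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    ci <- (i - 0.5) * src_h / size
    cj <- (j - 0.5) * src_w / size
    out[i, j] <- img[nearest(ci, src_h), nearest(cj, src_w)]
  }
  out
}

# exhaustive search for the maximal all-nonzero submatrix under iterated
# row/column deletion (fixed point is unique for this rule)
oracle_drop_zero <- function(m) {
  repeat {
    r <- apply(m != 0, 1, any)
    c <- apply(m != 0, 2, any)
    if (all(r) && all(c)) return(m)
    m <- m[r, c, drop = FALSE]
  }
}

# direct-sort CV oracle
oracle_cv_top <- function(m, fraction) {
  cv <- vapply(seq_len(ncol(m)), function(j) {
    mu <- mean(m[, j]); s <- stats::sd(m[, j])
    if (mu == 0) Inf else s / abs(mu)
  }, 0)
  ids <- colnames(m)
  ids[order(-cv, ids)][seq_len(ceiling(fraction * ncol(m)))]
}

# best factor-congruence over all column permutations and signs
oracle_congruence <- function(A_hat, A_true) {
  normalize <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")
  A_hat <- normalize(A_hat); A_true <- normalize(A_true)
  R <- ncol(A_true)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -Inf
  for (p in perms(seq_len(R))) {
    cong <- mean(abs(colSums(A_hat[, p, drop = FALSE] * A_true)))
    best <- max(best, cong)
  }
  best
}

# SSIM oracle materializing every window
oracle_ssim_windowed <- function(I, J, L = 1, k1 = 0.01, k2 = 0.03, w = 7) {
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  H <- nrow(I); W <- ncol(I)
  vals <- c()
  for (i in seq_len(H - w + 1)) for (j in seq_len(W - w + 1)) {
    a <- as.vector(I[i:(i + w - 1), j:(j + w - 1)])
    b <- as.vector(J[i:(i + w - 1), j:(j + w - 1)])
    n <- w * w
    mu1 <- mean(a); mu2 <- mean(b)
    v1 <- sum((a - mu1)^2) / n; v2 <- sum((b - mu2)^2) / n
    cv <- sum((a - mu1) * (b - mu2)) / n
    vals <- c(vals, ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
                ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2)))
  }
  mean(vals)
}

# rank-R tensor from known factor matrices
outer3 <- function(A, B, C) {
  d <- c(nrow(A), nrow(B), nrow(C))
  X <- array(0, dim = d)
  for (r in seq_len(ncol(A)))
    X <- X + outer(outer(A[, r], B[, r]), C[, r])
  X
}

# a small fitted model shared by tests that need one (built lazily once)
tiny_fit_env <- new.env()
get_tiny_fit <- function() {
  if (is.null(tiny_fit_env$fit)) {
    spec <- fixture_spec(n_patients = 16, size = 8, R = 4, seed = 3)
    fx <- make_fixtures(spec)
    cfg <- denoiser_config(n = 8, R = 4, depth = 2, base_channels = 4,
                           ch_mult = c(1, 2), time_dim = 8, n_tokens = 2,
                           d_k = 4)
    tiny_fit_env$fit <- cpdm(fx$images * 2 - 1, condition_scores(fx$factors),
                             schedule = noise_schedule(10, beta_start = 0.02,
                                                       beta_end = 0.3),
                             epochs = 2, batch_size = 8, config = cfg,
                             seed = 5)
    tiny_fit_env$fx <- fx
  }
  tiny_fit_env
}
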