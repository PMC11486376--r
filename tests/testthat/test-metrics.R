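make_stack <- function(n, N, seed = 1) {
  set.seed(seed)
  array(runif(n * n * N), dim = c(n, n, N))
}

test_that("pixel embeddings carry exact sufficient statistics", {
  imgs <- make_stack(4, 6, 2)
  e <- embed_images(imgs, "pixels")
  expect_equal(e$D, 16)
  # direct summation oracle for the mean
  brute_mu <- colMeans(t(apply(imgs, 3, as.numeric)))
  expect_equal(e$mu, brute_mu)
  # N-1 denominator
  expect_equal(e$Sigma, cov(e$features))

  # identical images -> zero covariance
  same <- array(rep(imgs[, , 1], 3), dim = c(4, 4, 3))
  expect_true(all(embed_images(same)$Sigma == 0))
  expect_error(embed_images(imgs[, , 1, drop = FALSE]), "2 images")
})

test_that("pca embedding matches the eigendecomposition of the pixel covariance", {
  imgs <- make_stack(4, 10, 3)
  e <- embed_images(imgs, "pca", pca_dim = 3)
  feats <- t(apply(imgs, 3, as.numeric))
  ctr <- scale(feats, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(ctr), symmetric = TRUE)
  # retained variance along each component matches the eigenvalues
  expect_equal(colSums(e$features^2), ev$values[1:3], tolerance = 1e-8)
})

test_that("Frechet distance satisfies its identities", {
  imgs <- make_stack(4, 8, 5)
  e <- embed_images(imgs)
  expect_equal(fid(e, e), 0, tolerance = 1e-6)

  # equal covariances, mean shift d -> exactly ||d||^2
  e2 <- e
  d <- rnorm(e$D)
  e2$mu <- e$mu + d
  expect_equal(fid(e, e2), sum(d^2), tolerance = 1e-8)

  # symmetry on different random sets
  f <- embed_images(make_stack(4, 8, 6))
  expect_equal(fid(e, f), fid(f, e), tolerance = 1e-8)
  expect_gt(fid(e, f), 0)

  # monotone in the mean shift at equal covariance
  e3 <- e; e3$mu <- e$mu + 2 * d
  expect_gt(fid(e, e3), fid(e, e2))

  f_bad <- embed_images(make_stack(4, 8, 6), "pca", pca_dim = 4)
  expect_error(fid(e, f_bad), "extractor")
})

test_that("Frechet distance agrees with an independent matrix square root", {
  skip_if_not_installed("pracma")
  # hand-set 2D Gaussians
  mk <- function(mu, Sigma) {
    structure(list(features = NULL, mu = mu, Sigma = Sigma,
                   extractor_id = "pixels", N = 10, D = 2),
              class = "embedding_set")
  }
  S1 <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  S2 <- matrix(c(1, -0.2, -0.2, 0.5), 2, 2)
  mu1 <- c(0, 1); mu2 <- c(2, -1)
  got <- fid(mk(mu1, S1), mk(mu2, S2))
  cross <- pracma::sqrtm(S1 %*% S2)$B           # independent implementation
  want <- sum((mu1 - mu2)^2) +
    sum(diag(S1 + S2 - 2 * cross))
  expect_equal(got, Re(want), tolerance = 1e-8)
})

test_that("FID spread over batches is a plain standard deviation", {
  real <- embed_images(make_stack(3, 10, 7))
  b1 <- embed_images(make_stack(3, 5, 8))
  b2 <- embed_images(make_stack(3, 5, 9))
  # identical batches -> 0
  expect_equal(as.numeric(fid_std(real, list(b1, b1, b1))), 0)
  # two batches: |f1 - f2| / sqrt(2)
  f1 <- fid(real, b1); f2 <- fid(real, b2)
  expect_equal(as.numeric(fid_std(real, list(b1, b2))),
               abs(f1 - f2) / sqrt(2))
  # five batches: brute-force sd
  bs <- lapply(10:14, function(s) embed_images(make_stack(3, 5, s)))
  fs <- vapply(bs, function(b) fid(real, b), 0)
  expect_equal(as.numeric(fid_std(real, bs)), sd(fs))
  expect_error(fid_std(real, list(b1)), "2 ")
})

test_that("MSE is the mean squared pixel difference", {
  I <- matrix(runif(16), 4, 4)
  expect_equal(img_mse(I, I), 0)
  expect_equal(img_mse(c(0, 1), c(1, 1)), 0.5)
  J <- matrix(runif(16), 4, 4)
  brute <- 0
  for (i in 1:16) brute <- brute + (I[i] - J[i])^2
  expect_equal(img_mse(I, J), brute / 16)
  expect_error(img_mse(I, matrix(0, 2, 2)), "shape")
})

test_that("SSIM satisfies its identities and closed forms", {
  set.seed(20)
  I <- matrix(runif(64), 8, 8)
  expect_equal(img_ssim(I, I), 1)
  expect_equal(img_ssim(I, I, mode = "windowed"), 1)

  # constant images a = 0, b = 1 at L = 1: variance terms cancel via c2
  a <- matrix(0, 4, 4); b <- matrix(1, 4, 4)
  c1 <- 1e-4
  expect_equal(img_ssim(a, b), c1 / (1 + c1), tolerance = 1e-12)
  expect_equal(img_ssim(a, b), 9.999e-5, tolerance = 1e-7)

  # bounded in [-1, 1]; anti-correlated images go negative
  J <- 1 - I
  v <- img_ssim(I - mean(I) + 0.5, J - mean(J) + 0.5)
  expect_true(v >= -1 && v <= 1)

  expect_error(img_ssim(I, I, L = 0), "L")
  expect_error(img_ssim(I, matrix(0, 2, 2)), "shape")
})

test_that("windowed SSIM matches the exhaustive-window oracle", {
  set.seed(22)
  I <- matrix(runif(64), 8, 8)
  J <- pmin(pmax(I + rnorm(64, sd = 0.1), 0), 1)
  expect_equal(img_ssim(I, J, mode = "windowed", window = 7),
               oracle_ssim_windowed(I, J, w = 7), tolerance = 1e-10)
  expect_equal(img_ssim(I, J, mode = "windowed", window = 3),
               oracle_ssim_windowed(I, J, w = 3), tolerance = 1e-10)
  expect_error(img_ssim(I, J, mode = "windowed", window = 9), "window")
})

test_that("the pooled evaluation report is finite and coherent", {
  real <- make_stack(4, 8, 30)
  gen <- make_stack(4, 8, 31)
  rep <- evaluate_images(real, gen, n_batches = 2)
  expect_s3_class(rep, "metrics_report")
  expect_true(is.finite(rep$fid) && rep$fid >= 0)
  expect_true(is.finite(rep$fid_std))
  expect_true(rep$mse >= 0)
  expect_true(rep$ssim >= -1 && rep$ssim <= 1)
  # self-comparison: fid and mse vanish, ssim is 1
  self <- evaluate_images(real, real)
  expect_equal(self$fid, 0, tolerance = 1e-6)
  expect_equal(self$mse, 0)
  expect_equal(self$ssim, 1)
})
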