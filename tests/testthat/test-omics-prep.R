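test_that("all-zero removal iterates to a fixed point", {
  m <- omics_matrix(matrix(1:9, 3, 3))
  expect_equal(drop_all_zero(m), matrix(1:9, 3, 3), ignore_attr = TRUE)

  m2 <- omics_matrix(cbind(c(1, 2, 3), c(0, 0, 0), c(4, 5, 6)))
  out2 <- drop_all_zero(m2)
  expect_equal(dim(out2), c(3, 2))

  # removing a zero column creates a zero row; compare with the oracle
  vals <- rbind(c(0, 1, 0),
                c(0, 0, 2),
                c(0, 0, 3))
  m3 <- omics_matrix(vals)
  out3 <- drop_all_zero(m3)
  oracle <- oracle_drop_zero(vals)
  expect_equal(out3, oracle, ignore_attr = TRUE)
  expect_true(all(rowSums(out3 != 0) > 0) && all(colSums(out3 != 0) > 0))

  expect_error(drop_all_zero(omics_matrix(matrix(0, 2, 2))), "zero")
})

test_that("CV filter selects by sd/|mean| with deterministic ties", {
  # constant gene is never selected unless everything is constant
  vals <- cbind(g1 = c(5, 5, 5), g2 = c(1, 5, 9), g3 = c(4, 5, 6))
  m <- omics_matrix(vals)
  expect_false("g1" %in% cv_filter(m, fraction = 2 / 3))

  # count arithmetic: ceiling(fraction * G)
  m20 <- omics_matrix(matrix(rnorm(5 * 20, mean = 10), 5, 20))
  expect_length(cv_filter(m20, 0.10), 2)
  expect_length(cv_filter(m20, 1), 20)

  # direct sort oracle on random data
  set.seed(31)
  m10 <- omics_matrix(matrix(rnorm(8 * 10, mean = 3), 8, 10))
  expect_identical(cv_filter(m10, 0.1), oracle_cv_top(unclass(m10), 0.1))
  expect_identical(cv_filter(m10, 0.5), oracle_cv_top(unclass(m10), 0.5))

  # zero-mean gene is treated as maximally variable
  mz <- omics_matrix(cbind(g1 = c(-1, 1), g2 = c(10, 10.1)))
  expect_equal(cv_filter(mz, 0.5), "g1")

  # stability under patient reordering
  perm <- sample(nrow(m10))
  m10p <- omics_matrix(unclass(m10)[perm, ], patient_ids = rownames(m10)[perm])
  expect_identical(cv_filter(m10, 0.3), cv_filter(m10p, 0.3))

  expect_error(cv_filter(m10, 0), "fraction")
})

test_that("tensor construction aligns patients, genes and modalities", {
  e <- omics_matrix(matrix(1:4, 2, 2,
                           dimnames = list(c("P1", "P2"), c("gA", "gB"))),
                    "expression")
  m <- omics_matrix(matrix(5:8, 2, 2,
                           dimnames = list(c("P1", "P2"), c("gA", "gB"))),
                    "methylation")
  tens <- build_tensor(list(e, m))
  expect_equal(dim(tens), c(2, 2, 2))
  # exhaustive lookup oracle
  for (p in c("P1", "P2")) for (g in c("gA", "gB")) {
    expect_equal(tens[p, g, "expression"], e[p, g])
    expect_equal(tens[p, g, "methylation"], m[p, g])
  }

  # single modality: slice equals the matrix
  t1 <- build_tensor(list(e))
  expect_equal(t1[, , 1], unclass(e)[c("P1", "P2"), c("gA", "gB")],
               ignore_attr = TRUE)

  # permuted patient order yields the identical tensor
  e_perm <- omics_matrix(unclass(e)[c("P2", "P1"), ], "expression")
  expect_identical(build_tensor(list(e_perm, m)), tens)

  # missing patient is reported by name
  m_missing <- omics_matrix(matrix(1:2, 1, 2,
                                   dimnames = list("P1", c("gA", "gB"))),
                            "methylation")
  expect_error(build_tensor(list(e, m_missing), patients = c("P1", "P2")),
               "P2")
})

test_that("ALS factorization recovers exact-rank structure", {
  set.seed(41)
  a <- rnorm(6); b <- rnorm(5); cc <- rnorm(3)
  X1 <- outer3(cbind(a), cbind(b), cbind(cc))
  f <- cp_als(X1, R = 1, seed = 2)
  expect_lt(tail(f$fit_diagnostics$rel_error, 1), 1e-6)

  expect_error(cp_als(X1, R = 0), "positive")
  X_bad <- X1; X_bad[1] <- NA
  expect_error(cp_als(X_bad, R = 1), "finite")
})

test_that("reconstruction error is monotone non-increasing over iterations", {
  set.seed(43)
  X <- array(rnorm(6 * 5 * 4), dim = c(6, 5, 4))
  f <- cp_als(X, R = 3, max_iters = 40, tol = 0, seed = 9)
  expect_true(all(diff(f$fit_diagnostics$rel_error) <= 1e-12))
})

test_that("noiseless rank-3 factors are recovered up to permutation and scale", {
  set.seed(47)
  A <- matrix(rnorm(20 * 3), 20, 3)
  B <- matrix(rnorm(12 * 3), 12, 3)
  C <- matrix(rnorm(3 * 3), 3, 3)
  X <- outer3(A, B, C)
  f <- cp_als(X, R = 3, seed = 5, max_iters = 500, tol = 1e-14)
  expect_lt(tail(f$fit_diagnostics$rel_error, 1), 1e-6)
  expect_gt(oracle_congruence(f$scores, A), 0.99)
})

test_that("factorization is deterministic given the seed", {
  set.seed(53)
  X <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  f1 <- cp_als(X, R = 2, seed = 77)
  f2 <- cp_als(X, R = 2, seed = 77)
  expect_identical(f1$scores, f2$scores)
  expect_warning(cp_als(X, R = 4, seed = 1, max_iters = 5), "rank")
})

test_that("condition scores are z-scored per factor", {
  set.seed(59)
  X <- array(rnorm(10 * 6 * 3), dim = c(10, 6, 3))
  f <- cp_als(X, R = 2, seed = 3)
  z <- condition_scores(f)
  expect_equal(colMeans(z), c(F1 = 0, F2 = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(F1 = 1, F2 = 1), tolerance = 1e-12)
})

test_that("omics matrices round-trip through TSV", {
  m <- omics_matrix(matrix(rnorm(6), 2, 3,
                           dimnames = list(c("P1", "P2"),
                                           c("g1", "g2", "g3"))),
                    "cnv")
  fp <- tempfile(fileext = ".tsv")
  write_omics_tsv(m, fp)
  back <- read_omics_tsv(fp, "cnv")
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(m))
})

test_that("the full omics path is deterministic end to end", {
  spec <- fixture_spec(n_patients = 12, size = 8, R = 4, n_genes = 20,
                       seed = 13)
  om <- make_omics(make_factors(spec), spec)
  f1 <- prepare_omics(om, fraction = 0.5, R = 3, seed = 21)
  f2 <- prepare_omics(om, fraction = 0.5, R = 3, seed = 21)
  expect_identical(f1$scores, f2$scores)
  expect_equal(nrow(f1$scores), 12)
})
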