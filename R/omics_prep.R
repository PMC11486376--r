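#' Create an omics matrix
#'
#' Lightweight constructor for a patients x genes omics matrix with aligned
#' identifiers. Rows are patients, columns are genes.
#'
#' @param values numeric matrix (patients x genes), finite.
#' @param modality one of `"expression"`, `"methylation"`, `"cnv"`.
#' @param patient_ids,gene_ids character identifiers; default to existing
#'   dimnames.
#' @return A numeric matrix with dimnames set and attribute `modality`.
#' @export
omics_matrix <- function(values, modality = c("expression", "methylation", "cnv"),
                         patient_ids = rownames(values),
                         gene_ids = colnames(values)) {
  modality <- match.arg(modality)
  if (!all(is.finite(values)))
    stop("omics matrix contains non-finite values", call. = FALSE)
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  if (anyDuplicated(patient_ids)) stop("duplicated patient ids", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids", call. = FALSE)
  dimnames(values) <- list(patient_ids, gene_ids)
  attr(values, "modality") <- modality
  values
}

#' Remove all-zero samples and features
#'
#' Iteratively deletes any patient row or gene column whose entries are all
#' zero, until a fixed point is reached (removing a column can in principle
#' zero out a row, so a single pass is not enough).
#'
#' @param m omics matrix (patients x genes).
#' @return The submatrix in which every row and column has a nonzero entry.
#' @export
drop_all_zero <- function(m) {
  mod <- attr(m, "modality")
  repeat {
    keep_r <- rowSums(m != 0) > 0
    keep_c <- colSums(m != 0) > 0
    if (all(keep_r) && all(keep_c)) break
    m <- m[keep_r, keep_c, drop = FALSE]
    if (nrow(m) == 0L || ncol(m) == 0L)
      stop("all rows or columns are zero after filtering", call. = FALSE)
  }
  attr(m, "modality") <- mod
  m
}

#' Coefficient-of-variation gene filter
#'
#' Ranks genes by the coefficient of variation CV = sd / |mean| on a
#' reference modality and returns the identifiers of the top fraction
#' (`ceiling(fraction * G)` genes). Genes with mean exactly zero are treated
#' as maximally variable (CV = +Inf). Ties are broken lexicographically by
#' gene id, so the selection is deterministic and invariant to patient
#' ordering.
#'
#' The reference modality defaults to expression: CV is scale-dependent and
#' ill-behaved on signed or near-zero-mean data such as copy-number ratios
#' or centred methylation values.
#'
#' @param matrices a single omics matrix or a list of them.
#' @param fraction proportion of genes to keep, in (0, 1]; default 0.10.
#' @param reference modality used to compute CV when a list is given.
#' @return Character vector of selected gene ids, ordered by decreasing CV.
#' @export
cv_filter <- function(matrices, fraction = 0.10, reference = "expression") {
  if (!(fraction > 0 && fraction <= 1))
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  m <- if (is.list(matrices)) {
    mods <- vapply(matrices, function(x) attr(x, "modality") %||% "", "")
    i <- match(reference, mods)
    if (is.na(i)) i <- 1L
    matrices[[i]]
  } else matrices
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  cv <- ifelse(mu == 0, Inf, sdv / abs(mu))
  n_keep <- ceiling(fraction * ncol(m))
  ids <- colnames(m)
  ord <- order(-cv, ids)
  ids[ord][seq_len(n_keep)]
}

#' Build a patients x genes x modalities tensor
#'
#' Stacks per-modality matrices over a common, sorted patient and gene axis.
#' Every modality must cover all requested patients and genes; input row or
#' column order does not matter.
#'
#' @param matrices list of omics matrices (one per modality).
#' @param genes gene ids to include (default: intersection of all).
#' @param patients patient ids (default: intersection of all).
#' @return An `omics_tensor`: 3D array with dimnames
#'   `(patient, gene, modality)`, axes sorted lexicographically.
#' @export
build_tensor <- function(matrices, genes = NULL, patients = NULL) {
  if (!is.list(matrices)) matrices <- list(matrices)
  mods <- vapply(seq_along(matrices), function(i)
    attr(matrices[[i]], "modality") %||% paste0("modality", i), "")
  if (is.null(patients))
    patients <- Reduce(intersect, lapply(matrices, rownames))
  if (is.null(genes))
    genes <- Reduce(intersect, lapply(matrices, colnames))
  patients <- sort(as.character(patients))
  genes <- sort(as.character(genes))
  tens <- array(NA_real_, dim = c(length(patients), length(genes), length(matrices)),
                dimnames = list(patients, genes, mods))
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    miss_p <- setdiff(patients, rownames(m))
    if (length(miss_p))
      stop(sprintf("modality '%s' is missing patients: %s", mods[i],
                   paste(utils::head(miss_p, 5), collapse = ", ")), call. = FALSE)
    miss_g <- setdiff(genes, colnames(m))
    if (length(miss_g))
      stop(sprintf("modality '%s' is missing genes: %s", mods[i],
                   paste(utils::head(miss_g, 5), collapse = ", ")), call. = FALSE)
    tens[, , i] <- m[patients, genes]
  }
  class(tens) <- c("omics_tensor", class(tens))
  tens
}

# mode-n unfolding of a 3D array: rows index mode `n`
unfold3 <- function(x, n) {
  d <- dim(x)
  perm <- c(n, setdiff(1:3, n))
  matrix(aperm(x, perm), d[n], prod(d[-n]))
}

# column-wise Khatri-Rao product
khatri_rao <- function(A, B) {
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (r in seq_len(ncol(A))) out[, r] <- kronecker(A[, r], B[, r])
  out
}

#' Rank-R CP tensor factorization by alternating least squares
#'
#' Decomposes a patients x genes x modalities tensor into R rank-one
#' components: \eqn{X \approx \sum_{r=1}^R a_r \circ b_r \circ c_r}, where
#' the patient-mode factor matrix (rows = patients, columns = factors) is
#' the latent representation used as the diffusion model's condition. The
#' factors are estimated by alternating least squares with seeded random
#' initialization; the squared reconstruction error is non-increasing across
#' iterations by construction and is recorded per iteration.
#'
#' After fitting, component scale is absorbed into the patient mode and the
#' gene/modality factor columns are normalized to unit length; components
#' are ordered by decreasing norm.
#'
#' @param tensor 3D array (patients x genes x modalities), finite.
#' @param R factor count (rank), default 17.
#' @param max_iters maximum ALS sweeps per start (default 200).
#' @param tol stop when the relative decrease of the reconstruction error
#'   falls below this (default 1e-8).
#' @param seed integer seed; each restart draws its initialization from a
#'   sub-stream derived from it.
#' @param n_starts number of seeded random restarts (default 5); ALS is
#'   sensitive to initialization, and the best-fitting start is kept.
#' @return An object of class `"latent_factors"`: list with `scores`
#'   (patients x R), `gene_loadings`, `modality_loadings`,
#'   `fit_diagnostics` (list with `rel_error` trace, `converged`,
#'   `iterations`), `R`, `seed`.
#' @export
cp_als <- function(tensor, R = 17, max_iters = 200, tol = 1e-8, seed = 1,
                   n_starts = 5) {
  if (!all(is.finite(tensor)))
    stop("tensor contains non-finite entries", call. = FALSE)
  if (length(R) != 1L || R < 1 || R != round(R))
    stop("`R` must be a positive integer", call. = FALSE)
  if (max_iters < 1) stop("`max_iters` must be >= 1", call. = FALSE)
  d <- dim(tensor)
  if (R > min(d))
    warning(sprintf("rank R = %d exceeds the smallest tensor dimension (%d)",
                    R, min(d)))
  X <- array(as.numeric(tensor), dim = d)
  X1 <- unfold3(X, 1); X2 <- unfold3(X, 2); X3 <- unfold3(X, 3)
  nrmX <- sqrt(sum(X^2))
  if (nrmX == 0) nrmX <- 1

  ridge <- 1e-12
  solve_gram <- function(G, rhs) {
    # rhs: R x n matrix; returns solution of G %*% Z = rhs, ridge fallback
    out <- tryCatch(solve(G, rhs), error = function(e) NULL)
    if (is.null(out))
      out <- solve(G + diag(ridge * (1 + diag(G)), nrow(G)), rhs)
    out
  }

  run_start <- function(start_seed) {
    set.seed(as.integer(start_seed))
    A <- matrix(stats::rnorm(d[1] * R), d[1], R)
    B <- matrix(stats::rnorm(d[2] * R), d[2], R)
    C <- matrix(stats::rnorm(d[3] * R), d[3], R)
    rel_err <- numeric(0)
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iters)) {
      A <- t(solve_gram((t(C) %*% C) * (t(B) %*% B),
                        t(X1 %*% khatri_rao(C, B))))
      B <- t(solve_gram((t(C) %*% C) * (t(A) %*% A),
                        t(X2 %*% khatri_rao(C, A))))
      C <- t(solve_gram((t(B) %*% B) * (t(A) %*% A),
                        t(X3 %*% khatri_rao(B, A))))
      approx1 <- A %*% t(khatri_rao(C, B))
      e <- sqrt(sum((X1 - approx1)^2)) / nrmX
      rel_err <- c(rel_err, e)
      if (is.finite(prev) && prev - e < tol * max(prev, 1e-300)) {
        converged <- TRUE
        break
      }
      prev <- e
    }
    list(A = A, B = B, C = C, rel_err = rel_err, converged = converged)
  }

  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    cand <- run_start(derive_seed(seed, 30 + s))
    if (is.null(best) ||
        utils::tail(cand$rel_err, 1) < utils::tail(best$rel_err, 1))
      best <- cand
  }
  A <- best$A; B <- best$B; C <- best$C
  rel_err <- best$rel_err
  converged <- best$converged

  # normalize gene/modality columns; absorb scale into patient scores
  nb <- sqrt(colSums(B^2)); nb[nb == 0] <- 1
  nc <- sqrt(colSums(C^2)); nc[nc == 0] <- 1
  B <- sweep(B, 2, nb, "/")
  C <- sweep(C, 2, nc, "/")
  A <- sweep(A, 2, nb * nc, "*")
  ord <- order(-colSums(A^2))
  A <- A[, ord, drop = FALSE]
  B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]

  dn <- dimnames(tensor)
  rownames(A) <- dn[[1]]; rownames(B) <- dn[[2]]; rownames(C) <- dn[[3]]
  colnames(A) <- colnames(B) <- colnames(C) <- paste0("F", seq_len(R))

  structure(
    list(scores = A, gene_loadings = B, modality_loadings = C,
         fit_diagnostics = list(rel_error = rel_err, converged = converged,
                                iterations = length(rel_err)),
         R = as.integer(R), seed = as.integer(seed)),
    class = "latent_factors")
}

#' @export
print.latent_factors <- function(x, ...) {
  cat(sprintf("Latent factor matrix: %d patients x %d factors\n",
              nrow(x$scores), x$R))
  fd <- x$fit_diagnostics
  cat(sprintf("  ALS iterations: %d (%s), final relative error %.4g\n",
              fd$iterations, if (fd$converged) "converged" else "max iters",
              utils::tail(fd$rel_error, 1)))
  invisible(x)
}

#' Condition vectors from latent factors
#'
#' Z-scores each factor column of a fitted [cp_als()] object, yielding the
#' per-patient condition vectors \eqn{\tau} consumed by the diffusion model.
#' The inner-product fusion is scale-sensitive, so factors are standardized
#' before conditioning.
#'
#' @param lf a `"latent_factors"` object (or a bare scores matrix).
#' @return Patients x R numeric matrix with columns of mean 0, sd 1
#'   (constant columns map to 0).
#' @export
condition_scores <- function(lf) {
  s <- if (inherits(lf, "latent_factors")) lf$scores else lf
  mu <- colMeans(s)
  sdv <- apply(s, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  scale(s, center = mu, scale = sdv)[, , drop = FALSE]
}

#' Read / write omics matrices as TSV
#'
#' TSV layout: header row of gene ids, first column of patient ids, one
#' patient per row.
#'
#' @param path file path.
#' @param modality modality tag attached on read.
#' @param m matrix to write.
#' @return `read_omics_tsv()` returns an [omics_matrix()].
#' @export
read_omics_tsv <- function(path, modality = "expression") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  omics_matrix(as.matrix(df), modality = modality)
}

#' @rdname read_omics_tsv
#' @export
write_omics_tsv <- function(m, path) {
  df <- data.frame(patient_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Full omics preprocessing path
#'
#' Drops all-zero rows/columns per modality, selects the top-CV gene
#' fraction, builds the patients x genes x modalities tensor, factorizes it
#' at rank `R`, and returns the fitted latent factors.
#'
#' @param matrices list of omics matrices.
#' @param fraction CV filter fraction (default 0.10).
#' @param R factorization rank (default 17).
#' @param seed seed for the ALS initialization.
#' @param ... passed to [cp_als()].
#' @return A `"latent_factors"` object.
#' @export
prepare_omics <- function(matrices, fraction = 0.10, R = 17, seed = 1, ...) {
  matrices <- lapply(matrices, drop_all_zero)
  genes <- cv_filter(matrices, fraction = fraction)
  tens <- build_tensor(matrices, genes = genes)
  cp_als(tens, R = R, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
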