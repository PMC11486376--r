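#' Parameters for the linear condition extension
#'
#' Creates the learnable map that extends an R-dimensional condition vector
#' \eqn{\tau} to an `n x n` feature matrix `F` for inner-product fusion.
#' The dense parameterization is a full `R -> n^2` linear map; the `outer`
#' parameterization uses two `R -> n` maps whose outputs are combined by an
#' outer product (fewer parameters, rank-1 maps).
#'
#' @param R condition dimension.
#' @param n image side length.
#' @param extension `"dense"` or `"outer"`.
#' @param init_sd standard deviation of the random weight initialization.
#' @param seed integer seed.
#' @return List with `W` (`n^2 x R`) and `b` (length `n^2`, zeros) for
#'   `"dense"`; `U`, `V` (`n x R`) for `"outer"`; plus `n`, `R`, `extension`.
#' @export
extension_params <- function(R, n, extension = c("dense", "outer"),
                             init_sd = 0.02, seed = 1) {
  extension <- match.arg(extension)
  set.seed(as.integer(seed))
  p <- if (extension == "dense") {
    list(W = matrix(stats::rnorm(n * n * R, sd = init_sd), n * n, R),
         b = numeric(n * n))
  } else {
    list(U = matrix(stats::rnorm(n * R, sd = init_sd), n, R),
         V = matrix(stats::rnorm(n * R, sd = init_sd), n, R))
  }
  c(p, list(n = n, R = R, extension = extension))
}

#' Linearly extend a condition vector to image shape
#'
#' Maps \eqn{\tau \in R^R} to an `n x n` matrix `F` by the learnable linear
#' map in `params`. With zero bias the map is exactly linear:
#' `extend_linear(a*t1 + b*t2) = a*extend_linear(t1) + b*extend_linear(t2)`.
#'
#' @param tau numeric condition vector of length `params$R`.
#' @param params from [extension_params()].
#' @return `n x n` numeric matrix.
#' @export
extend_linear <- function(tau, params) {
  if (length(tau) != params$R)
    stop(sprintf("tau has length %d, expected %d", length(tau), params$R),
         call. = FALSE)
  n <- params$n
  if (params$extension == "dense") {
    matrix(params$W %*% tau + params$b, n, n)
  } else {
    (params$U %*% tau) %*% t(params$V %*% tau) / sqrt(params$R)
  }
}

#' Inner-product fusion of condition map and image
#'
#' The fusion product \eqn{X = F P} (ordinary matrix product,
#' \eqn{X_{ij} = \sum_k F_{ik} P_{kj}}), encoding the interaction between the
#' extended genomic feature matrix `F` and the image `P`.
#'
#' @param F_map `n x n` extended condition matrix.
#' @param P `n x n` image matrix.
#' @return `n x n` matrix `F %*% P`.
#' @export
inner_product_fuse <- function(F_map, P) {
  if (!is.matrix(F_map) || !is.matrix(P) ||
      !identical(dim(F_map), dim(P)) || nrow(P) != ncol(P))
    stop("`F_map` and `P` must be equal-size square matrices", call. = FALSE)
  F_map %*% P
}

#' Form the noisy input
#'
#' Adds the fusion product back onto the (noised) image: `NI = P + X`. Both
#' `NI` and the condition vector itself are then passed to the denoiser.
#'
#' @param P noised image matrix.
#' @param X fusion product from [inner_product_fuse()].
#' @return Matrix `P + X`.
#' @export
noisy_input <- function(P, X) {
  if (!identical(dim(P), dim(X)))
    stop("`P` and `X` must have identical shapes", call. = FALSE)
  P + X
}

#' Parameters for cross-attention
#'
#' Learnable projections for single-head cross-attention between condition
#' tokens (queries) and image tokens (keys/values): `W_QA` projects condition
#' tokens to queries, `W_KB`/`W_VB` project image tokens to keys/values, and
#' `W_OB` maps the weighted values to the output feature dimension.
#'
#' @param d_a condition-token feature dimension.
#' @param d_b image-token feature dimension.
#' @param d_k key/query dimension.
#' @param d_v value dimension (default `d_k`).
#' @param d_out output feature dimension (default `d_b`).
#' @param init_sd weight init scale.
#' @param seed integer seed.
#' @return List of matrices `W_QA (d_a x d_k)`, `W_KB (d_b x d_k)`,
#'   `W_VB (d_b x d_v)`, `W_OB (d_v x d_out)`, and `d_k`.
#' @export
attention_params <- function(d_a, d_b, d_k, d_v = d_k, d_out = d_b,
                             init_sd = 0.1, seed = 1) {
  set.seed(as.integer(seed))
  list(W_QA = matrix(stats::rnorm(d_a * d_k, sd = init_sd), d_a, d_k),
       W_KB = matrix(stats::rnorm(d_b * d_k, sd = init_sd), d_b, d_k),
       W_VB = matrix(stats::rnorm(d_b * d_v, sd = init_sd), d_b, d_v),
       W_OB = matrix(stats::rnorm(d_v * d_out, sd = init_sd), d_v, d_out),
       d_k = d_k)
}

# numerically stabilized row softmax
row_softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  s <- e / rowSums(e)
  if (!all(is.finite(s))) stop("non-finite attention weights", call. = FALSE)
  s
}

#' Cross-attention between condition and image tokens
#'
#' Computes \eqn{Q_A = X_A W_{QA}}, \eqn{K_B = X_B W_{KB}},
#' \eqn{V_B = X_B W_{VB}}, the attention map
#' \eqn{A = \mathrm{softmax}(Q_A K_B^\top / \sqrt{d_k})} (row-wise, with
#' max-subtraction stabilization), the weighted values \eqn{WV = A V_B}, and
#' the fused representation \eqn{FR = WV\, W_{OB}}. Every row of `A` sums to
#' 1 and lies in (0, 1).
#'
#' @param X_A condition token array (`N_A x d_a`): queries come from the
#'   omics modality.
#' @param X_B image token array (`N_B x d_b`): keys and values come from the
#'   image modality.
#' @param params from [attention_params()].
#' @return List with `FR` (`N_A x d_out`), `A` (`N_A x N_B` attention map),
#'   and `WV` (`N_A x d_v`).
#' @export
cross_attention <- function(X_A, X_B, params) {
  if (ncol(X_A) != nrow(params$W_QA) || ncol(X_B) != nrow(params$W_KB))
    stop("token feature dimensions do not match attention parameters",
         call. = FALSE)
  Q <- X_A %*% params$W_QA
  K <- X_B %*% params$W_KB
  V <- X_B %*% params$W_VB
  A <- row_softmax(Q %*% t(K) / sqrt(params$d_k))
  WV <- A %*% V
  list(FR = WV %*% params$W_OB, A = A, WV = WV)
}
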