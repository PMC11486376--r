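# U-Net noise predictor eps_theta(x_t, t, tau).
#
# Structure: inner-product condition fusion at the input (NI = P + g*F%*%P,
# F = extend_linear(tau), g a learnable gate initialized at 0), a small
# encoder/decoder with average-pool downsampling, nearest-neighbour
# upsampling and skip concatenation, residual conv blocks with per-stage
# time-embedding injection, and cross-attention at the bottleneck where
# queries come from learned condition tokens (a linear lift of tau) and
# keys/values from the flattened bottleneck positions. The fused
# representation is redistributed to image positions through the transpose
# of the attention map and added residually.

#' Sinusoidal timestep embedding
#'
#' Embeds an integer timestep as interleaved sine/cosine pairs at `dim/2`
#' geometrically spaced frequencies \eqn{\omega_j = 10000^{-j/(d/2-1)}},
#' \eqn{j = 0, \dots, d/2-1} (so \eqn{\omega_0 = 1} and the first pair is
#' \eqn{(\sin t, \cos t)}). Injective over any practical `[1, T]` for
#' `dim >= 2`.
#'
#' @param t integer timestep(s), each >= 1.
#' @param dim even embedding dimension.
#' @return Numeric vector of length `dim`, or a `length(t) x dim` matrix.
#' @export
time_embedding <- function(t, dim = 16) {
  if (dim < 2 || dim %% 2 != 0) stop("`dim` must be even and >= 2", call. = FALSE)
  if (any(t < 1)) stop("timestep must be >= 1", call. = FALSE)
  half <- dim %/% 2
  w <- if (half == 1) 1 else 10000^(-(0:(half - 1)) / (half - 1))
  emb <- matrix(0, length(t), dim)
  ang <- outer(t, w)
  emb[, seq(1, dim, by = 2)] <- sin(ang)
  emb[, seq(2, dim, by = 2)] <- cos(ang)
  if (length(t) == 1L) drop(emb) else emb
}

#' Denoiser configuration
#'
#' Architecture hyperparameters of the U-Net noise predictor. The input
#' side `n` must be divisible by `2^depth` (checked here, at build time).
#'
#' @param n input image side length.
#' @param R condition vector dimension.
#' @param depth number of down/up stages (>= 1).
#' @param base_channels channels at the first stage.
#' @param ch_mult per-stage channel multipliers (length `depth`).
#' @param time_dim sinusoidal time-embedding dimension (even).
#' @param n_tokens number of learned condition tokens at the bottleneck.
#' @param d_k attention key/query (and value) dimension.
#' @param extension condition extension parameterization, `"dense"` or
#'   `"outer"` (see [extension_params()]; only `"dense"` is learned jointly).
#' @param gate_init initial value of the fusion gate (default 0: the model
#'   starts exactly unconditional through the fusion path).
#' @param aux_cond logical; if `TRUE` the condition is also projected into
#'   the time embedding (an additive conditioning pathway alongside fusion
#'   and attention).
#' @return List of class `"denoiser_config"`.
#' @export
denoiser_config <- function(n = 16, R = 8, depth = 2, base_channels = 8,
                            ch_mult = NULL, time_dim = 16, n_tokens = 4,
                            d_k = 8, extension = "dense", gate_init = 0,
                            aux_cond = TRUE) {
  if (depth < 1) stop("`depth` must be >= 1", call. = FALSE)
  if (n %% (2^depth) != 0)
    stop(sprintf("input size %d is not divisible by 2^%d", n, depth),
         call. = FALSE)
  if (is.null(ch_mult)) ch_mult <- 2^(seq_len(depth) - 1L)
  if (length(ch_mult) != depth)
    stop("`ch_mult` must have one entry per stage", call. = FALSE)
  structure(list(n = n, R = R, depth = depth,
                 base_channels = base_channels, ch_mult = ch_mult,
                 channels = base_channels * ch_mult, time_dim = time_dim,
                 n_tokens = n_tokens, d_k = d_k, extension = extension,
                 gate_init = gate_init, aux_cond = aux_cond),
            class = "denoiser_config")
}

rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

block_param_names <- c("W1", "b1", "Wt", "bt", "W2", "b2")

init_block <- function(cin, cout, E) {
  p <- list(W1 = rnorm_mat(9 * cin, cout, sqrt(2 / (9 * cin))),
            b1 = numeric(cout),
            Wt = rnorm_mat(E, cout, 1 / sqrt(E)),
            bt = numeric(cout),
            W2 = rnorm_mat(9 * cout, cout, sqrt(2 / (9 * cout))),
            b2 = numeric(cout))
  if (cin != cout) {
    p$Ws <- rnorm_mat(cin, cout, sqrt(1 / cin))
    p$bs <- numeric(cout)
  }
  p
}

#' Initialize denoiser parameters
#'
#' Draws all learnable weights for a [denoiser_config()]. The fusion gate,
#' the attention output matrix and the final convolution are zero-initialized
#' so an untrained model predicts zero noise and is exactly unconditional.
#'
#' @param config a [denoiser_config()].
#' @param seed integer seed.
#' @return Flat named list of numeric arrays (class `"denoiser_params"`).
#' @export
init_denoiser <- function(config, seed = 1) {
  set.seed(as.integer(seed))
  n <- config$n; R <- config$R; E <- config$time_dim
  ch <- config$channels; D <- config$depth
  C1 <- ch[1]; CD <- ch[D]
  p <- list()
  p[["ext.W"]] <- rnorm_mat(n * n, R, 0.02)
  p[["ext.b"]] <- numeric(n * n)
  p[["gate"]] <- config$gate_init
  p[["tmlp.W1"]] <- rnorm_mat(E, E, 1 / sqrt(E))
  p[["tmlp.b1"]] <- numeric(E)
  p[["tmlp.W2"]] <- rnorm_mat(E, E, 1 / sqrt(E))
  p[["tmlp.b2"]] <- numeric(E)
  if (config$aux_cond) p[["aux.W"]] <- rnorm_mat(R, E, 0.1)
  p[["in.W"]] <- rnorm_mat(9, C1, sqrt(2 / 9))
  p[["in.b"]] <- numeric(C1)
  add_block <- function(p, prefix, cin, cout) {
    bp <- init_block(cin, cout, E)
    for (nm in names(bp)) p[[paste0(prefix, ".", nm)]] <- bp[[nm]]
    p
  }
  for (i in seq_len(D))
    p <- add_block(p, paste0("down", i), if (i == 1) C1 else ch[i - 1], ch[i])
  p <- add_block(p, "mid1", CD, CD)
  dk <- config$d_k
  p[["attn.W_lift"]] <- rnorm_mat(config$n_tokens * CD, R, 0.1)
  p[["attn.b_lift"]] <- numeric(config$n_tokens * CD)
  p[["attn.W_QA"]] <- rnorm_mat(CD, dk, 1 / sqrt(CD))
  p[["attn.W_KB"]] <- rnorm_mat(CD, dk, 1 / sqrt(CD))
  p[["attn.W_VB"]] <- rnorm_mat(CD, dk, 1 / sqrt(CD))
  p[["attn.W_OB"]] <- matrix(0, dk, CD)
  p <- add_block(p, "mid2", CD, CD)
  for (i in rev(seq_len(D)))
    p <- add_block(p, paste0("up", i), 2 * ch[i], if (i == 1) C1 else ch[i - 1])
  p[["out.W"]] <- matrix(0, 9 * C1, 1)
  p[["out.b"]] <- 0
  class(p) <- "denoiser_params"
  p
}

block_fwd <- function(h, temb, p, prefix) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  c1 <- conv3_fwd(h, g("W1"), g("b1"))
  tp <- linear_fwd(temb, g("Wt"), g("bt"))
  a <- c1$y
  Cout <- dim(a)[4]
  for (cc in seq_len(Cout)) a[, , , cc] <- a[, , , cc] + tp$y[, cc]
  s1 <- silu_fwd(a)
  c2 <- conv3_fwd(s1$y, g("W2"), g("b2"))
  s2 <- silu_fwd(c2$y)
  has_proj <- !is.null(g("Ws"))
  sk <- if (has_proj) conv1_fwd(h, g("Ws"), g("bs")) else NULL
  y <- s2$y + if (has_proj) sk$y else h
  list(y = y,
       cache = list(c1 = c1$cache, tp = tp$cache, s1 = s1$cache,
                    c2 = c2$cache, s2 = s2$cache, sk = if (has_proj) sk$cache,
                    has_proj = has_proj))
}

block_bwd <- function(dy, cache, prefix, grads) {
  ds2 <- silu_bwd(dy, cache$s2)
  b2 <- conv3_bwd(ds2, cache$c2)
  grads <- acc_grad(grads, paste0(prefix, ".W2"), b2$dW)
  grads <- acc_grad(grads, paste0(prefix, ".b2"), b2$db)
  da <- silu_bwd(b2$dx, cache$s1)
  B <- dim(da)[1]; Cout <- dim(da)[4]
  dtp <- matrix(0, B, Cout)
  for (cc in seq_len(Cout))
    dtp[, cc] <- rowSums(matrix(da[, , , cc], B))
  lt <- linear_bwd(dtp, cache$tp)
  grads <- acc_grad(grads, paste0(prefix, ".Wt"), lt$dW)
  grads <- acc_grad(grads, paste0(prefix, ".bt"), lt$db)
  dtemb <- lt$dx
  b1 <- conv3_bwd(da, cache$c1)
  grads <- acc_grad(grads, paste0(prefix, ".W1"), b1$dW)
  grads <- acc_grad(grads, paste0(prefix, ".b1"), b1$db)
  dx <- b1$dx
  if (cache$has_proj) {
    bs <- conv1_bwd(dy, cache$sk)
    grads <- acc_grad(grads, paste0(prefix, ".Ws"), bs$dW)
    grads <- acc_grad(grads, paste0(prefix, ".bs"), bs$db)
    dx <- dx + bs$dx
  } else dx <- dx + dy
  list(dx = dx, dtemb = dtemb, grads = grads)
}

as_batch <- function(x, n) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  else if (length(dim(x)) == 3L && dim(x)[2] == n && dim(x)[3] == n) x
  else stop("`x` must be an n x n matrix or a (B, n, n) array", call. = FALSE)
  x
}

#' Run the denoiser forward
#'
#' Predicts the noise field \eqn{\hat\epsilon = \epsilon_\theta(x_t, t, \tau)}
#' for a batch. The condition enters through (a) inner-product fusion at the
#' input, (b) bottleneck cross-attention, and (c), when
#' `config$aux_cond` is `TRUE`, an additive projection into the time
#' embedding.
#'
#' @param model list with elements `config` ([denoiser_config()]) and
#'   `params` ([init_denoiser()]).
#' @param x `n x n` matrix or `(B, n, n)` array of noised inputs.
#' @param t integer timestep, scalar or length-B.
#' @param tau condition vector (length R), `B x R` matrix, or NULL for an
#'   all-zero condition.
#' @param keep_cache logical; keep intermediate activations for backprop.
#' @return `eps_hat` shaped like `x` (with attribute `"cache"` when
#'   `keep_cache = TRUE`).
#' @export
denoiser_forward <- function(model, x, t, tau = NULL, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  single <- is.matrix(x)
  x <- as_batch(x, cfg$n)
  B <- dim(x)[1]; n <- cfg$n; D <- cfg$depth; ch <- cfg$channels
  if (length(t) == 1L) t <- rep(t, B)
  if (is.null(tau)) tau <- matrix(0, B, cfg$R)
  if (is.vector(tau) && !is.matrix(tau)) {
    if (length(tau) != cfg$R)
      stop(sprintf("condition has %d factors but the model expects R = %d",
                   length(tau), cfg$R), call. = FALSE)
    tau <- matrix(tau, B, cfg$R, byrow = TRUE)
  }
  if (ncol(tau) != cfg$R)
    stop(sprintf("condition has %d factors but the model expects R = %d",
                 ncol(tau), cfg$R), call. = FALSE)

  # input fusion: NI_b = P_b + gate * (F_b %*% P_b)
  NI <- array(0, dim = c(B, n, n, 1L))
  fus <- vector("list", B)
  for (b in seq_len(B)) {
    P <- x[b, , ]
    Fm <- matrix(p[["ext.W"]] %*% tau[b, ] + p[["ext.b"]], n, n)
    Xf <- Fm %*% P
    NI[b, , , 1L] <- P + p[["gate"]] * Xf
    fus[[b]] <- list(P = P, Fm = Fm, Xf = Xf)
  }

  # time embedding
  emb <- time_embedding(t, cfg$time_dim)
  if (!is.matrix(emb)) emb <- matrix(emb, 1)
  t1 <- linear_fwd(emb, p[["tmlp.W1"]], p[["tmlp.b1"]])
  ts <- silu_fwd(t1$y)
  t2 <- linear_fwd(ts$y, p[["tmlp.W2"]], p[["tmlp.b2"]])
  temb <- t2$y
  if (cfg$aux_cond) temb <- temb + tau %*% p[["aux.W"]]

  cin <- conv3_fwd(NI, p[["in.W"]], p[["in.b"]])
  h <- cin$y
  skips <- vector("list", D)
  downs <- vector("list", D)
  pools <- vector("list", D)
  for (i in seq_len(D)) {
    bk <- block_fwd(h, temb, p, paste0("down", i))
    skips[[i]] <- bk$y
    downs[[i]] <- bk$cache
    pl <- avgpool2_fwd(bk$y)
    pools[[i]] <- pl$cache
    h <- pl$y
  }

  m1 <- block_fwd(h, temb, p, "mid1")
  h <- m1$y

  # bottleneck cross-attention (per batch item)
  CD <- ch[D]; nb <- dim(h)[2]; NT <- cfg$n_tokens
  att <- vector("list", B)
  h_att <- h
  for (b in seq_len(B)) {
    XB <- matrix(h[b, , , ], nb * nb, CD)
    XA <- matrix(p[["attn.W_lift"]] %*% tau[b, ] + p[["attn.b_lift"]], NT, CD)
    Q <- XA %*% p[["attn.W_QA"]]
    K <- XB %*% p[["attn.W_KB"]]
    V <- XB %*% p[["attn.W_VB"]]
    A <- row_softmax(Q %*% t(K) / sqrt(cfg$d_k))
    WV <- A %*% V
    FR <- WV %*% p[["attn.W_OB"]]
    U <- t(A) %*% FR
    h_att[b, , , ] <- array(XB + U, dim = c(nb, nb, CD))
    att[[b]] <- list(XA = XA, XB = XB, Q = Q, K = K, V = V, A = A, WV = WV,
                     FR = FR)
  }
  h <- h_att

  m2 <- block_fwd(h, temb, p, "mid2")
  h <- m2$y

  ups <- vector("list", D)
  upc <- vector("list", D)
  for (i in rev(seq_len(D))) {
    us <- upsample2_fwd(h)
    upc[[i]] <- us$cache
    d1 <- dim(us$y)
    hcat <- array(0, dim = c(d1[1], d1[2], d1[3], d1[4] + dim(skips[[i]])[4]))
    hcat[, , , seq_len(d1[4])] <- us$y
    hcat[, , , d1[4] + seq_len(dim(skips[[i]])[4])] <- skips[[i]]
    bk <- block_fwd(hcat, temb, p, paste0("up", i))
    ups[[i]] <- c(bk$cache, list(split_at = d1[4]))
    h <- bk$y
  }

  cout <- conv3_fwd(h, p[["out.W"]], p[["out.b"]])
  eps_hat <- cout$y[, , , 1L]
  if (single) eps_hat <- matrix(eps_hat, n, n)
  else eps_hat <- array(eps_hat, dim = c(B, n, n))

  if (keep_cache) {
    attr(eps_hat, "cache") <- list(
      fus = fus, tau = tau, emb = list(t1 = t1$cache, ts = ts$cache,
                                       t2 = t2$cache),
      cin = cin$cache, downs = downs, pools = pools, skips_dim = dim(skips[[1]]),
      m1 = m1$cache, att = att, m2 = m2$cache, ups = ups, upc = upc,
      cout = cout$cache, B = B, single = single, nb = nb)
  }
  eps_hat
}

#' Backpropagate through the denoiser
#'
#' Given the upstream gradient with respect to the predicted noise, returns
#' gradients for every parameter. `cache` is the attribute produced by
#' [denoiser_forward()] with `keep_cache = TRUE`.
#'
#' @param model list with `config` and `params`.
#' @param cache forward cache.
#' @param dout gradient of the loss w.r.t. `eps_hat` (same shape).
#' @return Flat named list of gradients matching `model$params`.
#' @export
denoiser_backward <- function(model, cache, dout) {
  cfg <- model$config; p <- model$params
  B <- cache$B; n <- cfg$n; D <- cfg$depth; ch <- cfg$channels
  grads <- list()
  dy <- array(dout, dim = c(B, n, n, 1L))

  bo <- conv3_bwd(dy, cache$cout)
  grads <- acc_grad(grads, "out.W", bo$dW)
  grads <- acc_grad(grads, "out.b", bo$db)
  dh <- bo$dx
  dtemb <- matrix(0, B, cfg$time_dim)
  dskips <- vector("list", D)

  for (i in seq_len(D)) {     # reverse of the up loop (up1 ran last)
    bk <- block_bwd(dh, cache$ups[[i]], paste0("up", i), grads)
    grads <- bk$grads
    dtemb <- dtemb + bk$dtemb
    sp <- cache$ups[[i]]$split_at
    dcat <- bk$dx
    dus <- dcat[, , , seq_len(sp), drop = FALSE]
    dskips[[i]] <- dcat[, , , sp + seq_len(dim(dcat)[4] - sp), drop = FALSE]
    dh <- upsample2_bwd(dus, cache$upc[[i]])
  }

  bk <- block_bwd(dh, cache$m2, "mid2", grads)
  grads <- bk$grads
  dtemb <- dtemb + bk$dtemb
  dh <- bk$dx

  # attention backward
  CD <- ch[D]; nb <- cache$nb; NT <- cfg$n_tokens
  dtau <- matrix(0, B, cfg$R)
  dh_pre <- dh
  for (b in seq_len(B)) {
    ac <- cache$att[[b]]
    dU <- matrix(dh[b, , , ], nb * nb, CD)   # grad wrt (XB + U)
    dXB <- dU                                 # residual path
    dFR <- ac$A %*% dU
    dA <- tcrossprod(ac$FR, dU)               # N_A x N_B, from U = t(A)%*%FR
    dWV <- tcrossprod(dFR, p[["attn.W_OB"]])
    grads <- acc_grad(grads, "attn.W_OB", crossprod(ac$WV, dFR))
    dA <- dA + tcrossprod(dWV, ac$V)
    dV <- crossprod(ac$A, dWV)
    dS <- ac$A * (dA - rowSums(dA * ac$A))
    dlog <- dS / sqrt(cfg$d_k)
    dQ <- dlog %*% ac$K
    dK <- crossprod(dlog, ac$Q)
    dXA <- tcrossprod(dQ, p[["attn.W_QA"]])
    grads <- acc_grad(grads, "attn.W_QA", crossprod(ac$XA, dQ))
    dXB <- dXB + tcrossprod(dK, p[["attn.W_KB"]]) +
      tcrossprod(dV, p[["attn.W_VB"]])
    grads <- acc_grad(grads, "attn.W_KB", crossprod(ac$XB, dK))
    grads <- acc_grad(grads, "attn.W_VB", crossprod(ac$XB, dV))
    dlift <- as.vector(dXA)
    grads <- acc_grad(grads, "attn.W_lift", dlift %o% cache$tau[b, ])
    grads <- acc_grad(grads, "attn.b_lift", dlift)
    dh_pre[b, , , ] <- array(dXB, dim = c(nb, nb, CD))
  }
  dh <- dh_pre

  bk <- block_bwd(dh, cache$m1, "mid1", grads)
  grads <- bk$grads
  dtemb <- dtemb + bk$dtemb
  dh <- bk$dx

  for (i in rev(seq_len(D))) {
    dh <- avgpool2_bwd(dh, cache$pools[[i]])
    dh <- dh + dskips[[i]]
    bk <- block_bwd(dh, cache$downs[[i]], paste0("down", i), grads)
    grads <- bk$grads
    dtemb <- dtemb + bk$dtemb
    dh <- bk$dx
  }

  bi <- conv3_bwd(dh, cache$cin)
  grads <- acc_grad(grads, "in.W", bi$dW)
  grads <- acc_grad(grads, "in.b", bi$db)
  dNI <- bi$dx

  # time-embedding backward
  if (cfg$aux_cond)
    grads <- acc_grad(grads, "aux.W", crossprod(cache$tau, dtemb))
  l2 <- linear_bwd(dtemb, cache$emb$t2)
  grads <- acc_grad(grads, "tmlp.W2", l2$dW)
  grads <- acc_grad(grads, "tmlp.b2", l2$db)
  dts <- silu_bwd(l2$dx, cache$emb$ts)
  l1 <- linear_bwd(dts, cache$emb$t1)
  grads <- acc_grad(grads, "tmlp.W1", l1$dW)
  grads <- acc_grad(grads, "tmlp.b1", l1$db)

  # fusion backward
  dgate <- 0
  dextW <- matrix(0, n * n, cfg$R)
  dextb <- numeric(n * n)
  for (b in seq_len(B)) {
    fb <- cache$fus[[b]]
    dNIb <- matrix(dNI[b, , , 1L], n, n)
    dgate <- dgate + sum(dNIb * fb$Xf)
    dXf <- p[["gate"]] * dNIb
    dF <- tcrossprod(dXf, fb$P)
    dextW <- dextW + as.vector(dF) %o% cache$tau[b, ]
    dextb <- dextb + as.vector(dF)
  }
  grads <- acc_grad(grads, "gate", dgate)
  grads <- acc_grad(grads, "ext.W", dextW)
  grads <- acc_grad(grads, "ext.b", dextb)
  grads
}

#' Save / load a denoiser checkpoint
#'
#' Serializes config, parameters, noise schedule and metadata so that a
#' reloaded model reproduces bit-identical outputs.
#'
#' @param model a fitted [cpdm()] object or a `list(config, params)` pair.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
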