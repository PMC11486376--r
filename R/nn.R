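# Minimal neural-network primitives with hand-derived backprop.
#
# Feature maps are 4D arrays dim c(B, H, W, C) (batch fastest in memory, so
# reshapes between array and matrix views need no permutation). 3x3
# convolutions use an im2col lowering: a precomputed gather index turns the
# zero-padded input into a (B*H*W) x (9*C) matrix, and the convolution is a
# single matrix product with the (9*Cin) x Cout weight, row order
# (kernel offset fastest, then input channel).

# gather index for 3x3/pad-1 im2col at spatial size H x W with C channels:
# column kc = k + 9*(c-1), k = dh + 3*(dw-1), dh/dw in 1..3
im2col_index <- function(H, W, C) {
  Hp <- H + 2L; Wp <- W + 2L
  hw_h <- rep(seq_len(H), times = W)
  hw_w <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L * C)
  for (c in seq_len(C)) for (dw in 1:3) for (dh in 1:3) {
    k <- dh + 3L * (dw - 1L)
    ph <- hw_h + dh - 1L
    pw <- hw_w + dw - 1L
    idx[, k + 9L * (c - 1L)] <- ph + Hp * (pw - 1L) + Hp * Wp * (c - 1L)
  }
  idx
}

pad1 <- function(x) {
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  xp[, 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- x
  xp
}

conv3_fwd <- function(x, W, b, idx = NULL) {
  d <- dim(x)   # B H W C
  if (is.null(idx)) idx <- im2col_index(d[2], d[3], d[4])
  xp <- pad1(x)
  Xp_m <- matrix(xp, d[1], length(xp) / d[1])
  Xc <- Xp_m[, as.vector(idx), drop = FALSE]
  dim(Xc) <- c(d[1] * d[2] * d[3], 9L * d[4])
  Cout <- ncol(W)
  y <- Xc %*% W
  y <- sweep(y, 2, b, "+")
  dim(y) <- c(d[1], d[2], d[3], Cout)
  list(y = y, cache = list(Xc = Xc, dims = d, W = W))
}

conv3_bwd <- function(dy, cache) {
  d <- cache$dims
  Cout <- ncol(cache$W)
  dy_m <- dy
  dim(dy_m) <- c(d[1] * d[2] * d[3], Cout)
  dW <- crossprod(cache$Xc, dy_m)
  db <- colSums(dy_m)
  dXc <- tcrossprod(dy_m, cache$W)          # (B*H*W) x 9C
  dim(dXc) <- c(d[1], d[2], d[3], 9L, d[4])
  dXp <- array(0, dim = c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  for (dw in 1:3) for (dh in 1:3) {
    k <- dh + 3L * (dw - 1L)
    hr <- dh:(dh + d[2] - 1L)
    wr <- dw:(dw + d[3] - 1L)
    dXp[, hr, wr, ] <- dXp[, hr, wr, ] + dXc[, , , k, ]
  }
  dx <- dXp[, 2:(d[2] + 1L), 2:(d[3] + 1L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  y <- sweep(xm %*% W, 2, b, "+")
  dim(y) <- c(d[1], d[2], d[3], ncol(W))
  list(y = y, cache = list(xm = xm, dims = d, W = W))
}

conv1_bwd <- function(dy, cache) {
  d <- cache$dims
  dy_m <- dy
  dim(dy_m) <- c(d[1] * d[2] * d[3], ncol(cache$W))
  dW <- crossprod(cache$xm, dy_m)
  db <- colSums(dy_m)
  dx <- tcrossprod(dy_m, cache$W)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = list(x = x, s = s))
}

silu_bwd <- function(dy, cache) {
  s <- cache$s
  dy * (s * (1 + cache$x * (1 - s)))
}

avgpool2_fwd <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[2], by = 2L); o2 <- o1 + 1L
  w1 <- seq(1L, d[3], by = 2L); w2 <- w1 + 1L
  y <- (x[, o1, w1, , drop = FALSE] + x[, o2, w1, , drop = FALSE] +
        x[, o1, w2, , drop = FALSE] + x[, o2, w2, , drop = FALSE]) / 4
  list(y = y, cache = d)
}

avgpool2_bwd <- function(dy, d) {
  dx <- array(0, dim = d)
  o1 <- seq(1L, d[2], by = 2L); o2 <- o1 + 1L
  w1 <- seq(1L, d[3], by = 2L); w2 <- w1 + 1L
  g <- dy / 4
  dx[, o1, w1, ] <- g; dx[, o2, w1, ] <- g
  dx[, o1, w2, ] <- g; dx[, o2, w2, ] <- g
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  y <- x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
         drop = FALSE]
  list(y = y, cache = d)
}

upsample2_bwd <- function(dy, d) {
  o1 <- seq(1L, 2L * d[2], by = 2L); o2 <- o1 + 1L
  w1 <- seq(1L, 2L * d[3], by = 2L); w2 <- w1 + 1L
  dy[, o1, w1, , drop = FALSE] + dy[, o2, w1, , drop = FALSE] +
    dy[, o1, w2, , drop = FALSE] + dy[, o2, w2, , drop = FALSE]
}

linear_fwd <- function(x, W, b) {
  list(y = sweep(x %*% W, 2, b, "+"), cache = list(x = x, W = W))
}

linear_bwd <- function(dy, cache) {
  list(dx = tcrossprod(dy, cache$W),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

# Adam optimizer over a flat named list of numeric arrays
adam_init <- function(params, lr = 2e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  zeros <- lapply(params, function(p) {p[] <- 0; p})
  list(m = zeros, v = zeros, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps)
}

adam_step <- function(params, grads, opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(params = params, opt = opt)
}

# accumulate gradient into a flat grad list
acc_grad <- function(grads, nm, g) {
  grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  grads
}
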