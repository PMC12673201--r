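# Internal layer primitives for the two-block 3D CNN.
#
# Activations are stored as 5-D arrays laid out (D, H, W, N, C): spatial dims
# first, then batch, then channels. With that layout a reshape to a matrix
# with one column per channel is free (column-major order), so convolutions
# become im2col + GEMM and batch norm becomes column-wise arithmetic, both of
# which the BLAS handles efficiently. Column-wise scale/shift is done with
# rep(v, each = nrow) rather than sweep(), which would aperm-copy the array.

col_rep <- function(v, m) rep(v, each = m)

pad_spatial <- function(x, p, value = 0) {
  d <- dim(x)
  out <- array(value, c(d[1:3] + 2L * p, d[4], d[5]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), , ] <- x
  out
}

conv_offsets <- function(k) as.matrix(expand.grid(a = 0:(k - 1), b = 0:(k - 1), c = 0:(k - 1)))

# im2col: rows index (d, h, w, n), column blocks index (offset, cin).
im2col3 <- function(xp, out_dims, k) {
  D <- out_dims[1]; H <- out_dims[2]; W <- out_dims[3]
  N <- out_dims[4]; Cin <- out_dims[5]
  offs <- conv_offsets(k)
  P <- matrix(0, D * H * W * N, k^3 * Cin)
  for (o in seq_len(nrow(offs))) {
    s <- xp[offs[o, 1] + seq_len(D), offs[o, 2] + seq_len(H),
            offs[o, 3] + seq_len(W), , , drop = FALSE]
    P[, (o - 1L) * Cin + seq_len(Cin)] <- s
  }
  P
}

# Same-padding 3D convolution. W is (k^3 * Cin) x Cout with rows ordered
# (cin within offset, offsets in conv_offsets() order); b has length Cout.
conv3_forward <- function(x, W, b, k) {
  d <- dim(x)
  p <- (k - 1L) %/% 2L
  P <- im2col3(pad_spatial(x, p), d, k)
  Y <- P %*% W
  Y <- Y + col_rep(b, nrow(Y))
  dim(Y) <- c(d[1:4], ncol(W))
  list(y = Y, P = P, in_dims = d)
}

conv3_backward <- function(gy, fwd, W, k, compute_gx = TRUE) {
  d <- fwd$in_dims
  Cout <- ncol(W)
  gY <- gy
  dim(gY) <- c(length(gy) %/% Cout, Cout)
  gW <- crossprod(fwd$P, gY)
  gb <- colSums(gY)
  gx <- NULL
  if (compute_gx) {
    p <- (k - 1L) %/% 2L
    gP <- tcrossprod(gY, W)
    offs <- conv_offsets(k)
    Cin <- d[5]
    gxp <- array(0, c(d[1:3] + 2L * p, d[4], d[5]))
    for (o in seq_len(nrow(offs))) {
      blk <- gP[, (o - 1L) * Cin + seq_len(Cin), drop = FALSE]
      dim(blk) <- c(d[1:4], Cin)
      ia <- offs[o, 1] + seq_len(d[1])
      ib <- offs[o, 2] + seq_len(d[2])
      ic <- offs[o, 3] + seq_len(d[3])
      gxp[ia, ib, ic, , ] <- gxp[ia, ib, ic, , , drop = FALSE] + blk
    }
    gx <- gxp[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), , ,
              drop = FALSE]
  }
  list(gx = gx, gW = gW, gb = gb)
}

bn_eps <- 1e-5

bn_forward <- function(x, bn, training, momentum = 0.1) {
  d <- dim(x)
  C <- d[5]
  m <- length(x) %/% C
  xm <- x
  dim(xm) <- c(m, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - col_rep(mu, m)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + bn_eps)
    xhat <- xc * col_rep(istd, m)
    run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    run_var <- (1 - momentum) * bn$run_var + momentum * v
  } else {
    istd <- 1 / sqrt(bn$run_var + bn_eps)
    xhat <- (xm - col_rep(bn$run_mean, m)) * col_rep(istd, m)
    run_mean <- bn$run_mean
    run_var <- bn$run_var
  }
  y <- xhat * col_rep(bn$gamma, m) + col_rep(bn$beta, m)
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(gy, fwd, gamma) {
  d <- dim(gy)
  C <- d[5]
  m <- length(gy) %/% C
  gym <- gy
  dim(gym) <- c(m, C)
  ggamma <- colSums(gym * fwd$xhat)
  gbeta <- colSums(gym)
  gxhat <- gym * col_rep(gamma, m)
  gx <- gxhat - col_rep(colSums(gxhat) / m, m) -
    fwd$xhat * col_rep(colSums(gxhat * fwd$xhat) / m, m)
  gx <- gx * col_rep(fwd$istd, m)
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# Max pooling, window 2, stride 2, ceil mode (odd sides padded with -Inf so
# 21 -> 11 and 11 -> 6). Ties go to the earliest window offset, so the
# backward pass routes each output gradient to exactly one input voxel.
maxpool2_forward <- function(x) {
  d <- dim(x)
  Dp <- d[1:3] + d[1:3] %% 2L
  xp <- array(-Inf, c(Dp, d[4], d[5]))
  xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), , ] <- x
  ia <- seq(1L, Dp[1], 2L); ib <- seq(1L, Dp[2], 2L); ic <- seq(1L, Dp[3], 2L)
  offs <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  best <- NULL; arg <- NULL
  for (o in 1:8) {
    s <- xp[ia + offs[o, 1], ib + offs[o, 2], ic + offs[o, 3], , , drop = FALSE]
    if (o == 1) {
      best <- s
      arg <- array(1L, dim(s))
    } else {
      u <- s > best
      best[u] <- s[u]
      arg[u] <- o
    }
  }
  list(y = best, arg = arg, in_dims = d)
}

maxpool2_backward <- function(gy, fwd) {
  d <- fwd$in_dims
  Dp <- d[1:3] + d[1:3] %% 2L
  gxp <- array(0, c(Dp, d[4], d[5]))
  ia <- seq(1L, Dp[1], 2L); ib <- seq(1L, Dp[2], 2L); ic <- seq(1L, Dp[3], 2L)
  offs <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  for (o in 1:8) {
    g <- gy
    g[fwd$arg != o] <- 0
    gxp[ia + offs[o, 1], ib + offs[o, 2], ic + offs[o, 3], , ] <- g
  }
  gxp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), , , drop = FALSE]
}

# Fully connected layer over flattened (spatial x channel) features.
fc_forward <- function(x, W, b) {
  d <- dim(x)
  N <- d[4]
  X <- t(matrix(aperm(x, c(1, 2, 3, 5, 4)), ncol = N))
  Z <- X %*% W
  Z <- Z + col_rep(b, N)
  list(z = Z, X = X, in_dims = d)
}

fc_backward <- function(gz, fwd, W) {
  d <- fwd$in_dims
  gW <- crossprod(fwd$X, gz)
  gb <- colSums(gz)
  gX <- tcrossprod(gz, W)
  gx <- aperm(array(t(gX), c(d[1:3], d[5], d[4])), c(1, 2, 3, 5, 4))
  list(gx = gx, gW = gW, gb = gb)
}

softmax_rows <- function(z) {
  mx <- do.call(pmax, lapply(seq_len(ncol(z)), function(j) z[, j]))
  e <- exp(z - mx)
  e / rowSums(e)
}

relu <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

# Full forward pass over a batch laid out (21, 21, 21, N, 1).
net_forward_batch <- function(x, params, config, training = FALSE,
                              keep_cache = FALSE) {
  k <- config$conv_kernel
  c1 <- conv3_forward(x, params$conv1$W, params$conv1$b, k)
  b1 <- bn_forward(c1$y, params$bn1, training)
  r1 <- relu(b1$y)
  p1 <- maxpool2_forward(r1)
  side1 <- dim(p1$y)[1]
  gwt <- as.vector(build_gaussian_weight(side1, config$gaussian_sd,
                                         config$gaussian_peak))
  w1 <- p1$y * gwt
  c2 <- conv3_forward(w1, params$conv2$W, params$conv2$b, k)
  b2 <- bn_forward(c2$y, params$bn2, training)
  r2 <- relu(b2$y)
  p2 <- maxpool2_forward(r2)
  fc <- fc_forward(p2$y, params$fc$W, params$fc$b)
  probs <- softmax_rows(fc$z)
  out <- list(probs = probs,
              run_stats = list(bn1 = b1[c("run_mean", "run_var")],
                               bn2 = b2[c("run_mean", "run_var")]))
  if (keep_cache) {
    out$cache <- list(c1 = c1, b1 = b1, r1 = r1, p1 = p1, gwt = gwt,
                      c2 = c2, b2 = b2, r2 = r2, p2 = p2, fc = fc, k = k)
  }
  out
}

# Backward pass for the weighted cross-entropy objective:
# d(loss)/d(logits) for example i is w_i * (probs_i - onehot_i) / n.
net_backward_batch <- function(fwd, t_onehot, wts, params) {
  cache <- fwd$cache
  n <- nrow(t_onehot)
  gz <- (fwd$probs - t_onehot) * (wts / n)
  g_fc <- fc_backward(gz, cache$fc, params$fc$W)
  g_p2 <- maxpool2_backward(g_fc$gx, cache$p2)
  g_r2 <- g_p2 * (cache$r2 > 0)
  g_b2 <- bn_backward(g_r2, cache$b2, params$bn2$gamma)
  g_c2 <- conv3_backward(g_b2$gx, cache$c2, params$conv2$W, cache$k)
  g_w1 <- g_c2$gx * cache$gwt
  g_p1 <- maxpool2_backward(g_w1, cache$p1)
  g_r1 <- g_p1 * (cache$r1 > 0)
  g_b1 <- bn_backward(g_r1, cache$b1, params$bn1$gamma)
  g_c1 <- conv3_backward(g_b1$gx, cache$c1, params$conv1$W, cache$k,
                         compute_gx = FALSE)
  list(
    conv1 = list(W = g_c1$gW, b = g_c1$gb),
    bn1 = list(gamma = g_b1$ggamma, beta = g_b1$gbeta),
    conv2 = list(W = g_c2$gW, b = g_c2$gb),
    bn2 = list(gamma = g_b2$ggamma, beta = g_b2$gbeta),
    fc = list(W = g_fc$gW, b = g_fc$gb)
  )
}

# Stack a list of 21^3 arrays into the (21, 21, 21, N, 1) batch layout.
stack_vois <- function(values) {
  n <- length(values)
  d <- dim(values[[1]])
  x <- array(0, c(d, n, 1L))
  for (i in seq_len(n)) x[, , , i, 1] <- values[[i]]
  x
}
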