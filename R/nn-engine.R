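#' @useDynLib neuroqpi nq_conv3_fwd nq_conv3_dw
NULL

# Minimal CNN engine used by the residual U-Net.
#
# Activations for a batch of B images of size H x W with C channels are
# stored as (B*H*W) x C matrices, column-major within each image
# (row index = (b-1)*H*W + (col-1)*H + row).  A 3x3 same-padding
# convolution is nine shifted matrix products computed by a fused, tiled
# dgemm kernel in C (src/conv3.c); pooling, batch norm, activations and
# the loss stay in R.  Weight matrices are (9*Cin) x Cout with shift-major
# blocks: rows [(k-1)*Cin+1, k*Cin] hold the kernel tap for shift k
# (offsets enumerated (di, dj) in {-1,0,1}^2, di fastest, so tap 10-k is
# the spatial opposite of tap k).

# cache of geometry descriptors keyed by "H_W_B"
.nn_cache <- new.env(parent = emptyenv())

nn_geometry <- function(H, W, B) {
  H <- as.integer(H); W <- as.integer(W); B <- as.integer(B)
  key <- paste(H, W, B, sep = "_")
  g <- .nn_cache[[key]]
  if (!is.null(g)) return(g)
  N <- B * H * W
  iv <- rep.int(rep.int(seq_len(H), W), B)
  jv <- rep.int(rep(seq_len(W), each = H), B)
  r <- seq_len(N)
  offs <- integer(9); lo <- integer(9); hi <- integer(9)
  bad <- vector("list", 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    o <- di + dj * H
    offs[k] <- o
    lo[k] <- max(1L, 1L - o)
    hi[k] <- min(N, N - o)
    ok <- iv + di >= 1L & iv + di <= H & jv + dj >= 1L & jv + dj <= W
    bad[[k]] <- r[!ok & r >= lo[k] & r <= hi[k]]
  }
  # 2x2 max pooling: index of each corner of each block, pooled-image order
  H2 <- H %/% 2L; W2 <- W %/% 2L
  i2 <- rep.int(rep.int(seq_len(H2), W2), B)
  j2 <- rep.int(rep(seq_len(W2), each = H2), B)
  b2 <- rep(seq_len(B), each = H2 * W2)
  corner <- function(di, dj)
    (b2 - 1L) * (H * W) + (2L * j2 - 2L + dj - 1L) * H + (2L * i2 - 2L + di)
  pool <- list(corner(1L, 1L), corner(2L, 1L), corner(1L, 2L), corner(2L, 2L))
  # zero-stuffing positions for stride-2 transpose convolution:
  # pixel (i,j) of the small image sits at (2i-1, 2j-1) of the doubled grid
  up <- (rep(seq_len(B), each = H * W) - 1L) * (4L * H * W) +
    (2L * jv - 2L) * (2L * H) + (2L * iv - 1L)
  g <- list(H = H, W = W, B = B, N = N, offs = offs, lo = lo, hi = hi,
            bad = bad, pool = pool, up = up)
  .nn_cache[[key]] <- g
  g
}

glorot_uniform <- function(n_in, n_out, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

new_conv <- function(cin, cout) {
  list(W = glorot_uniform(9 * cin, cout, 9 * cin, 9 * cout),
       b = numeric(cout), cin = cin, cout = cout)
}

new_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       moving_mean = numeric(c), moving_var = rep(1, c))
}

conv_fwd <- function(X, conv, geom) {
  .Call(nq_conv3_fwd, X, conv$W, geom$offs, geom$lo, geom$hi, geom$bad,
        conv$b)
}

# Weight matrix of the gradient convolution: block j is t(W[10-j]), the
# transposed spatially-opposite tap, so dX = conv(dY, Wback) with the
# ordinary forward shifts.
conv_wback <- function(conv) {
  cin <- conv$cin; cout <- conv$cout
  Wb <- matrix(0, 9 * cout, cin)
  for (k in 1:9)
    Wb[((k - 1) * cout + 1):(k * cout), ] <-
      t(conv$W[((9 - k) * cin + 1):((10 - k) * cin), , drop = FALSE])
  Wb
}

# returns list(dX, dW, db); X is the cached layer input
conv_bwd <- function(dY, X, conv, geom) {
  dW <- .Call(nq_conv3_dw, X, dY, geom$offs, geom$lo, geom$hi, geom$bad)
  db <- colSums(dY)
  dX <- .Call(nq_conv3_fwd, dY, conv_wback(conv), geom$offs, geom$lo,
              geom$hi, geom$bad, NULL)
  list(dX = dX, dW = dW, db = db)
}

relu_fwd <- function(X) { X[X < 0] <- 0; X }
relu_bwd <- function(dY, Xpre) { dY[Xpre <= 0] <- 0; dY }

maxpool_fwd <- function(X, geom) {
  xs <- lapply(geom$pool, function(ix) X[ix, , drop = FALSE])
  cur <- xs[[1]]
  arg <- matrix(1L, nrow(cur), ncol(cur))
  for (k in 2:4) {
    upd <- xs[[k]] > cur
    arg[upd] <- k
    cur[upd] <- xs[[k]][upd]
  }
  list(Y = cur, arg = arg)
}

maxpool_bwd <- function(dY, arg, geom) {
  N <- geom$N
  M <- nrow(dY)
  dX <- matrix(0, N, ncol(dY))
  for (k in 1:4) {
    wh <- which(arg == k)
    if (!length(wh)) next
    r <- ((wh - 1L) %% M) + 1L
    cc <- ((wh - 1L) %/% M) + 1L
    dX[(cc - 1L) * N + geom$pool[[k]][r]] <- dY[wh]
  }
  dX
}

# stride-2 3x3 transpose convolution via zero-stuffing + ordinary conv
upconv_fwd <- function(X, conv, geom_small, geom_big) {
  Z <- matrix(0, geom_big$N, ncol(X))
  Z[geom_small$up, ] <- X
  list(Y = conv_fwd(Z, conv, geom_big), Z = Z)
}

upconv_bwd <- function(dY, Z, conv, geom_small, geom_big) {
  g <- conv_bwd(dY, Z, conv, geom_big)
  list(dX = g$dX[geom_small$up, , drop = FALSE], dW = g$dW, db = g$db)
}

bn_fwd <- function(X, bn, training, eps = 1e-3) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    Xc <- X - matrix(mu, n, length(mu), byrow = TRUE)
    v <- colMeans(Xc * Xc)
  } else {
    mu <- bn$moving_mean; v <- bn$moving_var
    Xc <- X - matrix(mu, n, length(mu), byrow = TRUE)
  }
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * matrix(inv, n, length(inv), byrow = TRUE)
  Y <- Xhat * matrix(bn$gamma, n, length(inv), byrow = TRUE) +
    matrix(bn$beta, n, length(inv), byrow = TRUE)
  list(Y = Y, Xhat = Xhat, inv = inv, mu = mu, v = v)
}

bn_bwd <- function(dY, cache, bn) {
  n <- nrow(dY); C <- ncol(dY)
  Xhat <- cache$Xhat
  dgamma <- colSums(dY * Xhat)
  dbeta <- colSums(dY)
  dXhat <- dY * matrix(bn$gamma, n, C, byrow = TRUE)
  t1 <- matrix(colSums(dXhat), n, C, byrow = TRUE)
  t2 <- Xhat * matrix(colSums(dXhat * Xhat), n, C, byrow = TRUE)
  dX <- (dXhat - t1 / n - t2 / n) * matrix(cache$inv, n, C, byrow = TRUE)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

bn_update_moving <- function(bn, cache, momentum = 0.9) {
  bn$moving_mean <- momentum * bn$moving_mean + (1 - momentum) * cache$mu
  bn$moving_var <- momentum * bn$moving_var + (1 - momentum) * cache$v
  bn
}

softmax_rows <- function(X) {
  m <- do.call(pmax, as.data.frame(X))
  E <- exp(X - m)
  E / rowSums(E)
}
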