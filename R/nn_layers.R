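# Layer primitives for the BLAS-based CNN engine.
#
# Activations are dense matrices with one row per pixel and one column per
# channel. Rows are grouped sample-major; within a sample the H x W pixels
# are column-major. Convolutions are evaluated as sums of shifted-input
# matrix products, so all heavy lifting is gemm.

.nn_cache <- new.env(parent = emptyenv())

# Index vectors mapping output pixels to shifted input pixels for a 3x3
# padded convolution, against a 1-row zero-padded activation matrix: entry 1
# is the zero row, input pixel p sits at row p + 1. One vector per (dr, dc)
# offset; offset 5 is the identity.
conv_indices <- function(H, W, N) {
  key <- paste("conv", H, W, N, sep = ".")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  ii <- rep(seq_len(H), W)
  jj <- rep(seq_len(W), each = H)
  samp <- rep((seq_len(N) - 1L) * H * W, each = H * W)
  idx <- vector("list", 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    si <- ii + dr; sj <- jj + dc
    base <- ifelse(si >= 1L & si <= H & sj >= 1L & sj <= W,
                   (sj - 1L) * H + si, NA_integer_)
    ik <- rep(base, N) + samp + 1L
    ik[is.na(ik)] <- 1L
    idx[[k]] <- ik
  }
  .nn_cache[[key]] <- idx
  idx
}

# 2x2 max-pool candidate indices: 4 vectors, each length (H/2)(W/2)N.
pool_indices <- function(H, W, N) {
  key <- paste("pool", H, W, N, sep = ".")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  io <- rep(seq_len(Ho), Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  samp <- rep((seq_len(N) - 1L) * H * W, each = Ho * Wo)
  mk <- function(dr, dc) rep((2L * jo - 2L + dc) * H + (2L * io - 1L + dr), N) + samp
  out <- list(mk(0L, 0L), mk(1L, 0L), mk(0L, 1L), mk(1L, 1L))
  .nn_cache[[key]] <- out
  out
}

# Row-interpolation matrix for factor-2 bilinear upsampling (half-pixel
# convention, edges clamped). Used separably for rows and columns.
upsample2_matrix <- function(n_in) {
  key <- paste("up", n_in, sep = ".")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  n_out <- 2L * n_in
  R <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) / 2 + 0.5
    r0 <- floor(s); f <- s - r0
    r0c <- min(max(r0, 1L), n_in); r1c <- min(max(r0 + 1L), n_in)
    R[i, r0c] <- R[i, r0c] + (1 - f)
    R[i, r1c] <- R[i, r1c] + f
  }
  .nn_cache[[key]] <- R
  R
}

# ---- conv 3x3, padding 1 --------------------------------------------------
# No bias: every conv is followed by batch normalization, whose beta
# subsumes it.

conv_init <- function(c_in, c_out, gain = 2) {
  sd <- sqrt(gain / (9 * c_in))
  W <- lapply(seq_len(9L), function(k)
    matrix(stats::rnorm(c_in * c_out, 0, sd), c_in, c_out))
  list(W = W)
}

conv_fwd <- function(X, par, idx) {
  Xp <- rbind(0, X)
  out <- X %*% par$W[[5L]]   # identity offset
  for (k in c(1:4, 6:9))
    out <- out + Xp[idx[[k]], , drop = FALSE] %*% par$W[[k]]
  out
}

# The input gradient of a zero-padded "same" convolution is the "same"
# convolution of dOut with the mirrored, transposed kernel: offset k in the
# (dc, dr) enumeration mirrors to offset 10 - k.
conv_bwd <- function(dOut, X, par, idx) {
  Xp <- rbind(0, X)
  dOp <- rbind(0, dOut)
  dW <- vector("list", 9L)
  dW[[5L]] <- crossprod(X, dOut)
  dX <- dOut %*% t(par$W[[5L]])
  for (k in c(1:4, 6:9)) {
    dW[[k]] <- crossprod(Xp[idx[[k]], , drop = FALSE], dOut)
    dX <- dX + dOp[idx[[10L - k]], , drop = FALSE] %*% t(par$W[[k]])
  }
  list(dX = dX, grad = list(W = dW))
}

# ---- 1x1 conv head --------------------------------------------------------

# Optional prior: initial head bias = log class prior, so an untrained net
# already predicts the background-dominated class frequencies. With rare
# foreground classes this directs the first gradients at lesion pixels
# instead of spending epochs crushing background logits.
head_init <- function(c_in, c_out, prior = NULL) {
  b <- if (is.null(prior)) numeric(c_out) else {
    stopifnot(length(prior) == c_out, all(prior > 0))
    log(prior / sum(prior))
  }
  list(W = matrix(stats::rnorm(c_in * c_out, 0, sqrt(2 / c_in)), c_in, c_out),
       b = b)
}

head_fwd <- function(X, par) sweep(X %*% par$W, 2L, par$b, "+")

head_bwd <- function(dOut, X, par) {
  list(dX = dOut %*% t(par$W),
       grad = list(W = crossprod(X, dOut), b = colSums(dOut)))
}

# ---- batch normalization --------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_init <- function(c_out) {
  list(gamma = rep(1, c_out), beta = numeric(c_out))
}

bn_state_init <- function(c_out) {
  list(mean = numeric(c_out), var = rep(1, c_out))
}

# column-wise (per-channel) broadcast helper; faster than sweep()
col_bcast <- function(v, m) rep.int(v, rep.int(m, length(v)))

bn_fwd <- function(X, par, state, train) {
  m <- nrow(X); n <- ncol(X)
  if (train) {
    mu <- .colMeans(X, m, n)
    Xc <- X - col_bcast(mu, m)
    v <- .colMeans(Xc * Xc, m, n)
    state$mean <- (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * mu
    state$var <- (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * v
  } else {
    mu <- state$mean; v <- state$var
    Xc <- X - col_bcast(mu, m)
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  Xh <- Xc * col_bcast(inv_sd, m)
  Y <- Xh * col_bcast(par$gamma, m) + col_bcast(par$beta, m)
  list(out = Y, cache = list(Xh = Xh, inv_sd = inv_sd), state = state)
}

bn_bwd <- function(dY, cache, par) {
  m <- nrow(dY)
  Xh <- cache$Xh
  dgamma <- colSums(dY * Xh)
  dbeta <- colSums(dY)
  dXh <- dY * col_bcast(par$gamma, m)
  # standard batchnorm backward in normalized coordinates
  t1 <- dXh - col_bcast(colSums(dXh) / m, m)
  t2 <- Xh * col_bcast(colSums(dXh * Xh) / m, m)
  dX <- (t1 - t2) * col_bcast(cache$inv_sd, m)
  list(dX = dX, grad = list(gamma = dgamma, beta = dbeta))
}

# ---- relu -----------------------------------------------------------------

relu_fwd <- function(X) {
  X[X < 0] <- 0
  X
}

relu_bwd <- function(dY, Y) {
  dY[Y <= 0] <- 0
  dY
}

# ---- 2x2 max pool ---------------------------------------------------------

pool_fwd <- function(X, idx4) {
  A1 <- X[idx4[[1L]], , drop = FALSE]
  best <- A1
  arg <- matrix(1L, nrow(A1), ncol(A1))
  for (s in 2:4) {
    As <- X[idx4[[s]], , drop = FALSE]
    upd <- As > best
    best[upd] <- As[upd]
    arg[upd] <- s
  }
  list(out = best, arg = arg)
}

pool_bwd <- function(dOut, arg, idx4, n_in) {
  dX <- matrix(0, n_in, ncol(dOut))
  for (s in 1:4) {
    sel <- arg == s
    if (!any(sel)) next
    tmp <- dOut * sel
    dX[idx4[[s]], ] <- dX[idx4[[s]], , drop = FALSE] + tmp
  }
  dX
}

# ---- factor-2 bilinear upsample ------------------------------------------

up_fwd <- function(X, H, W, N) {
  R <- upsample2_matrix(H); Cm <- upsample2_matrix(W)
  C <- ncol(X)
  out <- matrix(0, 4L * H * W * N, C)
  hw <- H * W; HW2 <- 4L * hw
  for (n in seq_len(N)) {
    rows_in <- (n - 1L) * hw + seq_len(hw)
    rows_out <- (n - 1L) * HW2 + seq_len(HW2)
    for (ch in seq_len(C)) {
      M <- matrix(X[rows_in, ch], H, W)
      out[rows_out, ch] <- R %*% M %*% t(Cm)
    }
  }
  out
}

up_bwd <- function(dOut, H, W, N) {
  R <- upsample2_matrix(H); Cm <- upsample2_matrix(W)
  C <- ncol(dOut)
  dX <- matrix(0, H * W * N, C)
  hw <- H * W; HW2 <- 4L * hw
  for (n in seq_len(N)) {
    rows_in <- (n - 1L) * hw + seq_len(hw)
    rows_out <- (n - 1L) * HW2 + seq_len(HW2)
    for (ch in seq_len(C)) {
      M <- matrix(dOut[rows_out, ch], 2L * H, 2L * W)
      dX[rows_in, ch] <- crossprod(R, M) %*% Cm
    }
  }
  dX
}

# ---- softmax --------------------------------------------------------------

softmax_rows <- function(L) {
  mx <- L[, 1L]
  for (k in 2:ncol(L)) mx <- pmax(mx, L[, k])
  E <- exp(L - mx)
  E / rowSums(E)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = opt$t))
}
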