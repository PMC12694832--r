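# Low-level tensor operations for the network engine.
#
# Activation tensors are stored as dense matrices of shape (N*H*W) x C with
# rows ordered image-major, then row-major within an image:
#   row(n, r, c) = (n-1)*H*W + (r-1)*W + c        (1-based)
# Convolutions are evaluated as sums of shifted GEMMs: for each kernel
# offset a row-gather of the input (with a shared all-zero padding row)
# is multiplied by the corresponding C x Cout weight slab.  All gathers
# use precomputed integer index vectors cached per (H, W, N).

.idx_cache <- new.env(parent = emptyenv())

#' @noRd
.cache_get <- function(key, builder) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .idx_cache)
  }
  v
}

# Index of source pixel (r+dy, c+dx) for each output pixel, 0 when outside.
.shift_index1 <- function(H, W, dy, dx) {
  r <- rep(seq_len(H), each = W) + dy
  c <- rep(seq_len(W), times = H) + dx
  ok <- r >= 1L & r <= H & c >= 1L & c <= W
  idx <- ifelse(ok, (r - 1L) * W + c, 0L)
  as.integer(idx)
}

# Batched shift index; zero entries point at the appended all-zero row.
.shift_index <- function(H, W, N, dy, dx) {
  key <- sprintf("s:%d:%d:%d:%d:%d", H, W, N, dy, dx)
  .cache_get(key, function() {
    base <- .shift_index1(H, W, dy, dx)
    HW <- H * W
    zero_row <- N * HW + 1L
    out <- integer(N * HW)
    for (n in seq_len(N)) {
      b <- base
      b[b > 0L] <- b[b > 0L] + (n - 1L) * HW
      b[b == 0L] <- zero_row
      out[((n - 1L) * HW + 1L):(n * HW)] <- b
    }
    out
  })
}

# Offsets for a 3x3 kernel, dy-major; slab k and slab 10-k are opposite.
.OFF3 <- cbind(dy = rep(-1:1, each = 3), dx = rep(-1:1, times = 3))

# Add a per-column bias in place-ish (cheaper than matrix(byrow = TRUE)).
.add_bias <- function(y, b) {
  if (all(b == 0)) return(y)
  y + rep(b, each = nrow(y))
}

# Gathered patch matrix (N*H*W) x (9*C): column block k holds the input
# shifted by kernel offset k (zero padding via the appended zero row).
.im2col3 <- function(x, H, Wd, N) {
  xa <- rbind(x, 0)
  do.call(cbind, lapply(1:9, function(k)
    xa[.shift_index(H, Wd, N, .OFF3[k, 1], .OFF3[k, 2]), , drop = FALSE]))
}

# 3x3 same-padding convolution, forward (compiled kernel).
# x is (N*H*W) x C; W is (9*C) x Cout; b the bias.
#' @noRd
conv3_fwd <- function(x, W, b, H, Wd, N) {
  cpp_conv3_fwd(x, W, b, H, Wd, N)
}

#' @noRd
conv3_bwd <- function(dy, x, W, H, Wd, N, need_dx = TRUE) {
  r <- cpp_conv3_bwd(dy, x, W, H, Wd, N, need_dx)
  list(dx = r$dx, dW = r$dW, db = as.numeric(r$db))
}

#' 1x1 convolution (pure channel mixing).
#' @noRd
conv1_fwd <- function(x, W, b) {
  y <- x %*% W
  if (!is.null(b)) y <- .add_bias(y, b)
  y
}

#' @noRd
conv1_bwd <- function(dy, x, W, need_dx = TRUE) {
  list(dx = if (need_dx) dy %*% t(W) else NULL,
       dW = crossprod(x, dy), db = colSums(dy))
}

# Gather index for stride-2 2x2 downsampling: output pixel (r,c) of the
# (H/2, W/2) grid reads input pixel (2r-1+dy, 2c-1+dx), dy,dx in {0,1}.
.down_index <- function(H, W, N, k) {
  dy <- c(0L, 0L, 1L, 1L)[k]; dx <- c(0L, 1L, 0L, 1L)[k]
  key <- sprintf("d:%d:%d:%d:%d", H, W, N, k)
  .cache_get(key, function() {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    r <- rep(seq_len(H2), each = W2) * 2L - 1L + dy
    c <- rep(seq_len(W2), times = H2) * 2L - 1L + dx
    base <- (r - 1L) * W + c
    HW <- H * W
    as.integer(rep(base, times = N) + rep((seq_len(N) - 1L) * HW, each = H2 * W2))
  })
}

# Strided 2x2 convolution (stride 2): the between-area downsampling step.
# W is (4*C) x Cout.
#' @noRd
down2_fwd <- function(x, W, b, H, Wd, N) {
  C <- ncol(x); Cout <- ncol(W)
  H2 <- H %/% 2L; W2 <- Wd %/% 2L
  P <- do.call(cbind, lapply(1:4, function(k)
    x[.down_index(H, Wd, N, k), , drop = FALSE]))
  .add_bias(P %*% W, b)
}

#' @noRd
down2_bwd <- function(dy, x, W, H, Wd, N, need_dx = TRUE) {
  C <- ncol(x); Cout <- ncol(W)
  dW <- matrix(0, nrow(W), Cout)
  dx <- if (need_dx) matrix(0, nrow(x), C) else NULL
  for (k in 1:4) {
    idx <- .down_index(H, Wd, N, k)
    rows <- ((k - 1L) * C + 1L):(k * C)
    dW[rows, ] <- crossprod(x[idx, , drop = FALSE], dy)
    # each input pixel feeds exactly one output pixel: plain assignment
    if (need_dx) dx[idx, ] <- dy %*% t(W[rows, , drop = FALSE])
  }
  list(dx = dx, dW = dW, db = colSums(dy))
}

# Scatter index for stride-2 2x2 transposed convolution: input pixel (r,c)
# of the (h,w) grid writes output pixel (2r-1+dy, 2c-1+dx) of the (2h,2w)
# grid.  The four offset sets partition the output exactly.
.up_index <- function(h, w, N, k) {
  dy <- c(0L, 0L, 1L, 1L)[k]; dx <- c(0L, 1L, 0L, 1L)[k]
  key <- sprintf("u:%d:%d:%d:%d", h, w, N, k)
  .cache_get(key, function() {
    W2 <- 2L * w
    r <- rep(seq_len(h), each = w) * 2L - 1L + dy
    c <- rep(seq_len(w), times = h) * 2L - 1L + dx
    base <- (r - 1L) * W2 + c
    as.integer(rep(base, times = N) + rep((seq_len(N) - 1L) * 4L * h * w, each = h * w))
  })
}

# Transposed convolution, kernel 2x2, stride 2 (between-area upsampling).
# W is C x (4*Cout), block k in columns ((k-1)*Cout+1):(k*Cout).
#' @noRd
up2_fwd <- function(x, W, b, h, w, N) {
  Cout <- ncol(W) %/% 4L
  P <- x %*% W
  y <- matrix(0, N * 4L * h * w, Cout)
  for (k in 1:4) {
    idx <- .up_index(h, w, N, k)
    y[idx, ] <- P[, ((k - 1L) * Cout + 1L):(k * Cout), drop = FALSE]
  }
  .add_bias(y, b)
}

#' @noRd
up2_bwd <- function(dy, x, W, h, w, N, need_dx = TRUE) {
  Cout <- ncol(W) %/% 4L
  dW <- matrix(0, nrow(W), ncol(W))
  dx <- if (need_dx) matrix(0, nrow(x), ncol(x)) else NULL
  for (k in 1:4) {
    idx <- .up_index(h, w, N, k)
    cols <- ((k - 1L) * Cout + 1L):(k * Cout)
    dPk <- dy[idx, , drop = FALSE]
    dW[, cols] <- crossprod(x, dPk)
    if (need_dx) dx <- dx + dPk %*% t(W[, cols, drop = FALSE])
  }
  list(dx = dx, dW = dW, db = colSums(dy))
}

#' Per-channel batch normalization.
#' @return list(y, cache) in training mode; y uses running stats in eval.
#' @noRd
bn_fwd <- function(x, gamma, beta, rmean, rvar, train, eps = 1e-5) {
  n <- nrow(x); C <- ncol(x)
  if (train) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * rep(istd, each = n)
    y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
    list(y = y, mu = mu, v = v, istd = istd, xhat = xhat, xc = xc)
  } else {
    istd <- 1 / sqrt(rvar + eps)
    y <- (x - rep(rmean, each = n)) * rep(gamma * istd, each = n) +
      rep(beta, each = n)
    list(y = y)
  }
}

#' @noRd
bn_bwd <- function(dy, cache, gamma) {
  n <- nrow(dy); C <- ncol(dy)
  xhat <- cache$xhat; istd <- cache$istd
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(gamma, each = n)
  # dx = istd/n * (n*dxhat - colSums(dxhat) - xhat*colSums(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
    rep(istd, each = n)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' @noRd
relu <- function(x) (x > 0) * x

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Reorder a (N*H*W) x C activation into an N x (H*W*C) row-per-image
#' matrix for fully connected layers (channel-major feature blocks).
#' @noRd
flatten_conv <- function(x, HW, N) {
  a <- array(x, dim = c(HW, N, ncol(x)))
  matrix(aperm(a, c(2, 1, 3)), N, HW * ncol(x))
}

#' @noRd
unflatten_conv <- function(m, HW, N, C) {
  a <- array(m, dim = c(N, HW, C))
  matrix(aperm(a, c(2, 1, 3)), HW * N, C)
}

#' He-scaled Gaussian initial weights.
#' @noRd
.winit <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}
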