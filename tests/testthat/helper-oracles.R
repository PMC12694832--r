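# Independent reference implementations used as oracles.  These are
# deliberately written as plain scalar loops / direct formulas, separate
# from the package's vectorized code paths.

# Elementwise modulation, scalar loop.
oracle_modulate <- function(a, z, beta) {
  out <- numeric(length(a))
  bvec <- if (length(beta) == 1) rep(beta, ncol(a) %||% 1) else beta
  for (i in seq_along(a)) {
    ch <- if (is.matrix(a)) ((i - 1) %/% nrow(a)) + 1 else 1
    v <- a[i] * (z[i] + bvec[ch])
    out[i] <- if (v > 0) v else 0
  }
  if (is.matrix(a)) matrix(out, nrow(a)) else out
}

# Scalar binary cross-entropy on logits.
oracle_bce <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) {
    p <- 1 / (1 + exp(-x[i]))
    s <- s - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
  }
  s / length(x)
}

# Scalar masked BCE (ignore = 1 drops the pixel).
oracle_seg_bce <- function(x, y, ignore) {
  s <- 0; n <- 0
  for (i in seq_along(x)) {
    if (ignore[i] > 0) next
    p <- 1 / (1 + exp(-x[i]))
    s <- s - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
    n <- n + 1
  }
  s / n
}

oracle_class_abs_error <- function(scores, labels) {
  tot <- 0
  for (r in seq_len(nrow(scores))) {
    e <- 0
    for (k in 1:12) e <- e + abs(scores[r, k] - labels[r, k])
    tot <- tot + e
  }
  tot / nrow(scores)
}

oracle_pixel_abs_error <- function(map, mask) {
  s <- 0; n <- 0
  for (i in seq_along(map)) if (mask[i]) { s <- s + abs(map[i] - 1); n <- n + 1 }
  s / n
}

oracle_background_rate <- function(map, masks, threshold) {
  cnt <- 0; n <- 0
  for (i in seq_along(map)) {
    inobj <- FALSE
    for (m in masks) if (m[i]) inobj <- TRUE
    if (!inobj) {
      n <- n + 1
      if (map[i] > threshold) cnt <- cnt + 1
    }
  }
  cnt / n
}

# Dominant texture orientation (degrees in [0, 180)) from the 2-D power
# spectrum: the energy axis is orthogonal to the bar orientation.
oracle_fft_orientation <- function(img) {
  f <- stats::fft(img - mean(img))
  P <- Mod(f)^2
  H <- nrow(img); W <- ncol(img)
  fy <- c(0:(H %/% 2), -((H - (H %/% 2) - 1):1)) / H
  fx <- c(0:(W %/% 2), -((W - (W %/% 2) - 1):1)) / W
  best <- c(0, 0); bp <- -1
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (fy[r] == 0 && fx[c] == 0) next
    rad <- sqrt(fy[r]^2 + fx[c]^2)
    if (rad < 0.03 || rad > 0.45) next
    if (P[r, c] > bp) { bp <- P[r, c]; best <- c(fy[r], fx[c]) }
  }
  # spectral peak direction is perpendicular to the bars
  ang <- atan2(best[1], best[2]) * 180 / pi
  (ang + 90) %% 180
}

# Brute-force box dilation via per-pixel neighbourhood scan.
oracle_dilate <- function(mask, w) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    hit <- FALSE
    for (dr in -w:w) for (dc in -w:w) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc]) hit <- TRUE
    }
    out[r, c] <- hit
  }
  out
}

oracle_erode <- function(mask, w) !oracle_dilate(!mask, w)

# Point-in-rotated-rectangle rasterizer (half-open boxes, independent of
# the package's vectorized version).
oracle_rect_pixels <- function(H, W, center, hw, rotation) {
  th <- rotation * pi / 180
  n <- 0
  for (r in seq_len(H)) for (c in seq_len(W)) {
    dy <- r - center[1]; dx <- c - center[2]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    if (v >= -hw[1] / 2 && v < hw[1] / 2 && u >= -hw[2] / 2 && u < hw[2] / 2)
      n <- n + 1
  }
  n
}

# Nearest-neighbour bitmap up-sampling.
oracle_nn_upsample <- function(m, f) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H * f, W * f)
  for (r in seq_len(H * f)) for (c in seq_len(W * f))
    out[r, c] <- m[ceiling(r / f), ceiling(c / f)]
  out
}

# Direct sliding least-squares Savitzky-Golay filter (MATLAB-style edge
# handling: the first/last full window's polynomial evaluated at the
# boundary positions).
oracle_sgolay <- function(x, p, n) {
  half <- (n - 1) / 2
  L <- length(x)
  out <- numeric(L)
  fitval <- function(idx, at) {
    X <- outer(idx - mean(idx), 0:p, `^`)
    cf <- qr.coef(qr(X), x[idx])
    sum(cf * (at - mean(idx))^(0:p))
  }
  for (i in seq_len(L)) {
    if (i <= half) out[i] <- fitval(1:n, i)
    else if (i > L - half) out[i] <- fitval((L - n + 1):L, i)
    else out[i] <- fitval((i - half):(i + half), i)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small helper: a deterministic two-object scene (square + rectangle).
make_two_object_scene <- function(seed = 42) {
  compose_scene(
    list(figure_spec("square", c(17, 17), c(16, 16), 0, texture_spec(115)),
         figure_spec("rectangle", c(40, 38), c(14, 24), 0, texture_spec(115))),
    background = texture_spec(25), seed = seed)
}
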