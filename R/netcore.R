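# The dual-pathway network.
#
# Feedforward (driving): image -> V1m -> V2m -> V4m -> ITm -> FCm, three
# conv-BN-ReLU blocks with skip connections per area, stride-2 2x2
# convolutions between areas, sigmoid class scores (multi-label).
#
# Feedback (modulatory): a one-hot attention vector gates the class scores;
# a driving head (fully connected mirror + transposed convolution +
# concatenation with the feedforward 7x7 tensor + 1x1 fusion) produces the
# top-level feedback drive; per-layer mirrors in V4m/V2m/V1m then apply
#   b = max(0, a * (z + beta)),   c = b - a,
# with stride-2 transposed convolutions between areas and spatial (3x3)
# deconvolutional connections between mirrored layers inside an area.  A
# learned 1x1 read-out of the lowest V1m mirror gives the 56x56 map.

#' Network configuration
#'
#' @param features Channel counts for V1m, V2m, V4m.
#' @param itm Width of the fully connected ITm layer.
#' @param n_classes Number of object classes (FCm width).
#' @param input_size Side of the square input image.
#' @param beta_granularity `"channel"` (one beta per feature map of each
#'   mirrored layer) or `"layer"` (one scalar per mirrored layer).
#' @param readout_source `"c"` (default; the feedback signal `c = b - a`,
#'   the network's segmentation signal, which is zero wherever no feedback
#'   arrives) or `"b"` (feedback-unit activity) as input to the
#'   segmentation read-out.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(features = c(20L, 50L, 100L), itm = 500L,
                       n_classes = 12L, input_size = 56L,
                       beta_granularity = c("channel", "layer"),
                       readout_source = c("c", "b")) {
  stopifnot(length(features) == 3, input_size %% 8 == 0)
  structure(list(
    features = as.integer(features), itm = as.integer(itm),
    n_classes = as.integer(n_classes), input_size = as.integer(input_size),
    sizes = as.integer(c(input_size, input_size / 2, input_size / 4)),
    top = as.integer(input_size / 8),
    beta_granularity = match.arg(beta_granularity),
    readout_source = match.arg(readout_source)), class = "seg_config")
}

#' Architecture fingerprint (JSON) used to guard checkpoint loading
#' @param config A [seg_config()].
#' @export
config_fingerprint <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
}

.AREAS <- c("v1", "v2", "v4")

# Parameter names of one conv block (with optional 1x1 skip projection).
.init_block <- function(P, nm, cin, cout) {
  P[[paste0(nm, ".W")]] <- .winit(9 * cin, cout, 9 * cin)
  P[[paste0(nm, ".b")]] <- numeric(cout)
  if (cin != cout) P[[paste0(nm, ".skipW")]] <- .winit(cin, cout, cin)
  P[[paste0(nm, ".g")]] <- rep(1, cout)
  P[[paste0(nm, ".be")]] <- numeric(cout)
  P
}

#' Create a network with freshly initialized parameters
#'
#' Weights are He-scaled Gaussian; batch-norm scale/offset start at 1/0;
#' every modulation offset beta starts at 1 so that, before any feedback
#' arrives (z = 0), the mirror reproduces the feedforward activity
#' (b = a, c = 0).
#'
#' @param config A [seg_config()].
#' @param seed Integer seed for the initialization.
#' @return Object of class `segnet_model`.
#' @export
seg_network <- function(config = seg_config(), seed = 1L) {
  F1 <- config$features[1]; F2 <- config$features[2]; F3 <- config$features[3]
  top <- config$top; K <- config$n_classes
  with_seed(seed, {
    P <- list()
    # feedforward
    P <- .init_block(P, "ff.v1.b1", 1L, F1)
    P <- .init_block(P, "ff.v1.b2", F1, F1)
    P <- .init_block(P, "ff.v1.b3", F1, F1)
    P[["ff.down1.W"]] <- .winit(4 * F1, F2, 4 * F1); P[["ff.down1.b"]] <- numeric(F2)
    P <- .init_block(P, "ff.v2.b1", F2, F2)
    P <- .init_block(P, "ff.v2.b2", F2, F2)
    P <- .init_block(P, "ff.v2.b3", F2, F2)
    P[["ff.down2.W"]] <- .winit(4 * F2, F3, 4 * F2); P[["ff.down2.b"]] <- numeric(F3)
    P <- .init_block(P, "ff.v4.b1", F3, F3)
    P <- .init_block(P, "ff.v4.b2", F3, F3)
    P <- .init_block(P, "ff.v4.b3", F3, F3)
    P[["ff.down3.W"]] <- .winit(4 * F3, F3, 4 * F3); P[["ff.down3.b"]] <- numeric(F3)
    P[["ff.itm.W"]] <- .winit(F3 * top * top, config$itm, F3 * top * top)
    P[["ff.itm.b"]] <- numeric(config$itm)
    P[["ff.fcm.W"]] <- .winit(config$itm, K, config$itm)
    P[["ff.fcm.b"]] <- numeric(K)
    # feedback head (driving).  The modulation b = a*(z+beta) multiplies
    # the incoming drive by the feedforward activity at every mirrored
    # layer, so plain He scaling lets z grow geometrically down the
    # chain and saturates the read-out before training starts; feedback
    # weights therefore start at a small gain.
    fbg <- 0.25
    .wfb <- function(nr, nc, fan_in) fbg * .winit(nr, nc, fan_in)
    P[["fb.head.fc1.W"]] <- .winit(K, config$itm, K)
    P[["fb.head.fc1.b"]] <- numeric(config$itm)
    P[["fb.head.deconv.W"]] <- .winit(config$itm, F3 * top * top, config$itm)
    P[["fb.head.deconv.b"]] <- numeric(F3 * top * top)
    P[["fb.head.fuse.W"]] <- .wfb(2 * F3, F3, 2 * F3)
    P[["fb.head.fuse.b"]] <- numeric(F3)
    # between-area transposed convolutions and within-area 3x3 mirrors
    P[["fb.up.v4.W"]] <- .wfb(F3, 4 * F3, F3); P[["fb.up.v4.b"]] <- numeric(F3)
    P[["fb.v4.l32.W"]] <- .wfb(9 * F3, F3, 9 * F3); P[["fb.v4.l32.b"]] <- numeric(F3)
    P[["fb.v4.l21.W"]] <- .wfb(9 * F3, F3, 9 * F3); P[["fb.v4.l21.b"]] <- numeric(F3)
    P[["fb.up.v2.W"]] <- .wfb(F3, 4 * F2, F3); P[["fb.up.v2.b"]] <- numeric(F2)
    P[["fb.v2.l32.W"]] <- .wfb(9 * F2, F2, 9 * F2); P[["fb.v2.l32.b"]] <- numeric(F2)
    P[["fb.v2.l21.W"]] <- .wfb(9 * F2, F2, 9 * F2); P[["fb.v2.l21.b"]] <- numeric(F2)
    P[["fb.up.v1.W"]] <- .wfb(F2, 4 * F1, F2); P[["fb.up.v1.b"]] <- numeric(F1)
    P[["fb.v1.l32.W"]] <- .wfb(9 * F1, F1, 9 * F1); P[["fb.v1.l32.b"]] <- numeric(F1)
    P[["fb.v1.l21.W"]] <- .wfb(9 * F1, F1, 9 * F1); P[["fb.v1.l21.b"]] <- numeric(F1)
    P[["fb.readout.W"]] <- .wfb(F1, 1L, F1)
    P[["fb.readout.b"]] <- numeric(1)
    # modulation offsets
    Fs <- c(v1 = F1, v2 = F2, v4 = F3)
    for (ar in .AREAS) for (l in 1:3) {
      len <- if (config$beta_granularity == "channel") Fs[[ar]] else 1L
      P[[sprintf("beta.%s.%d", ar, l)]] <- rep(1, len)
    }
    # batch-norm running statistics (mutable by reference)
    bn <- new.env(parent = emptyenv())
    for (ar in .AREAS) for (l in 1:3) {
      nm <- sprintf("ff.%s.b%d", ar, l)
      bn[[paste0(nm, ".rmean")]] <- numeric(Fs[[ar]])
      bn[[paste0(nm, ".rvar")]] <- rep(1, Fs[[ar]])
    }
    structure(list(config = config, params = P, bn = bn,
                   fingerprint = config_fingerprint(config)),
              class = "segnet_model")
  })
}

#' @export
print.segnet_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(paste0("<segnet_model> V1m %dx%dx%d | V2m %dx%dx%d | V4m %dx%dx%d",
                     " | ITm %d | FCm %d\n  %d parameters, beta per %s,",
                     " read-out from '%s'\n"),
              cfg$features[1], cfg$sizes[1], cfg$sizes[1],
              cfg$features[2], cfg$sizes[2], cfg$sizes[2],
              cfg$features[3], cfg$sizes[3], cfg$sizes[3],
              cfg$itm, cfg$n_classes, np, cfg$beta_granularity,
              cfg$readout_source))
  invisible(x)
}

#' Expected activation shapes of a model (used widely in tests)
#' @param net A `segnet_model`.
#' @return Named list of `c(channels, rows, cols)` per layer.
#' @export
model_shapes <- function(net) {
  cfg <- net$config
  s <- cfg$sizes; f <- cfg$features; top <- cfg$top
  out <- list()
  for (i in 1:3) for (l in 1:3)
    out[[sprintf("%s.b%d", .AREAS[i], l)]] <- c(f[i], s[i], s[i])
  out[["down3"]] <- c(f[3], top, top)
  out[["itm"]] <- cfg$itm
  out[["fcm"]] <- cfg$n_classes
  out[["concat"]] <- c(2L * f[3], top, top)
  out
}

# ---------------------------------------------------------------------------
# Feedforward pass

# One conv-BN-ReLU block with skip connection: y = relu(BN(conv(x)) + skip(x))
.block_fwd <- function(x, P, bn, nm, H, W, N, train, use_bn = TRUE) {
  z <- conv3_fwd(x, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]], H, W, N)
  if (use_bn) {
    bnr <- bn_fwd(z, P[[paste0(nm, ".g")]], P[[paste0(nm, ".be")]],
                  bn[[paste0(nm, ".rmean")]], bn[[paste0(nm, ".rvar")]], train)
    if (train) {
      mom <- 0.1
      bn[[paste0(nm, ".rmean")]] <- (1 - mom) * bn[[paste0(nm, ".rmean")]] + mom * bnr$mu
      bn[[paste0(nm, ".rvar")]] <- (1 - mom) * bn[[paste0(nm, ".rvar")]] + mom * bnr$v
    }
    h <- bnr$y
  } else {
    bnr <- NULL
    h <- z
  }
  skipW <- P[[paste0(nm, ".skipW")]]
  s <- if (is.null(skipW)) x else x %*% skipW
  pre <- h + s
  list(y = relu(pre), x = x, z = z, bn = bnr, pre = pre)
}

.block_bwd <- function(dy, cache, P, nm, H, W, N, G, use_bn = TRUE,
                       need_dx = TRUE) {
  dpre <- dy * (cache$pre > 0)
  skipW <- P[[paste0(nm, ".skipW")]]
  if (use_bn) {
    bnb <- bn_bwd(dpre, cache$bn, P[[paste0(nm, ".g")]])
    G[[paste0(nm, ".g")]] <- bnb$dgamma
    G[[paste0(nm, ".be")]] <- bnb$dbeta
    dz <- bnb$dx
  } else dz <- dpre
  cb <- conv3_bwd(dz, cache$x, P[[paste0(nm, ".W")]], H, W, N,
                  need_dx = need_dx)
  G[[paste0(nm, ".W")]] <- cb$dW
  G[[paste0(nm, ".b")]] <- cb$db
  if (!is.null(skipW)) G[[paste0(nm, ".skipW")]] <- crossprod(cache$x, dpre)
  if (!need_dx) return(NULL)
  if (!is.null(skipW)) cb$dx + dpre %*% t(skipW) else cb$dx + dpre
}

# Full feedforward pass on a batch stored as (N*H*W) x 1 matrix.
.ff_forward <- function(net, x, N, train = FALSE, use_bn = TRUE) {
  P <- net$params; cfg <- net$config
  s <- cfg$sizes; top <- cfg$top
  C <- list()
  a <- list()
  h <- x
  for (i in 1:3) {
    ar <- .AREAS[i]
    for (l in 1:3) {
      nm <- sprintf("ff.%s.b%d", ar, l)
      C[[nm]] <- .block_fwd(h, P, net$bn, nm, s[i], s[i], N, train, use_bn)
      h <- C[[nm]]$y
      a[[sprintf("%s.b%d", ar, l)]] <- h
    }
    dn <- sprintf("ff.down%d", i)
    C[[dn]] <- h
    h <- down2_fwd(h, P[[paste0(dn, ".W")]], P[[paste0(dn, ".b")]], s[i], s[i], N)
  }
  a[["down3"]] <- h                       # (N*top*top) x F3
  flat <- flatten_conv(h, top * top, N)   # N x (top*top*F3)
  itm_pre <- flat %*% P[["ff.itm.W"]] +
    matrix(P[["ff.itm.b"]], N, cfg$itm, byrow = TRUE)
  itm <- relu(itm_pre)
  logits <- itm %*% P[["ff.fcm.W"]] +
    matrix(P[["ff.fcm.b"]], N, cfg$n_classes, byrow = TRUE)
  a[["itm"]] <- itm
  list(cache = C, a = a, flat = flat, itm_pre = itm_pre, itm = itm,
       logits = logits, scores = sigmoid(logits), N = N)
}

# Backward through the feedforward pathway given d(logits).
.ff_backward <- function(net, fw, dlogits, G, use_bn = TRUE) {
  P <- net$params; cfg <- net$config
  s <- cfg$sizes; top <- cfg$top; N <- fw$N
  G[["ff.fcm.W"]] <- crossprod(fw$itm, dlogits)
  G[["ff.fcm.b"]] <- colSums(dlogits)
  ditm <- (dlogits %*% t(P[["ff.fcm.W"]])) * (fw$itm_pre > 0)
  G[["ff.itm.W"]] <- crossprod(fw$flat, ditm)
  G[["ff.itm.b"]] <- colSums(ditm)
  dflat <- ditm %*% t(P[["ff.itm.W"]])
  dh <- unflatten_conv(dflat, top * top, N, cfg$features[3])
  for (i in 3:1) {
    ar <- .AREAS[i]
    dn <- sprintf("ff.down%d", i)
    db <- down2_bwd(dh, fw$cache[[dn]], P[[paste0(dn, ".W")]], s[i], s[i], N)
    G[[paste0(dn, ".W")]] <- db$dW
    G[[paste0(dn, ".b")]] <- db$db
    dh <- db$dx
    for (l in 3:1) {
      nm <- sprintf("ff.%s.b%d", ar, l)
      dh <- .block_bwd(dh, fw$cache[[nm]], P, nm, s[i], s[i], N, G, use_bn,
                       need_dx = !(i == 1 && l == 1))
    }
  }
  invisible(G)
}

# ---------------------------------------------------------------------------
# Exported elementwise operations (the modulation equations)

#' Modulatory feedback interaction: b = max(0, a * (z + beta))
#'
#' Feedback is gated by the feedforward activity `a`: wherever `a` is zero
#' the feedback unit stays silent, so feedback can scale but never drive.
#'
#' @param a Non-negative feedforward activity (vector/matrix).
#' @param z Incoming feedback drive (same shape, may be negative).
#' @param beta Learned offset: scalar, or one value per column of `a`.
#' @return `b`, same shape as `a`, non-negative.
#' @export
modulate <- function(a, z, beta) {
  if (any(a < 0)) stop("modulate: feedforward activity must be non-negative")
  if (!identical(dim(a), dim(z)) || length(a) != length(z))
    stop("modulate: a and z must have the same shape")
  zb <- if (length(beta) == 1 || is.null(dim(a))) z + beta
  else z + matrix(beta, nrow(a), ncol(a), byrow = TRUE)
  b <- pmax(0, a * zb)
  dim(b) <- dim(a)
  b
}

#' Feedback signal: c = b - a
#'
#' The signed difference between feedback-unit activity and feedforward
#' activity; this is the quantity propagated to the next lower layer.
#'
#' @param b Feedback-unit activity.
#' @param a Feedforward activity, same shape.
#' @return `c = b - a`.
#' @export
feedback_signal <- function(b, a) {
  if (length(b) != length(a) || !identical(dim(b), dim(a)))
    stop("feedback_signal: shape mismatch")
  b - a
}

#' Gate class scores with a one-hot attention vector
#'
#' @param scores Length-12 class scores in `[0, 1]` (or an N x 12 matrix).
#' @param attend One-hot length-12 vector (or N x 12 one-hot rows).
#' @return Elementwise product; at most one non-zero entry per row.
#' @export
attention_gate <- function(scores, attend) {
  av <- if (is.matrix(attend)) attend else matrix(attend, 1)
  if (any(av != 0 & av != 1) || any(rowSums(av) != 1))
    stop("attention_gate: attend must be one-hot")
  if (length(scores) != length(attend))
    stop("attention_gate: shape mismatch")
  scores * attend
}

#' One-hot attention vector for a class
#' @param class_index Integer 1..12 (see `CLASS_NAMES`) or a class name.
#' @param n_classes Vector length.
#' @export
attention_vector <- function(class_index, n_classes = 12L) {
  if (is.character(class_index)) class_index <- match(class_index, CLASS_NAMES)
  v <- numeric(n_classes)
  v[class_index] <- 1
  v
}

# ---------------------------------------------------------------------------
# Feedback pass

# Mirror chain of one area: z enters at the mirror of block 3 and descends
# through spatial (3x3) deconvolutional connections between mirrored
# layers.  Returns b/c per mirrored layer; c of block 1 leaves the area.
.fb_area_fwd <- function(P, cfg, ar, z3, a3, a2, a1, hw, N) {
  bet <- function(l) P[[sprintf("beta.%s.%d", ar, l)]]
  b3 <- modulate(a3, z3, bet(3)); c3 <- b3 - a3
  z2 <- conv3_fwd(c3, P[[sprintf("fb.%s.l32.W", ar)]],
                  P[[sprintf("fb.%s.l32.b", ar)]], hw, hw, N)
  b2 <- modulate(a2, z2, bet(2)); c2 <- b2 - a2
  z1 <- conv3_fwd(c2, P[[sprintf("fb.%s.l21.W", ar)]],
                  P[[sprintf("fb.%s.l21.b", ar)]], hw, hw, N)
  b1 <- modulate(a1, z1, bet(1)); c1 <- b1 - a1
  list(z3 = z3, z2 = z2, z1 = z1, b3 = b3, b2 = b2, b1 = b1,
       c3 = c3, c2 = c2, c1 = c1)
}

# Full feedback pass; `fw` is the result of .ff_forward on the same batch.
# `attend` is an N x K one-hot matrix.
.fb_forward <- function(net, fw, attend) {
  P <- net$params; cfg <- net$config
  N <- fw$N; top <- cfg$top; s <- cfg$sizes
  F1 <- cfg$features[1]; F2 <- cfg$features[2]; F3 <- cfg$features[3]
  gated <- fw$scores * attend
  h1_pre <- gated %*% P[["fb.head.fc1.W"]] +
    matrix(P[["fb.head.fc1.b"]], N, cfg$itm, byrow = TRUE)
  h1 <- relu(h1_pre)
  hd_pre <- h1 %*% P[["fb.head.deconv.W"]] +
    matrix(P[["fb.head.deconv.b"]], N, F3 * top * top, byrow = TRUE)
  hd <- relu(hd_pre)
  t_hd <- unflatten_conv(hd, top * top, N, F3)      # (N*top*top) x F3
  concat <- cbind(t_hd, fw$a[["down3"]])            # (N*top*top) x 2F3
  z_top <- conv1_fwd(concat, P[["fb.head.fuse.W"]], P[["fb.head.fuse.b"]])
  z43 <- up2_fwd(z_top, P[["fb.up.v4.W"]], P[["fb.up.v4.b"]], top, top, N)
  v4 <- .fb_area_fwd(P, cfg, "v4", z43, fw$a[["v4.b3"]], fw$a[["v4.b2"]],
                     fw$a[["v4.b1"]], s[3], N)
  z23 <- up2_fwd(v4$c1, P[["fb.up.v2.W"]], P[["fb.up.v2.b"]], s[3], s[3], N)
  v2 <- .fb_area_fwd(P, cfg, "v2", z23, fw$a[["v2.b3"]], fw$a[["v2.b2"]],
                     fw$a[["v2.b1"]], s[2], N)
  z13 <- up2_fwd(v2$c1, P[["fb.up.v1.W"]], P[["fb.up.v1.b"]], s[2], s[2], N)
  v1 <- .fb_area_fwd(P, cfg, "v1", z13, fw$a[["v1.b3"]], fw$a[["v1.b2"]],
                     fw$a[["v1.b1"]], s[1], N)
  src <- if (cfg$readout_source == "b") v1$b1 else v1$c1
  map_logits <- conv1_fwd(src, P[["fb.readout.W"]], P[["fb.readout.b"]])
  list(gated = gated, h1_pre = h1_pre, h1 = h1, hd_pre = hd_pre, hd = hd,
       t_hd = t_hd, concat = concat, z_top = z_top,
       v4 = v4, v2 = v2, v1 = v1, src = src,
       map_logits = map_logits, map = sigmoid(map_logits), N = N)
}

# Backward through one mirror area; a* are frozen constants.
# Returns d(z3) w.r.t. the incoming drive.
.fb_area_bwd <- function(P, cfg, ar, cache, a3, a2, a1, dc1, db1_extra, G,
                         hw, N) {
  bet <- function(l) P[[sprintf("beta.%s.%d", ar, l)]]
  beta_grad <- function(db_eff, a, b) {
    g <- db_eff * (b > 0) * a
    if (cfg$beta_granularity == "channel") colSums(g) else sum(g)
  }
  db1 <- dc1 + (db1_extra %||% 0)
  gate1 <- (cache$b1 > 0) * a1
  G[[sprintf("beta.%s.1", ar)]] <- (G[[sprintf("beta.%s.1", ar)]] %||% 0) +
    beta_grad(db1, a1, cache$b1)
  dz1 <- db1 * gate1
  cb <- conv3_bwd(dz1, cache$c2, P[[sprintf("fb.%s.l21.W", ar)]], hw, hw, N)
  G[[sprintf("fb.%s.l21.W", ar)]] <- cb$dW
  G[[sprintf("fb.%s.l21.b", ar)]] <- cb$db
  db2 <- cb$dx
  gate2 <- (cache$b2 > 0) * a2
  G[[sprintf("beta.%s.2", ar)]] <- (G[[sprintf("beta.%s.2", ar)]] %||% 0) +
    beta_grad(db2, a2, cache$b2)
  dz2 <- db2 * gate2
  cb <- conv3_bwd(dz2, cache$c3, P[[sprintf("fb.%s.l32.W", ar)]], hw, hw, N)
  G[[sprintf("fb.%s.l32.W", ar)]] <- cb$dW
  G[[sprintf("fb.%s.l32.b", ar)]] <- cb$db
  db3 <- cb$dx
  gate3 <- (cache$b3 > 0) * a3
  G[[sprintf("beta.%s.3", ar)]] <- (G[[sprintf("beta.%s.3", ar)]] %||% 0) +
    beta_grad(db3, a3, cache$b3)
  db3 * gate3
}

# Backward through the feedback pathway given d(map_logits) and an
# optional direct gradient on the V1m mirror's feedback signal c (used by
# the per-unit deep supervision during phase 2); feedforward parameters
# receive no gradient (frozen by construction).
.fb_backward <- function(net, fw, fb, dmap, G, dc11 = NULL) {
  P <- net$params; cfg <- net$config
  N <- fw$N; top <- cfg$top; s <- cfg$sizes
  F3 <- cfg$features[3]
  cb <- conv1_bwd(dmap, fb$src, P[["fb.readout.W"]])
  G[["fb.readout.W"]] <- cb$dW
  G[["fb.readout.b"]] <- cb$db
  if (cfg$readout_source == "b") {
    dc1 <- matrix(0, nrow(fb$v1$c1), ncol(fb$v1$c1)); db1x <- cb$dx
  } else {
    dc1 <- cb$dx; db1x <- NULL
  }
  if (!is.null(dc11)) dc1 <- dc1 + dc11
  dz13 <- .fb_area_bwd(P, cfg, "v1", fb$v1, fw$a[["v1.b3"]], fw$a[["v1.b2"]],
                       fw$a[["v1.b1"]], dc1, db1x, G, s[1], N)
  ub <- up2_bwd(dz13, fb$v2$c1, P[["fb.up.v1.W"]], s[2], s[2], N)
  G[["fb.up.v1.W"]] <- ub$dW; G[["fb.up.v1.b"]] <- ub$db
  dz23 <- .fb_area_bwd(P, cfg, "v2", fb$v2, fw$a[["v2.b3"]], fw$a[["v2.b2"]],
                       fw$a[["v2.b1"]], ub$dx, NULL, G, s[2], N)
  ub <- up2_bwd(dz23, fb$v4$c1, P[["fb.up.v2.W"]], s[3], s[3], N)
  G[["fb.up.v2.W"]] <- ub$dW; G[["fb.up.v2.b"]] <- ub$db
  dz43 <- .fb_area_bwd(P, cfg, "v4", fb$v4, fw$a[["v4.b3"]], fw$a[["v4.b2"]],
                       fw$a[["v4.b1"]], ub$dx, NULL, G, s[3], N)
  ub <- up2_bwd(dz43, fb$z_top, P[["fb.up.v4.W"]], top, top, N)
  G[["fb.up.v4.W"]] <- ub$dW; G[["fb.up.v4.b"]] <- ub$db
  cb <- conv1_bwd(ub$dx, fb$concat, P[["fb.head.fuse.W"]])
  G[["fb.head.fuse.W"]] <- cb$dW; G[["fb.head.fuse.b"]] <- cb$db
  dt_hd <- cb$dx[, seq_len(F3), drop = FALSE]   # feedforward half is frozen
  dhd <- flatten_conv(dt_hd, top * top, N) * (fb$hd_pre > 0)
  G[["fb.head.deconv.W"]] <- crossprod(fb$h1, dhd)
  G[["fb.head.deconv.b"]] <- colSums(dhd)
  dh1 <- (dhd %*% t(P[["fb.head.deconv.W"]])) * (fb$h1_pre > 0)
  G[["fb.head.fc1.W"]] <- crossprod(fb$gated, dh1)
  G[["fb.head.fc1.b"]] <- colSums(dh1)
  invisible(G)
}

# Data-dependent initialization of the feedback pathway.  The mirror
# chain multiplies the feedback drive by the feedforward activity at
# every layer, so any fixed weight scale either explodes or vanishes
# geometrically with depth once the feedforward statistics are fixed.
# Before phase-2 training each feedback weight matrix is rescaled, in
# topological order, so that the drive it produces has a target standard
# deviation on a calibration batch (layer-sequential unit variance).
.calibrate_fb <- function(net, fw, attend, z_sd = 0.5) {
  P <- net$params
  cfg <- net$config
  N <- fw$N; top <- cfg$top; s <- cfg$sizes
  F3 <- cfg$features[3]
  rescale <- function(Wname, bname, val, target) {
    sdv <- stats::sd(val)
    if (!is.finite(sdv) || sdv < 1e-12) return(1)
    g <- target / sdv
    P[[Wname]] <<- P[[Wname]] * g
    if (!is.null(bname)) P[[bname]] <<- P[[bname]] * g
    g
  }
  gated <- fw$scores * attend
  h1p <- gated %*% P[["fb.head.fc1.W"]]
  rescale("fb.head.fc1.W", "fb.head.fc1.b", h1p, 1)
  h1 <- relu(gated %*% P[["fb.head.fc1.W"]])
  hdp <- h1 %*% P[["fb.head.deconv.W"]]
  rescale("fb.head.deconv.W", "fb.head.deconv.b", hdp, 1)
  hd <- relu(h1 %*% P[["fb.head.deconv.W"]])
  t_hd <- unflatten_conv(hd, top * top, N, F3)
  concat <- cbind(t_hd, fw$a[["down3"]])
  zt <- conv1_fwd(concat, P[["fb.head.fuse.W"]], NULL)
  rescale("fb.head.fuse.W", "fb.head.fuse.b", zt, z_sd)
  z_top <- conv1_fwd(concat, P[["fb.head.fuse.W"]], P[["fb.head.fuse.b"]])
  prev_c <- z_top
  prev_hw <- top
  ups <- c("v4", "v2", "v1")
  a3n <- c("v4.b3", "v2.b3", "v1.b3")
  for (i in 1:3) {
    ar <- ups[i]
    up_w <- sprintf("fb.up.%s.W", ar)
    z3 <- up2_fwd(prev_c, P[[up_w]], P[[sprintf("fb.up.%s.b", ar)]],
                  prev_hw, prev_hw, N)
    rescale(up_w, sprintf("fb.up.%s.b", ar), z3, z_sd)
    z3 <- up2_fwd(prev_c, P[[up_w]], P[[sprintf("fb.up.%s.b", ar)]],
                  prev_hw, prev_hw, N)
    a3 <- fw$a[[a3n[i]]]
    a2 <- fw$a[[sub("b3", "b2", a3n[i])]]
    a1 <- fw$a[[sub("b3", "b1", a3n[i])]]
    hw <- s[c(3, 2, 1)[i]]
    b3 <- modulate(a3, z3, P[[sprintf("beta.%s.3", ar)]]); c3 <- b3 - a3
    w32 <- sprintf("fb.%s.l32.W", ar)
    z2 <- conv3_fwd(c3, P[[w32]], P[[sprintf("fb.%s.l32.b", ar)]], hw, hw, N)
    rescale(w32, sprintf("fb.%s.l32.b", ar), z2, z_sd)
    z2 <- conv3_fwd(c3, P[[w32]], P[[sprintf("fb.%s.l32.b", ar)]], hw, hw, N)
    b2 <- modulate(a2, z2, P[[sprintf("beta.%s.2", ar)]]); c2 <- b2 - a2
    w21 <- sprintf("fb.%s.l21.W", ar)
    z1 <- conv3_fwd(c2, P[[w21]], P[[sprintf("fb.%s.l21.b", ar)]], hw, hw, N)
    rescale(w21, sprintf("fb.%s.l21.b", ar), z1, z_sd)
    z1 <- conv3_fwd(c2, P[[w21]], P[[sprintf("fb.%s.l21.b", ar)]], hw, hw, N)
    b1 <- modulate(a1, z1, P[[sprintf("beta.%s.1", ar)]]); c1 <- b1 - a1
    prev_c <- c1
    prev_hw <- hw
  }
  src <- if (cfg$readout_source == "b") b1 else c1
  lg <- conv1_fwd(src, P[["fb.readout.W"]], NULL)
  rescale("fb.readout.W", NULL, lg, 1)
  net$params <- P
  net
}

# ---------------------------------------------------------------------------
# User-facing passes

# Stack images (56x56 matrices or a list of stimuli) into the internal
# (N*H*W) x 1 row-major batch matrix.
.stack_images <- function(images, input_size) {
  if (inherits(images, "stimulus")) images <- list(images)
  if (is.matrix(images) && is.numeric(images)) images <- list(images)
  imgs <- lapply(images, function(im) if (inherits(im, "stimulus")) im$image else im)
  for (im in imgs)
    if (!is.matrix(im) || nrow(im) != input_size || ncol(im) != input_size)
      stop("expected ", input_size, "x", input_size, " image(s)")
  matrix(unlist(lapply(imgs, function(im) as.vector(t(im)))), ncol = 1)
}

#' Run the feedforward pathway
#'
#' @param net A `segnet_model`.
#' @param images A 56x56 matrix, a `stimulus`, or a list of either.
#' @param use_bn Apply batch normalization (running statistics).  Setting
#'   `FALSE` bypasses normalization, useful for zero-propagation checks.
#' @return `list(scores, logits, activities)`; `activities` holds every
#'   cached feedforward activity (`v1.b1` ... `down3`, `itm`) as
#'   `(N*H*W) x C` matrices.
#' @export
feedforward_pass <- function(net, images, use_bn = TRUE) {
  x <- .stack_images(images, net$config$input_size)
  N <- nrow(x) / net$config$input_size^2
  fw <- .ff_forward(net, x, N, train = FALSE, use_bn = use_bn)
  structure(list(scores = fw$scores, logits = fw$logits, activities = fw$a,
                 n = N, .fw = fw), class = "ff_result")
}

#' Run the modulatory feedback pathway after a feedforward pass
#'
#' @param net A `segnet_model`.
#' @param ff An `ff_result` from [feedforward_pass()] on the same images.
#' @param attend One-hot length-12 vector (applied to every image) or an
#'   N x 12 one-hot matrix.
#' @return `list(map, state)`; `map` is a 56x56 matrix in `[0,1]` (or a
#'   56x56xN array for batches), `state` holds per-layer `z`, `b`, `c`.
#' @export
feedback_pass <- function(net, ff, attend) {
  stopifnot(inherits(ff, "ff_result"))
  N <- ff$n
  A <- if (is.matrix(attend)) attend else
    matrix(attend, N, length(attend), byrow = TRUE)
  if (any(A != 0 & A != 1) || any(rowSums(A) != 1))
    stop("feedback_pass: attend must be one-hot")
  fb <- .fb_forward(net, ff$.fw, A)
  sz <- net$config$input_size
  maps <- .rows_to_maps(fb$map, sz, N)
  state <- list(
    z = list(v4.b3 = fb$v4$z3, v4.b2 = fb$v4$z2, v4.b1 = fb$v4$z1,
             v2.b3 = fb$v2$z3, v2.b2 = fb$v2$z2, v2.b1 = fb$v2$z1,
             v1.b3 = fb$v1$z3, v1.b2 = fb$v1$z2, v1.b1 = fb$v1$z1),
    b = list(v4.b3 = fb$v4$b3, v4.b2 = fb$v4$b2, v4.b1 = fb$v4$b1,
             v2.b3 = fb$v2$b3, v2.b2 = fb$v2$b2, v2.b1 = fb$v2$b1,
             v1.b3 = fb$v1$b3, v1.b2 = fb$v1$b2, v1.b1 = fb$v1$b1),
    c = list(v4.b3 = fb$v4$c3, v4.b2 = fb$v4$c2, v4.b1 = fb$v4$c1,
             v2.b3 = fb$v2$c3, v2.b2 = fb$v2$c2, v2.b1 = fb$v2$c1,
             v1.b3 = fb$v1$c3, v1.b2 = fb$v1$c2, v1.b1 = fb$v1$c1))
  list(map = maps, state = state, concat_channels = ncol(fb$concat),
       .fb = fb)
}

# Convert (N*H*W) x 1 row-major map rows back to matrices.
.rows_to_maps <- function(rows, sz, N) {
  if (N == 1) return(matrix(rows, sz, sz, byrow = TRUE))
  out <- array(0, c(sz, sz, N))
  for (n in seq_len(N))
    out[, , n] <- matrix(rows[((n - 1) * sz * sz + 1):(n * sz * sz)], sz, sz,
                         byrow = TRUE)
  out
}

#' Attention-conditioned segmentation of a stimulus
#'
#' Convenience wrapper: feedforward pass, then feedback pass attending to
#' `class_index`.
#'
#' @param net Trained `segnet_model`.
#' @param stim A `stimulus` or 56x56 image matrix.
#' @param class_index Attended class (1..12 or name).
#' @return 56x56 segmentation map in `[0, 1]`.
#' @export
segment <- function(net, stim, class_index) {
  ff <- feedforward_pass(net, stim)
  fb <- feedback_pass(net, ff, attention_vector(class_index,
                                                net$config$n_classes))
  fb$map
}
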