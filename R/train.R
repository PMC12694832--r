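# Two-phase optimization and evaluation metrics.
#
# Phase "ff" trains the feedforward pathway for multi-label classification
# (sigmoid + binary cross-entropy on logits).  Phase "fb" freezes every
# feedforward parameter and trains the feedback pathway for
# attention-conditioned segmentation with a pixel-wise BCE that ignores
# pure-texture background pixels.

#' Training configuration
#'
#' Defaults follow the reference protocol (Adam, learning rate 0.001,
#' weight decay 0.0005; 2,500 epochs at batch 1024 for the feedforward
#' phase and batch 256 for the feedback phase).  Overrides are recorded in
#' the returned object and echoed in the run log.
#'
#' @param phase `"ff"` or `"fb"`.
#' @param epochs,batch_size Optimization schedule.
#' @param learning_rate,weight_decay Adam settings.
#' @param seed Integer seed for shuffling and attended-class sampling.
#' @param ignore_policy For phase `"fb"`: `"texture_background"` ignores
#'   only pixels outside every object (non-attended objects keep target 0,
#'   which teaches suppression of unattended objects);
#'   `"all_nonattended"` ignores everything outside the attended object.
#' @param cache_activations For phase `"fb"`: precompute the frozen
#'   feedforward activations once for the whole dataset instead of
#'   re-evaluating them every epoch.  `NULL` (default) enables the cache
#'   when its estimated size stays below ~1.5 GB.
#' @param verbose Print per-epoch progress.
#' @export
train_config <- function(phase = c("ff", "fb"), epochs = 2500L,
                         batch_size = NULL, learning_rate = 0.001,
                         weight_decay = 0.0005, seed = 1L,
                         ignore_policy = c("texture_background",
                                           "all_nonattended"),
                         cache_activations = NULL, verbose = FALSE) {
  phase <- match.arg(phase)
  defaults <- list(ff = 1024L, fb = 256L)
  if (is.null(batch_size)) batch_size <- defaults[[phase]]
  structure(list(phase = phase, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed),
                 ignore_policy = match.arg(ignore_policy),
                 cache_activations = cache_activations,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# ---------------------------------------------------------------------------
# Losses

# Stable elementwise BCE-with-logits.
.bce_logits <- function(x, y) pmax(x, 0) - x * y + log1p(exp(-abs(x)))

#' Multi-label classification loss (BCE with logits)
#'
#' @param logits Length-12 vector or N x 12 matrix of class logits.
#' @param labels Multi-hot labels in `{0, 1}`, same shape.
#' @return Mean binary cross-entropy over all entries.
#' @export
ff_loss <- function(logits, labels) {
  if (length(logits) != length(labels)) stop("ff_loss: shape mismatch")
  if (any(!labels %in% c(0, 1))) stop("ff_loss: labels must be 0/1")
  if (any(!is.finite(logits))) stop("ff_loss: non-finite logits")
  mean(.bce_logits(logits, labels))
}

#' Segmentation loss (pixel-wise BCE with logits, masked)
#'
#' @param map_logits 56x56 matrix (or vector) of pixel logits.
#' @param target Binary target map, 1 on the attended object.
#' @param ignore Binary mask of pixels excluded from the loss.
#' @return Mean BCE over the non-ignored pixels.
#' @export
seg_loss <- function(map_logits, target, ignore) {
  if (length(map_logits) != length(target) || length(target) != length(ignore))
    stop("seg_loss: shape mismatch")
  keep <- !(ignore > 0)
  if (!any(keep)) stop("seg_loss: all pixels ignored, loss undefined")
  mean(.bce_logits(map_logits[keep], target[keep]))
}

# ---------------------------------------------------------------------------
# Metrics

#' Per-image classification absolute error
#'
#' Sum over the 12 classes of |score - label|, averaged over images.
#' Ranges from 0 (every object in every image correctly classified) to 12
#' (none correct).
#'
#' @param scores N x 12 matrix (or length-12 vector) in `[0, 1]`.
#' @param labels Multi-hot labels, same shape.
#' @export
classification_abs_error <- function(scores, labels) {
  s <- if (is.matrix(scores)) scores else matrix(scores, 1)
  l <- if (is.matrix(labels)) labels else matrix(labels, 1)
  if (ncol(s) != 12 || ncol(l) != 12)
    stop("classification_abs_error: expected 12 classes")
  if (any(s < 0 | s > 1)) stop("classification_abs_error: scores outside [0,1]")
  mean(rowSums(abs(s - l)))
}

#' Pixel-wise absolute error over attended-object pixels
#'
#' Mean of |map - 1| over the pixels of the attended object only; 0 when
#' every object pixel is labeled, 1 when none is.  Background pixels are
#' not considered.
#'
#' @param map Segmentation map in `[0, 1]`.
#' @param mask Logical mask of the attended object (non-empty).
#' @export
pixel_abs_error <- function(map, mask) {
  if (length(map) != length(mask)) stop("pixel_abs_error: shape mismatch")
  if (!any(mask)) stop("pixel_abs_error: empty object mask")
  if (any(map < 0 | map > 1)) stop("pixel_abs_error: map outside [0,1]")
  mean(abs(map[mask] - 1))
}

#' Fraction of background pixels labeled as the attended class
#'
#' @param map Segmentation map in `[0, 1]`.
#' @param masks List of logical object masks (or H x W x K array); the
#'   background is everything outside their union.
#' @param threshold Decision threshold, default 0.5.
#' @export
background_false_rate <- function(map, masks, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("background_false_rate: threshold must be in (0,1)")
  if (is.array(masks) && length(dim(masks)) == 3)
    masks <- lapply(seq_len(dim(masks)[3]), function(k) masks[, , k])
  bg <- !Reduce(`|`, masks)
  if (length(bg) != length(map)) stop("background_false_rate: shape mismatch")
  mean(map[bg] > threshold)
}

#' Multi-label detection accuracy
#'
#' Fraction of correct per-class presence decisions (score thresholded at
#' `threshold`) over all images and classes.
#' @param scores N x 12 score matrix. @param labels Multi-hot matrix.
#' @param threshold Decision threshold.
#' @export
detection_accuracy <- function(scores, labels, threshold = 0.5) {
  mean((scores > threshold) == (labels > 0.5))
}

#' Intersection-over-union of a thresholded map and a mask
#' @param map Map in `[0,1]`. @param mask Logical mask.
#' @param threshold Decision threshold.
#' @export
mask_iou <- function(map, mask, threshold = 0.5) {
  pred <- map > threshold
  u <- sum(pred | mask)
  if (u == 0) return(1)
  sum(pred & mask) / u
}

# ---------------------------------------------------------------------------
# Adam

.adam_new <- function() new.env(parent = emptyenv())

# One Adam step over the parameter subset `names(grads)`; L2 weight decay
# is added to the gradient (the reference optimizer's convention).
.adam_step <- function(params, G, st, lr, wd, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  for (nm in ls(G)) {
    g <- G[[nm]] + wd * params[[nm]]
    m <- st[[paste0(nm, ".m")]]
    v <- st[[paste0(nm, ".v")]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    st[[paste0(nm, ".m")]] <- m
    st[[paste0(nm, ".v")]] <- v
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}

# ---------------------------------------------------------------------------
# Data marshalling

# Precompute the flat row-major image vectors (3136 x N) and label matrix.
.prep_data <- function(stimuli) {
  X <- vapply(stimuli, function(st) as.vector(t(st$image)),
              numeric(length(stimuli[[1]]$image)))
  Y <- t(vapply(stimuli, function(st) st$labels, numeric(12)))
  list(X = X, Y = Y)
}

.batch_x <- function(X, idx) matrix(as.vector(X[, idx]), ncol = 1)

# ---------------------------------------------------------------------------
# Phase 1: feedforward training

#' Train the feedforward pathway (phase 1)
#'
#' Multi-label classification with Adam on sigmoid + BCE loss.  Only
#' `ff/*` parameter groups are updated.
#'
#' @param net A `segnet_model`.
#' @param stimuli Training stimuli from [generate_dataset()].
#' @param config A [train_config()] with `phase = "ff"`.
#' @param val_stimuli Optional held-out stimuli; per-epoch validation
#'   metrics are logged when given.
#' @return `list(net, history)`; `history` is a data frame with per-epoch
#'   loss (and validation metrics when available).
#' @export
train_feedforward <- function(net, stimuli, config, val_stimuli = NULL) {
  stopifnot(config$phase == "ff")
  dat <- .prep_data(stimuli)
  n <- length(stimuli)
  st <- .adam_new()
  hist <- list()
  t_step <- 0L
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(n, start + config$batch_size - 1)]
        B <- length(idx)
        x <- .batch_x(dat$X, idx)
        y <- dat$Y[idx, , drop = FALSE]
        fw <- .ff_forward(net, x, B, train = TRUE)
        loss <- ff_loss(fw$logits, y)
        if (!is.finite(loss)) stop("train_feedforward: loss diverged (NaN)")
        G <- new.env(parent = emptyenv())
        dlogits <- (fw$scores - y) / length(y)
        .ff_backward(net, fw, dlogits, G)
        t_step <- t_step + 1L
        net$params <- .adam_step(net$params, G, st, config$learning_rate,
                                 config$weight_decay, t_step)
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      row <- data.frame(epoch = ep, loss = ep_loss / nb)
      if (!is.null(val_stimuli)) {
        ev <- evaluate_classification(net, val_stimuli)
        row$val_abs_error <- ev$classification_abs_error
        row$val_accuracy <- ev$detection_accuracy
      }
      hist[[ep]] <- row
      if (config$verbose)
        message(sprintf("ff epoch %d/%d loss %.4f%s", ep, config$epochs,
                        row$loss,
                        if (!is.null(row$val_accuracy))
                          sprintf(" val_acc %.3f", row$val_accuracy) else ""))
    }
  })
  list(net = net, history = do.call(rbind, hist))
}

#' Classification metrics on a stimulus set
#' @param net Model. @param stimuli Stimuli. @param batch_size Batch size.
#' @return `list(scores, classification_abs_error, detection_accuracy)`.
#' @export
evaluate_classification <- function(net, stimuli, batch_size = 128L) {
  dat <- .prep_data(stimuli)
  n <- length(stimuli)
  scores <- matrix(0, n, net$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    fw <- .ff_forward(net, .batch_x(dat$X, idx), length(idx), train = FALSE)
    scores[idx, ] <- fw$scores
  }
  list(scores = scores,
       classification_abs_error = classification_abs_error(scores, dat$Y),
       detection_accuracy = detection_accuracy(scores, dat$Y))
}

# ---------------------------------------------------------------------------
# Phase 2: feedback training

.FB_LAYERS <- c("v1.b1", "v1.b2", "v1.b3", "v2.b1", "v2.b2", "v2.b3",
                "v4.b1", "v4.b2", "v4.b3", "down3")

# Evaluate the frozen feedforward pathway once per stimulus; activations
# are stored per image so arbitrary batches can be reassembled.
.precompute_ff <- function(net, dat, n, chunk = 128L) {
  cache <- vector("list", n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1)
    fw <- .ff_forward(net, .batch_x(dat$X, idx), length(idx), train = FALSE)
    rows <- vapply(.FB_LAYERS, function(nm)
      nrow(fw$a[[nm]]) / length(idx), numeric(1))
    for (j in seq_along(idx)) {
      a <- lapply(.FB_LAYERS, function(nm) {
        r <- rows[[nm]]
        fw$a[[nm]][((j - 1) * r + 1):(j * r), , drop = FALSE]
      })
      names(a) <- .FB_LAYERS
      cache[[idx[j]]] <- list(a = a, scores = fw$scores[j, , drop = FALSE])
    }
  }
  cache
}

.gather_ff <- function(cache, idx) {
  a <- lapply(.FB_LAYERS, function(nm)
    do.call(rbind, lapply(cache[idx], function(ci) ci$a[[nm]])))
  names(a) <- .FB_LAYERS
  list(a = a, scores = do.call(rbind, lapply(cache[idx], `[[`, "scores")),
       N = length(idx))
}

# Flat row-major target/ignore vectors for a batch: one attended class per
# stimulus, sampled uniformly among the classes present.
.seg_targets <- function(stimuli, idx, attend_classes, policy) {
  sz2 <- length(stimuli[[1]]$image)
  tg <- matrix(0, sz2 * length(idx), 1)
  ig <- matrix(0, sz2 * length(idx), 1)
  A <- matrix(0, length(idx), 12)
  for (j in seq_along(idx)) {
    st <- stimuli[[idx[j]]]
    k <- attend_classes[j]
    A[j, k] <- 1
    rows <- ((j - 1) * sz2 + 1):(j * sz2)
    tg[rows] <- as.vector(t(st$masks[, , k]))
    any_obj <- apply(st$masks, c(1, 2), any)
    if (policy == "texture_background") {
      ig[rows] <- as.vector(t(!any_obj))
    } else {
      ig[rows] <- as.vector(t(!st$masks[, , k]))
    }
  }
  list(target = tg, ignore = ig, attend = A)
}

#' Train the modulatory feedback pathway (phase 2)
#'
#' The feedforward parameters are frozen (and verified unchanged); only
#' `fb/*` and `beta/*` groups are updated.  For every example an attended
#' class is sampled uniformly among the classes present in the image, and
#' the pixel-wise BCE is computed under the configured ignore policy.
#'
#' @inheritParams train_feedforward
#' @param config A [train_config()] with `phase = "fb"`.
#' @return `list(net, history)`.
#' @export
train_feedback <- function(net, stimuli, config, val_stimuli = NULL) {
  stopifnot(config$phase == "fb")
  ff_names <- grep("^ff\\.", names(net$params), value = TRUE)
  ff_before <- net$params[ff_names]
  dat <- .prep_data(stimuli)
  present <- lapply(stimuli, function(st) which(st$labels > 0))
  n <- length(stimuli)
  # the feedforward pathway is frozen, so its activations can be computed
  # once for the whole dataset (memory permitting)
  cfg <- net$config
  per_img <- 8 * (3 * cfg$sizes[1]^2 * cfg$features[1] +
                    3 * cfg$sizes[2]^2 * cfg$features[2] +
                    3 * cfg$sizes[3]^2 * cfg$features[3] +
                    cfg$top^2 * cfg$features[3] + cfg$n_classes)
  use_cache <- config$cache_activations %||% (n * per_img < 1.5e9)
  ffcache <- if (use_cache) .precompute_ff(net, dat, n) else NULL
  # layer-sequential calibration of the feedback weights against the
  # trained feedforward statistics (see .calibrate_fb)
  cal_idx <- seq_len(min(64L, n))
  cal_att <- with_seed(config$seed, vapply(cal_idx, function(i) {
    p <- present[[i]]
    if (length(p) == 1) p else sample(p, 1)
  }, integer(1)))
  cal_A <- matrix(0, length(cal_idx), net$config$n_classes)
  cal_A[cbind(seq_along(cal_idx), cal_att)] <- 1
  cal_fw <- if (use_cache) .gather_ff(ffcache, cal_idx)
  else .ff_forward(net, .batch_x(dat$X, cal_idx), length(cal_idx),
                   train = FALSE)
  net <- .calibrate_fb(net, cal_fw, cal_A)
  st_opt <- .adam_new()
  hist <- list()
  t_step <- 0L
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(n, start + config$batch_size - 1)]
        B <- length(idx)
        att <- vapply(idx, function(i) {
          p <- present[[i]]
          if (length(p) == 1) p else sample(p, 1)
        }, integer(1))
        tgt <- .seg_targets(stimuli, idx, att, config$ignore_policy)
        fw <- if (use_cache) .gather_ff(ffcache, idx)
        else .ff_forward(net, .batch_x(dat$X, idx), B, train = FALSE)
        fb <- .fb_forward(net, fw, tgt$attend)
        keep <- !(tgt$ignore > 0)
        # the segmentation objective supervises the V1m feedback units
        # directly -- every mirror channel should reach activity 1 on
        # attended-object pixels and 0 on counted non-attended pixels --
        # plus the scalar read-out map
        c11 <- fb$v1$c1
        F1 <- ncol(c11)
        keep_rep <- matrix(keep, nrow(c11), F1)
        tgt_rep <- matrix(tgt$target, nrow(c11), F1)
        loss_units <- mean(.bce_logits(c11[keep_rep], tgt_rep[keep_rep]))
        loss_map <- mean(.bce_logits(fb$map_logits[keep], tgt$target[keep]))
        loss <- loss_units + loss_map
        if (!is.finite(loss)) stop("train_feedback: loss diverged (NaN)")
        dmap <- matrix(0, nrow(fb$map_logits), 1)
        dmap[keep] <- (sigmoid(fb$map_logits[keep]) - tgt$target[keep]) /
          sum(keep)
        dc11 <- matrix(0, nrow(c11), F1)
        dc11[keep_rep] <- (sigmoid(c11[keep_rep]) - tgt_rep[keep_rep]) /
          sum(keep_rep)
        G <- new.env(parent = emptyenv())
        .fb_backward(net, fw, fb, dmap, G, dc11 = dc11)
        t_step <- t_step + 1L
        net$params <- .adam_step(net$params, G, st_opt, config$learning_rate,
                                 config$weight_decay, t_step)
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      row <- data.frame(epoch = ep, loss = ep_loss / nb)
      if (!is.null(val_stimuli)) {
        ev <- evaluate_segmentation(net, val_stimuli)
        row$val_iou <- ev$mean_iou
        row$val_pixel_abs_error <- ev$pixel_abs_error
      }
      hist[[ep]] <- row
      if (config$verbose)
        message(sprintf("fb epoch %d/%d loss %.4f%s", ep, config$epochs,
                        row$loss,
                        if (!is.null(row$val_iou))
                          sprintf(" val_iou %.3f", row$val_iou) else ""))
    }
  })
  if (!identical(net$params[ff_names], ff_before))
    stop("train_feedback: feedforward parameters changed during phase 2")
  list(net = net, history = do.call(rbind, hist))
}

#' Segmentation metrics on a stimulus set
#'
#' For every stimulus, each present class is attended in turn; the map is
#' compared with that class's mask.
#'
#' @param net Model. @param stimuli Stimuli.
#' @param threshold Decision threshold for IoU / background rate.
#' @param batch_size Batch size.
#' @return `list(mean_iou, pixel_abs_error, background_false_rate, n_eval)`.
#' @export
evaluate_segmentation <- function(net, stimuli, threshold = 0.5,
                                  batch_size = 64L) {
  # expand to (stimulus, attended class) pairs
  pairs <- do.call(rbind, lapply(seq_along(stimuli), function(i) {
    ks <- which(stimuli[[i]]$labels > 0)
    cbind(i = rep(i, length(ks)), k = ks)
  }))
  dat <- .prep_data(stimuli)
  sz <- net$config$input_size
  ious <- numeric(nrow(pairs)); paes <- numeric(nrow(pairs))
  bfrs <- numeric(nrow(pairs))
  for (start in seq(1, nrow(pairs), by = batch_size)) {
    rows <- start:min(nrow(pairs), start + batch_size - 1)
    idx <- pairs[rows, "i"]
    B <- length(rows)
    A <- matrix(0, B, 12)
    A[cbind(seq_len(B), pairs[rows, "k"])] <- 1
    fw <- .ff_forward(net, .batch_x(dat$X, idx), B, train = FALSE)
    fb <- .fb_forward(net, fw, A)
    for (j in seq_len(B)) {
      st <- stimuli[[idx[j]]]
      k <- pairs[rows[j], "k"]
      m <- matrix(fb$map[((j - 1) * sz * sz + 1):(j * sz * sz)], sz, sz,
                  byrow = TRUE)
      ious[rows[j]] <- mask_iou(m, st$masks[, , k], threshold)
      paes[rows[j]] <- pixel_abs_error(m, st$masks[, , k])
      bfrs[rows[j]] <- background_false_rate(m, st$masks, threshold)
    }
  }
  list(mean_iou = mean(ious), pixel_abs_error = mean(paes),
       background_false_rate = mean(bfrs), n_eval = nrow(pairs))
}

# ---------------------------------------------------------------------------
# Checkpoints

#' Save a model checkpoint
#'
#' The archive holds the named parameter groups (`ff/*`, `fb/*`, `beta/*`),
#' batch-norm running statistics and a JSON architecture fingerprint.
#'
#' @param net A `segnet_model`. @param path Output file.
#' @export
save_checkpoint <- function(net, path) {
  bn <- as.list(net$bn)
  saveRDS(list(fingerprint = as.character(net$fingerprint),
               config = unclass(net$config), params = net$params, bn = bn),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file.
#' @param expect_config Optional [seg_config()]; loading fails if the
#'   stored architecture fingerprint does not match.
#' @return A `segnet_model`.
#' @export
load_checkpoint <- function(path, expect_config = NULL) {
  ck <- readRDS(path)
  if (!is.null(expect_config) &&
      !identical(as.character(config_fingerprint(expect_config)),
                 ck$fingerprint))
    stop("load_checkpoint: architecture fingerprint mismatch")
  cfg <- structure(ck$config, class = "seg_config")
  bn <- new.env(parent = emptyenv())
  for (nm in names(ck$bn)) bn[[nm]] <- ck$bn[[nm]]
  structure(list(config = cfg, params = ck$params, bn = bn,
                 fingerprint = ck$fingerprint), class = "segnet_model")
}

#' Checksum of the feedforward parameter group (freeze verification)
#' @param net A `segnet_model`.
#' @export
ff_checksum <- function(net) {
  nm <- sort(grep("^ff\\.", names(net$params), value = TRUE))
  sum(vapply(seq_along(nm),
             function(i) sum(net$params[[nm[i]]] * i), numeric(1)))
}
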