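# Losses, metrics and the two-phase training loop.

smoke_cfg <- seg_config(features = c(2L, 3L, 4L), itm = 6L, input_size = 8L)

test_that("classification loss matches closed forms and the scalar oracle", {
  # logits 0 -> ln 2 per class
  expect_equal(ff_loss(rep(0, 12), rep(c(0, 1), 6)), log(2))
  # saturated logits drive the loss to zero
  y <- c(1, 0, 1, rep(0, 9))
  x <- ifelse(y == 1, 40, -40)
  expect_lt(ff_loss(x, y), 1e-12)
  expect_error(ff_loss(c(Inf, rep(0, 11)), rep(0, 12)), "finite")
  expect_error(ff_loss(rep(0, 12), rep(0.5, 12)), "0/1")

  set.seed(2)
  for (r in 1:30) {
    x <- stats::rnorm(12, sd = 3)
    y <- stats::rbinom(12, 1, 0.4)
    expect_equal(ff_loss(x, y), oracle_bce(x, y), tolerance = 1e-10)
  }
})

test_that("segmentation loss honors the ignore mask and matches the scalar oracle", {
  n <- 64
  set.seed(3)
  x <- stats::rnorm(n, sd = 2)
  y <- stats::rbinom(n, 1, 0.3)
  # perfect logits on counted pixels
  xp <- ifelse(y == 1, 40, -40)
  expect_lt(seg_loss(xp, y, ignore = rep(0, n)), 1e-12)
  # all but one pixel ignored -> that pixel's BCE
  ig <- rep(1, n); ig[5] <- 0
  expect_equal(seg_loss(x, y, ig), oracle_bce(x[5], y[5]))
  expect_error(seg_loss(x, y, rep(1, n)), "ignored")

  for (r in 1:20) {
    x <- stats::rnorm(n, sd = 2)
    y <- stats::rbinom(n, 1, 0.3)
    ig <- stats::rbinom(n, 1, 0.4)
    expect_equal(seg_loss(x, y, ig), oracle_seg_bce(x, y, ig),
                 tolerance = 1e-10)
  }
})

test_that("the three evaluation metrics attain their documented extremes and match counting oracles", {
  set.seed(4)
  lab <- matrix(stats::rbinom(60, 1, 0.3), 5, 12)
  expect_equal(classification_abs_error(lab, lab), 0)
  expect_equal(classification_abs_error(1 - lab, lab), 12)
  expect_equal(classification_abs_error(c(0.9, rep(0, 11)),
                                        c(1, rep(0, 11))), 0.1)
  expect_error(classification_abs_error(rep(0.5, 11), rep(0, 11)), "12")
  expect_error(classification_abs_error(rep(2, 12), rep(0, 12)), "\\[0,1\\]")

  mask <- matrix(FALSE, 8, 8); mask[2:5, 3:6] <- TRUE
  m1 <- matrix(1, 8, 8)
  expect_equal(pixel_abs_error(m1, mask), 0)
  expect_equal(pixel_abs_error(m1 * 0, mask), 1)
  mh <- m1 * 0; mh[2:3, 3:6] <- 1
  expect_equal(pixel_abs_error(mh, mask), 0.5)
  expect_error(pixel_abs_error(m1, mask & FALSE), "empty")

  expect_equal(background_false_rate(m1 * 0, list(mask)), 0)
  expect_equal(background_false_rate(m1, list(mask)), 1)
  expect_error(background_false_rate(m1, list(mask), threshold = 0), "threshold")

  for (r in 1:20) {
    sc <- matrix(stats::runif(60), 5, 12)
    expect_equal(classification_abs_error(sc, lab),
                 oracle_class_abs_error(sc, lab), tolerance = 1e-12)
    mp <- matrix(stats::runif(64), 8, 8)
    expect_equal(pixel_abs_error(mp, mask), oracle_pixel_abs_error(mp, mask),
                 tolerance = 1e-12)
    oth <- matrix(stats::runif(64) > 0.8, 8, 8)
    expect_equal(background_false_rate(mp, list(mask, oth), 0.5),
                 oracle_background_rate(mp, list(mask, oth), 0.5),
                 tolerance = 1e-12)
  }
})

# A miniature dataset of random "stimuli" living on the 8x8 canvas keeps
# the optimizer tests fast; the structure matches real stimuli exactly.
make_mini_data <- function(n, seed) {
  with_seed <- get("with_seed", asNamespace("segnet"))
  with_seed(seed, lapply(seq_len(n), function(i) {
    img <- matrix(stats::runif(64), 8, 8)
    masks <- array(FALSE, c(8, 8, 12))
    k <- sample(1:2, 1)
    r0 <- sample(1:5, 1); c0 <- sample(1:5, 1)
    masks[r0:(r0 + 2), c0:(c0 + 2), k] <- TRUE
    img[masks[, , k]] <- img[masks[, , k]] * 0.5 + (k - 1) * 0.5
    structure(list(image = img,
                   labels = as.numeric(apply(masks, 3, any)),
                   masks = masks, scene = list()), class = "stimulus")
  }))
}

test_that("phase-1 training reduces the loss, updates only ff groups and is seed-reproducible", {
  ds <- make_mini_data(48, 5)
  net <- seg_network(smoke_cfg, seed = 6)
  fb_before <- net$params[grep("^(fb|beta)\\.", names(net$params))]
  cfgtr <- train_config("ff", epochs = 4L, batch_size = 16L, seed = 7)
  fit <- train_feedforward(net, ds, cfgtr)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  # one phase-1 run touches no feedback parameter
  expect_identical(fit$net$params[names(fb_before)], fb_before)
  # reproducible trajectory
  fit2 <- train_feedforward(net, ds, cfgtr)
  expect_equal(fit2$history$loss, fit$history$loss, tolerance = 1e-12)
})

test_that("phase-2 training freezes the feedforward pathway bit-exactly and learns", {
  ds <- make_mini_data(48, 8)
  net <- seg_network(smoke_cfg, seed = 9)
  fit1 <- train_feedforward(net, ds, train_config("ff", epochs = 2L,
                                                  batch_size = 16L, seed = 1))
  ck <- ff_checksum(fit1$net)
  fit2 <- train_feedback(fit1$net, ds,
                         train_config("fb", epochs = 4L, batch_size = 16L,
                                      seed = 2))
  expect_identical(ff_checksum(fit2$net), ck)
  expect_identical(fit2$net$params[grep("^ff\\.", names(fit2$net$params))],
                   fit1$net$params[grep("^ff\\.", names(fit1$net$params))])
  expect_lt(tail(fit2$history$loss, 1), fit2$history$loss[1])
})

test_that("two-phase learning reduces both losses from initialization across seeds", {
  for (s in 1:3) {
    ds <- make_mini_data(40, 100 + s)
    net <- seg_network(smoke_cfg, seed = s)
    f1 <- train_feedforward(net, ds, train_config("ff", epochs = 3L,
                                                  batch_size = 20L, seed = s))
    expect_lt(tail(f1$history$loss, 1), f1$history$loss[1])
    f2 <- train_feedback(f1$net, ds, train_config("fb", epochs = 3L,
                                                  batch_size = 20L, seed = s))
    expect_lt(tail(f2$history$loss, 1), f2$history$loss[1])
  }
})
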