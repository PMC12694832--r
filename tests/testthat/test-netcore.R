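# Network core: modulation equations, gating, architecture, passes.

tiny_cfg <- seg_config(features = c(2L, 3L, 4L), itm = 6L, input_size = 8L)

test_that("modulate implements b = max(0, a (z + beta)) with gating and scaling", {
  # direct arithmetic from the equation
  expect_equal(modulate(0, 5, 1), 0)       # silent units cannot be driven
  expect_equal(modulate(2, 0.5, 0), 1)
  expect_equal(modulate(1, -3, 1), 0)      # rectification
  expect_error(modulate(-1, 0, 0), "non-negative")
  expect_error(modulate(matrix(1, 2, 2), matrix(1, 3, 2), 0), "shape")

  set.seed(1)
  for (r in 1:20) {
    a <- matrix(stats::rexp(50), 10, 5)
    z <- matrix(stats::rnorm(50), 10, 5)
    beta <- stats::rnorm(5)
    b <- modulate(a, z, beta)
    expect_equal(b, oracle_modulate(a, z, beta), tolerance = 1e-12)
    # gating: a = 0 forces b = 0 and c = 0
    a0 <- a; a0[sample(50, 12)] <- 0
    b0 <- modulate(a0, z, beta)
    expect_true(all(b0[a0 == 0] == 0))
    expect_true(all(feedback_signal(b0, a0)[a0 == 0] == 0))
    # multiplicative scaling in a
    lam <- stats::runif(1, 0, 3)
    expect_equal(modulate(lam * a, z, beta), lam * modulate(a, z, beta),
                 tolerance = 1e-12)
    expect_true(all(b >= 0))
  }
})

test_that("feedback_signal is the plain difference and may be negative", {
  a <- matrix(stats::runif(12), 3, 4)
  expect_equal(feedback_signal(a, a), a * 0)
  expect_equal(feedback_signal(1, 2), -1)
  expect_error(feedback_signal(1:3, 1:4), "shape")
})

test_that("attention gating multiplies scores by a one-hot template", {
  s <- c(0.9, 0.1, rep(0, 10))
  g <- attention_gate(s, attention_vector(1))
  expect_equal(g, c(0.9, rep(0, 11)))
  expect_equal(sum(attention_gate(s, attention_vector(5)) != 0), 0)  # score 0
  expect_lte(sum(attention_gate(runif(12), attention_vector(7)) != 0), 1)
  expect_error(attention_gate(s, rep(1, 12)), "one-hot")
  expect_error(attention_gate(s, rep(0, 12)), "one-hot")
})

test_that("every published architecture dimension is honored", {
  net <- seg_network(seg_config(), seed = 1)
  sh <- model_shapes(net)
  expect_equal(sh$v1.b1, c(20, 56, 56))
  expect_equal(sh$v2.b1, c(50, 28, 28))
  expect_equal(sh$v4.b3, c(100, 14, 14))
  expect_equal(sh$down3, c(100, 7, 7))
  expect_equal(sh$itm, 500)
  expect_equal(sh$fcm, 12)
  expect_equal(sh$concat, c(200, 7, 7))

  img <- matrix(stats::runif(56 * 56), 56, 56)
  ff <- feedforward_pass(net, img)
  expect_equal(dim(ff$activities$v1.b1), c(56 * 56, 20))
  expect_equal(dim(ff$activities$v2.b2), c(28 * 28, 50))
  expect_equal(dim(ff$activities$v4.b1), c(14 * 14, 100))
  expect_equal(dim(ff$activities$down3), c(7 * 7, 100))
  expect_equal(dim(ff$activities$itm), c(1, 500))
  expect_length(ff$scores, 12)
  expect_true(all(ff$scores >= 0 & ff$scores <= 1))

  fb <- feedback_pass(net, ff, attention_vector(1))
  expect_equal(fb$concat_channels, 200)
  expect_equal(dim(fb$map), c(56, 56))
  expect_true(all(fb$map >= 0 & fb$map <= 1))
  for (nm in names(fb$state$b)) {
    expect_equal(dim(fb$state$b[[nm]]), dim(ff$activities[[nm]]))
    expect_equal(dim(fb$state$c[[nm]]), dim(ff$activities[[nm]]))
    expect_equal(dim(fb$state$z[[nm]]), dim(ff$activities[[nm]]))
  }
  expect_error(feedforward_pass(net, matrix(0, 28, 28)), "56")
})

test_that("zero input with zero biases propagates zeros when normalization is bypassed", {
  net <- seg_network(tiny_cfg, seed = 2)
  # zero all biases and batch-norm offsets
  for (nm in names(net$params)) {
    if (grepl("\\.(b|be)$", nm)) net$params[[nm]][] <- 0
  }
  ff <- feedforward_pass(net, matrix(0, 8, 8), use_bn = FALSE)
  for (nm in c("v1.b1", "v2.b3", "v4.b2", "down3"))
    expect_true(all(ff$activities[[nm]] == 0))
  expect_true(all(ff$logits == 0))
})

test_that("feedforward quantities are identical across all 12 attention settings while feedback maps differ", {
  net <- seg_network(tiny_cfg, seed = 3)
  img <- matrix(stats::runif(64), 8, 8)
  ff <- feedforward_pass(net, img)
  maps <- vector("list", 12)
  for (k in 1:12) {
    ffk <- feedforward_pass(net, img)
    expect_identical(ffk$scores, ff$scores)
    for (nm in names(ff$activities))
      expect_identical(ffk$activities[[nm]], ff$activities[[nm]])
    maps[[k]] <- feedback_pass(net, ffk, attention_vector(k))$map
  }
  dists <- vapply(2:12, function(k) max(abs(maps[[k]] - maps[[1]])),
                  numeric(1))
  expect_gt(max(dists), 0)  # attention changes the feedback read-out
  expect_error(feedback_pass(net, ff, rep(0.5, 12)), "one-hot")
})

test_that("gating holds across the whole mirror stack for random nets and inputs", {
  for (s in 1:3) {
    net <- seg_network(tiny_cfg, seed = s)
    img <- matrix(stats::runif(64), 8, 8)
    ff <- feedforward_pass(net, img)
    fb <- feedback_pass(net, ff, attention_vector((s %% 12) + 1))
    for (nm in names(fb$state$b)) {
      a <- ff$activities[[nm]]
      expect_true(all(a >= 0))
      expect_true(all(fb$state$b[[nm]] >= 0))
      expect_true(all(fb$state$b[[nm]][a == 0] == 0))
      expect_true(all(fb$state$c[[nm]][a == 0] == 0))
      expect_equal(fb$state$c[[nm]], fb$state$b[[nm]] - a)
    }
  }
})

test_that("checkpoints round-trip and refuse mismatched architectures", {
  net <- seg_network(tiny_cfg, seed = 4)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f, expect_config = tiny_cfg)
  expect_equal(net2$params, net$params)
  img <- matrix(stats::runif(64), 8, 8)
  expect_equal(feedforward_pass(net2, img)$scores,
               feedforward_pass(net, img)$scores)
  expect_error(load_checkpoint(f, expect_config = seg_config()),
               "fingerprint")
  unlink(f)
})
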