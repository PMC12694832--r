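# Time-stepped propagation: wavefront semantics, traces, smoothing, FGM.

ts_cfg <- seg_config(features = c(3L, 4L, 6L), itm = 10L)

make_sim_net <- function(seed = 1) seg_network(ts_cfg, seed = seed)

test_that("initialization is seed-deterministic and settles to the noise fixed point", {
  net <- make_sim_net()
  s1 <- init_state(net, attention_vector(1), seed = 11)
  s2 <- init_state(net, attention_vector(1), seed = 11)
  expect_identical(s1$values, s2$values)
  s3 <- init_state(net, attention_vector(1), seed = 12)
  expect_false(identical(s3$values, s1$values))

  # zero-variance noise equals the response to the constant mean image
  sch0 <- schedule_config(noise_mean = 0.2, noise_sd = 0)
  s0 <- init_state(net, attention_vector(1), sch0, seed = 1)
  const <- matrix(0.2, 56, 56)
  ff <- feedforward_pass(net, const)
  fb <- feedback_pass(net, ff, attention_vector(1))
  expect_equal(s0$values$mv1$l1$b, fb$state$b$v1.b1, tolerance = 1e-10)

  net_noffb <- make_sim_net()
  net_noffb$params <- net_noffb$params[grep("^ff\\.", names(net_noffb$params))]
  expect_error(init_state(net_noffb, attention_vector(1)), "feedback")
})

test_that("stepping a static stimulus reaches the direct-pass fixed point in both granularities", {
  net <- make_sim_net()
  img <- make_background_texture(c(56, 56), texture_spec(30), seed = 2)
  ff <- feedforward_pass(net, img)
  fb <- feedback_pass(net, ff, attention_vector(2))

  for (gr in c("area", "layer")) {
    st <- init_state(net, attention_vector(2), schedule_config(gr), seed = 5)
    x <- matrix(as.vector(t(img)), ncol = 1)
    path <- if (gr == "area") 8 else 24
    for (i in seq_len(path + 2)) st <- sim_step(st, x, net)
    mirror <- if (gr == "area") st$values$mv1$l1 else st$values$`mv1.1`
    expect_equal(mirror$b, fb$state$b$v1.b1, tolerance = 1e-10)
    map <- if (gr == "area") st$values$mv1$map else st$values$`mv1.1`$map
    expect_equal(map, fb$.fb$map, tolerance = 1e-10)
  }
})

test_that("the wavefront crosses exactly one connection per step", {
  net <- make_sim_net()
  imgA <- make_background_texture(c(56, 56), texture_spec(30), seed = 2)
  imgB <- make_background_texture(c(56, 56), texture_spec(120), seed = 3)
  # identical inits; two different stimuli
  stA <- init_state(net, attention_vector(1), seed = 9)
  stB <- init_state(net, attention_vector(1), seed = 9)
  xA <- matrix(as.vector(t(imgA)), ncol = 1)
  xB <- matrix(as.vector(t(imgB)), ncol = 1)
  # node name -> minimal connection distance from the input (area
  # granularity); mirror nodes are reached early through the feedforward
  # activity they modulate, long before class information loops via FCm
  dist <- c(v1 = 1, v2 = 2, v4 = 3, itm = 4, fcm = 5, mv4 = 4, mv2 = 3, mv1 = 2)
  for (tstep in 1:8) {
    stA <- sim_step(stA, xA, net)
    stB <- sim_step(stB, xB, net)
    for (nd in names(dist)) {
      same <- identical(stA$values[[nd]], stB$values[[nd]])
      if (dist[[nd]] > tstep) {
        expect_true(same, label = sprintf("step %d node %s untouched", tstep, nd))
      } else {
        expect_false(same, label = sprintf("step %d node %s stimulus-driven", tstep, nd))
      }
    }
  }
  # feedforward chain is at a fixed point afterwards (static image)
  v1_now <- stA$values$v1
  stA <- sim_step(stA, xA, net)
  expect_identical(stA$values$v1, v1_now)
})

test_that("region time-courses aggregate with SEM across stimuli and FGM is shift-invariant", {
  net <- make_sim_net()
  ds <- lapply(1:3, function(s) make_two_object_scene(seed = 20 + s))
  sch <- schedule_config("area", total_steps = 10)
  tr <- run_timecourse(net, ds, attend = 1, sch, seed = 3)
  expect_s3_class(tr, "trace_set")
  expect_setequal(unique(tr$region), c("figure", "edge", "ground"))
  expect_equal(max(tr$step), 10)
  expect_true(all(is.finite(tr$sem)))
  expect_true(all(tr$n == 3))

  # single stimulus: SEM reported as absent
  tr1 <- run_timecourse(net, ds[1], attend = 1, sch, seed = 3)
  expect_true(all(is.na(tr1$sem)))

  f <- fgm(tr)
  expect_equal(nrow(f), 11)
  # identical figure and ground traces give zero FGM
  tr0 <- tr
  tr0$mean[tr0$region == "figure"] <- tr0$mean[tr0$region == "ground"]
  tr0$mean[tr0$region == "edge"] <- tr0$mean[tr0$region == "ground"]
  f0 <- fgm(tr0)
  expect_true(all(f0$fgm_figure == 0 & f0$fgm_edge == 0))
  # adding a constant to all regions leaves FGM unchanged
  trc <- tr; trc$mean <- trc$mean + 3.7
  expect_equal(fgm(trc)[-1], f[-1])

  # stimuli without the analyzed figure are skipped with a message
  dsd <- compose_scene(list(glyph_spec(4, NULL, 1, seed = 5)),
                       texture_spec(10), seed = 6)
  expect_message(run_timecourse(net, list(ds[[1]], dsd), attend = 1, sch,
                                seed = 1), "skipped")

  # determinism
  tr2 <- run_timecourse(net, ds, attend = 1, sch, seed = 3)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
})

test_that("smooth_trace preserves constants and ramps and matches a direct least-squares filter", {
  expect_equal(smooth_trace(rep(2, 20), 40, 3, 7), rep(2, 40),
               tolerance = 1e-10)
  ramp <- seq(0, 1, length.out = 30)
  sm <- smooth_trace(ramp, 60, 3, 7)
  expect_equal(sm, seq(0, 1, length.out = 60), tolerance = 1e-8)
  expect_error(smooth_trace(1:10, 20, 3, 8), "odd")
  expect_error(smooth_trace(1:10, 20, 7, 7), "order")
  expect_error(smooth_trace(1:3, 5, 3, 7), "length")

  set.seed(8)
  x <- cumsum(stats::rnorm(40))
  sm <- as.numeric(signal::sgolayfilt(x, p = 3, n = 7))
  expect_equal(sm, oracle_sgolay(x, 3, 7), tolerance = 1e-8)
})

test_that("space-time profiles are organized ground-edge-figure with NA for empty bins", {
  net <- make_sim_net()
  ds <- lapply(1:2, function(s) make_two_object_scene(seed = 30 + s))
  sp <- spacetime_profile(net, ds, attend = 1,
                          schedule_config("area", total_steps = 10), seed = 2,
                          max_distance = 6)
  expect_s3_class(sp, "spacetime_profile")
  expect_equal(dim(sp$fgm), c(13, 11))
  expect_equal(sp$bins, -6:6)
  # the 16x16 square supports at most 8 erosions; interior bins beyond
  # the figure half-width are empty, reported NA
  expect_true(all(is.na(sp$fgm["6", ])) || all(is.finite(sp$fgm["6", ])))
  # deep-ground rows are finite (plenty of pixels)
  expect_true(all(is.finite(sp$fgm["-6", ])))
})
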