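# Stimulus generator: textures, figures, glyphs, scenes, region maps.

test_that("background textures are deterministic, orientation-faithful and respect degenerate specs", {
  spec <- texture_spec(orientation = 0)
  t1 <- make_background_texture(c(56, 56), spec, seed = 5)
  t2 <- make_background_texture(c(56, 56), spec, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1 >= 0 & t1 <= 1))

  # zero contrast -> blank canvas
  blank <- make_background_texture(c(56, 56), texture_spec(0, contrast = 0), 1)
  expect_identical(blank, matrix(0, 56, 56))

  # zero density is a degenerate spec
  expect_error(texture_spec(0, element_density = -1), "positive")
  sp0 <- texture_spec(0)
  sp0$element_density <- 0
  expect_error(make_background_texture(c(56, 56), sp0, 1), "density")

  # dominant spectral orientation matches the requested bar orientation
  # (Fourier-peak oracle, independent estimator)
  h <- make_background_texture(c(56, 56), texture_spec(0, element_length = 9), 3)
  v <- make_background_texture(c(56, 56), texture_spec(90, element_length = 9), 3)
  oh <- oracle_fft_orientation(h)
  ov <- oracle_fft_orientation(v)
  d <- abs(oh - ov) %% 180
  expect_lt(min(d, 180 - d) - 90, 25)  # axes differ by ~90 degrees
  expect_lt(min(oh, 180 - oh), 25)     # horizontal bars -> orientation ~0
})

test_that("texture figures rasterize exactly and reject invalid specs", {
  canvas <- matrix(0, 56, 56)
  fig <- figure_spec("square", c(28, 28), c(10, 10), 0, texture_spec(90))
  res <- render_texture_figure(canvas, fig, seed = 1)
  expect_equal(sum(res$mask), 100)

  # rotated square against an independent point-in-polygon rasterizer
  for (rot in c(15, 45, 77)) {
    figr <- figure_spec("square", c(28.3, 27.6), c(12, 12), rot, texture_spec(90))
    resr <- render_texture_figure(canvas, figr, seed = 1)
    expect_equal(sum(resr$mask),
                 oracle_rect_pixels(56, 56, c(28.3, 27.6), c(12, 12), rot))
  }

  expect_error(figure_spec("square", c(28, 28), c(10, 14), 0, texture_spec(90)),
               "equal side lengths")
  out <- figure_spec("rectangle", c(5, 28), c(14, 20), 0, texture_spec(90))
  expect_error(render_texture_figure(canvas, out, 1), "boundary")
})

test_that("digit glyphs are centered, scale correctly and threshold to empty", {
  canvas <- matrix(0, 56, 56)
  g <- glyph_spec(3, c(28, 28), scale = 1, seed = 4)
  res <- render_glyph(canvas, g)
  ctr <- which(res$mask, arr.ind = TRUE)
  expect_lt(abs(mean(ctr[, 1]) - 28), 2.5)
  expect_lt(abs(mean(ctr[, 2]) - 28), 2.5)

  # scale doubling quadruples the stroke count within rasterization
  # tolerance, cross-checked with a nearest-neighbour up-sampling oracle
  g2 <- glyph_spec(3, c(28, 28), scale = 2, seed = 4)
  res2 <- render_glyph(canvas, g2)
  bm <- synth_glyph(3, 4)
  nn4 <- sum(oracle_nn_upsample(bm, 2) > 0.5)
  expect_lt(abs(sum(res2$mask) - nn4) / nn4, 0.25)
  expect_gt(sum(res2$mask), 2.5 * sum(res$mask))

  # nothing exceeds threshold 1.0
  res_empty <- render_glyph(canvas, g, threshold = 1.0)
  expect_false(any(res_empty$mask))
  expect_identical(res_empty$canvas, canvas)

  # clipping raises
  expect_error(render_glyph(canvas, glyph_spec(3, c(3, 28), seed = 4)),
               "clipped")
})

test_that("procedural glyph classes are reproducible and mutually distinguishable", {
  expect_identical(synth_glyph(7, 11), synth_glyph(7, 11))
  expect_error(synth_glyph(10, 1), "0..9")

  # a '1' is taller than wide
  b1 <- synth_glyph(1, 2) > 0.5
  rows <- range(which(rowSums(b1) > 0)); cols <- range(which(colSums(b1) > 0))
  expect_gt(diff(rows), diff(cols))

  # intra-class pixel overlap beats inter-class overlap over seeded renders
  n_seed <- 25
  bitmaps <- lapply(0:9, function(d)
    lapply(seq_len(5), function(s) synth_glyph(d, s) > 0.5))
  jacc <- function(a, b) sum(a & b) / max(1, sum(a | b))
  intra <- mean(vapply(0:9, function(d) {
    bs <- bitmaps[[d + 1]]
    mean(vapply(1:4, function(i) jacc(bs[[i]], bs[[i + 1]]), numeric(1)))
  }, numeric(1)))
  inter <- mean(vapply(0:9, function(d) {
    mean(vapply(setdiff(0:9, d), function(e)
      jacc(bitmaps[[d + 1]][[1]], bitmaps[[e + 1]][[1]]), numeric(1)))
  }, numeric(1)))
  expect_gt(intra, inter)
})

test_that("compose_scene yields consistent labels, masks and overlap handling", {
  st <- make_two_object_scene()
  expect_s3_class(st, "stimulus")
  expect_equal(st$labels, c(1, 1, rep(0, 10)))
  # label-mask consistency
  expect_equal(st$labels, as.numeric(apply(st$masks, 3, any)))
  # masks disjoint
  expect_lte(max(apply(st$masks, c(1, 2), sum)), 1)

  # square + two digits
  st3 <- compose_scene(
    list(figure_spec("square", NULL, c(16, 16), 10, texture_spec(115)),
         glyph_spec(5, NULL, 1, seed = 1), glyph_spec(6, NULL, 1, seed = 2)),
    texture_spec(25), seed = 7)
  expect_equal(sum(st3$labels), 3)
  expect_equal(which(st3$labels > 0), c(1, 8, 9))

  # forced identical centers -> placement error
  expect_error(compose_scene(
    list(glyph_spec(2, c(28, 28), seed = 1), glyph_spec(3, c(28, 28), seed = 2)),
    texture_spec(25), seed = 1), "overlap")

  expect_error(compose_scene(list(), texture_spec(25), 1), "1 to 3")

  # figure texture must differ from background orientation
  expect_error(compose_scene(
    list(figure_spec("square", c(28, 28), c(16, 16), 0, texture_spec(25))),
    texture_spec(25), seed = 1), "orientation")
})

test_that("generated datasets are reproducible with sensible class statistics", {
  d1 <- generate_dataset(10, "square", seed = 3)
  expect_length(d1, 10)
  expect_true(all(vapply(d1, function(s) s$labels[1] == 1, logical(1))))

  d2 <- generate_dataset(8, c("square", "rectangle", "0", "7"), seed = 9)
  d3 <- generate_dataset(8, c("square", "rectangle", "0", "7"), seed = 9)
  expect_identical(d2, d3)
  expect_error(generate_dataset(5, character(0), seed = 1), "empty")

  # per-class frequency within 3 binomial SD of the uniform-draw
  # expectation (objects drawn without replacement from the pool)
  n <- 300
  pool <- c("square", "rectangle", "0", "1")
  dd <- generate_dataset(n, pool, seed = 17)
  counts <- colSums(t(vapply(dd, function(s) s$labels, numeric(12))))[1:4]
  # E[#objects per image] = mean(1:4-capped count); classes symmetric
  nobj <- vapply(dd, function(s) sum(s$labels), numeric(1))
  p <- mean(nobj) / 4
  expect_true(all(abs(counts - n * p) <= 3 * sqrt(n * p * (1 - p)) + 1e-9))
})

test_that("region maps partition the canvas and match the brute-force oracle", {
  mask <- matrix(FALSE, 56, 56); mask[20:29, 20:29] <- TRUE
  rm1 <- region_map(mask, edge_width = 1)
  expect_equal(sum(rm1$assignment == "figure"), 64)  # 8x8 after erosion
  expect_equal(sum(rm1$assignment %in% c("figure", "edge")),
               sum(oracle_dilate(mask, 1)))
  expect_equal(rm1$assignment == "figure", oracle_erode(mask, 1))

  rm2 <- region_map(mask, edge_width = 2)
  # exact partition
  expect_equal(sum(table(rm2$assignment)), 56 * 56)

  # full-canvas mask leaves no ground
  full <- matrix(TRUE, 56, 56)
  expect_equal(sum(region_map(full, 1)$assignment == "ground"), 0)

  # other objects are excluded, never ground
  other <- matrix(FALSE, 56, 56); other[40:45, 40:45] <- TRUE
  rm3 <- region_map(mask, 2, list(other))
  expect_true(all(rm3$assignment[other] == "excluded"))

  expect_error(region_map(mask, edge_width = 0), "edge_width")
  expect_error(region_map(matrix(FALSE, 8, 8), 1), "empty")
})

test_that("figures are camouflaged: luminance matched between figure and ground", {
  diffs <- vapply(1:6, function(s) {
    st <- compose_scene(
      list(figure_spec("square", NULL, c(20, 20), stats::runif(1, 0, 180),
                       texture_spec(115))),
      texture_spec(25), seed = s * 13)
    rm <- region_map(st$masks[, , 1], 2)
    abs(mean(st$image[rm$assignment == "figure"]) -
          mean(st$image[rm$assignment == "ground"]))
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
  expect_true(all(diffs < 0.08))
})
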