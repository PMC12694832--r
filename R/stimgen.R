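# SegMNIST-style stimulus generation: oriented-texture backgrounds,
# texture-defined squares/rectangles, digit glyphs, ground-truth masks and
# figure/edge/ground region maps.
#
# Class order everywhere: 1 = square, 2 = rectangle, 3:12 = digits 0:9.

#' Object class order used throughout the package
#'
#' Class 1 is the texture square, class 2 the texture rectangle, classes
#' 3-12 the digits 0-9.  Labels, masks, scores and attention vectors all
#' follow this order.
#' @export
CLASS_NAMES <- c("square", "rectangle", as.character(0:9))

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of an oriented line-element texture
#'
#' Textures are fields of short oriented bars.  A figure is defined purely
#' by a change in element orientation, never by luminance, so figure and
#' ground have matched first-order statistics (camouflage).
#'
#' @param orientation Element orientation in degrees; wraps modulo 180.
#'   0 runs along image rows (horizontal).
#' @param element_density Elements per 100 px^2.
#' @param element_length,element_width Bar geometry in px.
#' @param jitter Positional jitter (px standard deviation) applied to the
#'   element grid.
#' @param contrast Peak bar intensity in (0, 1]; 0 gives a blank texture.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(orientation, element_density = 7, element_length = 5,
                         element_width = 1.5, jitter = 1, contrast = 1) {
  if (element_density < 0 || element_length <= 0 || element_width <= 0)
    stop("texture_spec: density, length and width must be positive")
  if (contrast < 0 || contrast > 1) stop("texture_spec: contrast must be in [0, 1]")
  structure(list(orientation = orientation %% 180, element_density = element_density,
                 element_length = element_length, element_width = element_width,
                 jitter = jitter, contrast = contrast),
            class = "texture_spec")
}

#' Specification of a texture-defined figure (square or rectangle)
#'
#' @param shape `"square"` or `"rectangle"`.
#' @param center `(row, col)` center in px, or `NULL` to let
#'   [compose_scene()] choose a non-overlapping placement.
#' @param side_lengths `(h, w)` in px; a square requires `h == w`.
#' @param rotation Rotation of the outline in degrees.
#' @param texture A [texture_spec()] for the figure interior; its
#'   orientation must differ from the background orientation.
#' @return An object of class `figure_spec`.
#' @export
figure_spec <- function(shape, center = NULL, side_lengths, rotation = 0,
                        texture) {
  shape <- match.arg(shape, c("square", "rectangle"))
  if (shape == "square" && side_lengths[1] != side_lengths[2])
    stop("figure_spec: a square must have equal side lengths")
  if (shape == "rectangle" && side_lengths[1] == side_lengths[2])
    stop("figure_spec: a rectangle must have unequal side lengths")
  if (any(side_lengths <= 0)) stop("figure_spec: side lengths must be positive")
  stopifnot(inherits(texture, "texture_spec"))
  structure(list(shape = shape, center = center, side_lengths = side_lengths,
                 rotation = rotation, texture = texture),
            class = "figure_spec")
}

#' Specification of a digit glyph
#'
#' @param digit_class Integer 0-9.
#' @param center `(row, col)` center in px or `NULL` (placed by
#'   [compose_scene()]).
#' @param scale Multiplicative scale relative to the native 28x28 bitmap.
#' @param source `"procedural"` (built-in stroke-skeleton glyphs) or
#'   `"mnist"` (bitmap supplied at render time).
#' @param seed Seed for the procedural glyph's shape jitter.
#' @return An object of class `glyph_spec`.
#' @export
glyph_spec <- function(digit_class, center = NULL, scale = 1,
                       source = c("procedural", "mnist"), seed = 0L) {
  if (!digit_class %in% 0:9) stop("glyph_spec: digit_class must be in 0..9")
  if (scale <= 0) stop("glyph_spec: scale must be positive")
  structure(list(digit_class = as.integer(digit_class), center = center,
                 scale = scale, source = match.arg(source),
                 seed = as.integer(seed)),
            class = "glyph_spec")
}

# ---------------------------------------------------------------------------
# Texture synthesis

# Fast clamp to [0, 1] (avoids the generic pmin/pmax dispatch overhead).
.clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Draw anti-aliased oriented bars into an H x W canvas (max compositing);
# rasterized by the compiled kernel.
.draw_bars <- function(img, cy, cx, theta_deg, len, wid, contrast) {
  cpp_draw_bars(img, cy, cx, theta_deg, len, wid, contrast)
}

# Jittered-grid element centers for a given density.
.element_centers <- function(H, W, density, jitter) {
  n_elem <- max(1, round(density * H * W / 100))
  s <- sqrt(H * W / n_elem)
  gy <- seq(s / 2, H, by = s); gx <- seq(s / 2, W, by = s)
  cy <- rep(gy, times = length(gx)) + stats::rnorm(length(gy) * length(gx), 0, jitter)
  cx <- rep(gx, each = length(gy)) + stats::rnorm(length(gy) * length(gx), 0, jitter)
  list(cy = cy, cx = cx)
}

#' Generate an oriented-texture background
#'
#' Renders a field of anti-aliased oriented bars on a jittered grid.
#' Deterministic for a fixed seed.
#'
#' @param size `(rows, cols)` of the canvas.
#' @param spec A [texture_spec()].
#' @param seed Integer seed.
#' @return A numeric matrix in `[0, 1]`.
#' @export
make_background_texture <- function(size, spec, seed) {
  stopifnot(inherits(spec, "texture_spec"), all(size > 0))
  if (spec$element_density == 0) stop("make_background_texture: zero element density")
  H <- size[1]; W <- size[2]
  img <- matrix(0, H, W)
  if (spec$contrast == 0) return(img)
  with_seed(seed, {
    ctr <- .element_centers(H, W, spec$element_density, spec$jitter)
    img <- .draw_bars(img, ctr$cy, ctr$cx, spec$orientation,
                      spec$element_length, spec$element_width, spec$contrast)
  })
  img
}

# ---------------------------------------------------------------------------
# Figures

# Logical mask of a rotated rectangle; half-open pixel boxes in the
# rotated frame so an axis-aligned h x w figure covers exactly h*w pixels.
.rect_mask <- function(H, W, center, hw, rotation) {
  th <- rotation * pi / 180
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- rr - center[1]; dx <- cc - center[2]
  u <- dx * cos(th) + dy * sin(th)    # width axis
  v <- -dx * sin(th) + dy * cos(th)   # height axis
  (v >= -hw[1] / 2) & (v < hw[1] / 2) & (u >= -hw[2] / 2) & (u < hw[2] / 2)
}

.rect_corners <- function(center, hw, rotation) {
  th <- rotation * pi / 180
  u <- c(-1, 1, 1, -1) * hw[2] / 2
  v <- c(-1, -1, 1, 1) * hw[1] / 2
  rbind(row = center[1] + u * sin(th) + v * cos(th),
        col = center[2] + u * cos(th) - v * sin(th))
}

#' Render a texture-defined figure onto a canvas
#'
#' Pixels inside the (possibly rotated) outline are replaced with the
#' figure's own texture; the returned mask marks exactly those pixels.
#'
#' @param canvas Numeric matrix (modified copy is returned).
#' @param fig A [figure_spec()] with a non-`NULL` center.
#' @param seed Seed for the figure texture.
#' @return `list(canvas, mask)` where `mask` is logical.
#' @export
render_texture_figure <- function(canvas, fig, seed) {
  stopifnot(inherits(fig, "figure_spec"), !is.null(fig$center))
  H <- nrow(canvas); W <- ncol(canvas)
  corners <- .rect_corners(fig$center, fig$side_lengths, fig$rotation)
  if (any(corners["row", ] < 0.5) || any(corners["row", ] > H + 0.5) ||
      any(corners["col", ] < 0.5) || any(corners["col", ] > W + 0.5))
    stop("render_texture_figure: figure crosses the canvas boundary")
  mask <- .rect_mask(H, W, fig$center, fig$side_lengths, fig$rotation)
  tex <- make_background_texture(c(H, W), fig$texture, seed)
  canvas[mask] <- tex[mask]
  list(canvas = canvas, mask = mask)
}

# ---------------------------------------------------------------------------
# Digit glyphs

.arc_pts <- function(cx, cy, rx, ry, a0, a1, n = 28) {
  a <- seq(a0, a1, length.out = n)
  cbind(x = cx + rx * cos(a), y = cy - ry * sin(a))
}

# Stroke skeletons per digit in unit coordinates (x right, y down).
.glyph_skeleton <- function(digit) {
  P <- function(...) rbind(...)
  switch(as.character(digit),
    "0" = list(.arc_pts(0.5, 0.5, 0.26, 0.36, 0, 2 * pi, 40)),
    "1" = list(P(c(0.36, 0.26), c(0.52, 0.12), c(0.52, 0.88))),
    "2" = list(rbind(.arc_pts(0.5, 0.32, 0.24, 0.2, pi, 0, 20),
                     c(0.26, 0.84), c(0.76, 0.84))),
    "3" = list(.arc_pts(0.46, 0.3, 0.24, 0.18, pi * 0.85, -pi / 2, 20),
               .arc_pts(0.46, 0.68, 0.26, 0.2, pi / 2, -pi * 0.85, 20)),
    "4" = list(P(c(0.64, 0.12), c(0.24, 0.62), c(0.8, 0.62)),
               P(c(0.64, 0.4), c(0.64, 0.88))),
    "5" = list(P(c(0.74, 0.14), c(0.3, 0.14), c(0.28, 0.45)),
               .arc_pts(0.47, 0.64, 0.26, 0.22, pi * 0.75, -pi * 0.6, 24)),
    "6" = list(rbind(.arc_pts(0.58, 0.3, 0.3, 0.26, pi / 3, pi, 14)[-14, ],
                     .arc_pts(0.5, 0.66, 0.22, 0.22, pi, -pi, 32))),
    "7" = list(P(c(0.24, 0.15), c(0.76, 0.15), c(0.42, 0.88))),
    "8" = list(.arc_pts(0.5, 0.3, 0.2, 0.17, 0, 2 * pi, 28),
               .arc_pts(0.5, 0.67, 0.24, 0.21, 0, 2 * pi, 28)),
    "9" = list(.arc_pts(0.5, 0.34, 0.22, 0.22, 0, 2 * pi, 28),
               P(c(0.72, 0.34), c(0.66, 0.88))))
}

.render_polyline <- function(img, pts, thick) {
  cpp_draw_polyline(img, pts[, 1], pts[, 2], thick)
}

#' Procedurally render a 28x28 digit bitmap
#'
#' Each digit class has a fixed stroke skeleton; the seed jitters stroke
#' thickness, slant and placement so repeated renders of one class vary
#' like handwriting while staying recognizable.
#'
#' @param digit_class Integer 0-9.
#' @param seed Integer seed.
#' @return A 28x28 numeric matrix in `[0, 1]`.
#' @export
synth_glyph <- function(digit_class, seed) {
  if (!is.numeric(digit_class) || !digit_class %in% 0:9)
    stop("synth_glyph: digit_class must be in 0..9")
  with_seed(as.integer((as.numeric(seed) * 17 + digit_class) %% 2147483647), {
    slant <- stats::rnorm(1, 0, 0.07)
    thick <- pmax(1.1, stats::rnorm(1, 1.9, 0.3))
    sc <- stats::runif(1, 0.92, 1.05)
    off <- stats::rnorm(2, 0, 0.4)
    img <- matrix(0, 28, 28)
    for (pl in .glyph_skeleton(digit_class)) {
      x <- pl[, 1]; y <- pl[, 2]
      x <- x + slant * (0.5 - y)                       # shear
      x <- (x - 0.5) * sc + 0.5; y <- (y - 0.5) * sc + 0.5
      pts <- cbind(x * 22 + 3.5 + off[1], y * 22 + 3.5 + off[2])
      img <- .render_polyline(img, pts, thick)
    }
    img
  })
}

#' Bilinear image resize
#' @noRd
.resize_bilinear <- function(m, oh, ow) {
  H <- nrow(m); W <- ncol(m)
  ry <- (seq_len(oh) - 0.5) * H / oh + 0.5
  rx <- (seq_len(ow) - 0.5) * W / ow + 0.5
  y0 <- pmin(H, pmax(1, floor(ry))); y1 <- pmin(H, y0 + 1)
  x0 <- pmin(W, pmax(1, floor(rx))); x1 <- pmin(W, x0 + 1)
  fy <- pmin(1, pmax(0, ry - y0)); fx <- pmin(1, pmax(0, rx - x0))
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  FY <- matrix(fy, oh, ow); FX <- matrix(fx, oh, ow, byrow = TRUE)
  a * (1 - FY) * (1 - FX) + b * (1 - FY) * FX + c_ * FY * (1 - FX) + d * FY * FX
}

#' Render a digit glyph onto a canvas
#'
#' The glyph bitmap is scaled, thresholded into stroke pixels, and the
#' strokes overwrite the canvas; the mask is exactly the stroke pixels.
#'
#' @param canvas Numeric matrix.
#' @param glyph A [glyph_spec()] with a non-`NULL` center.
#' @param threshold Stroke threshold on the scaled bitmap.
#' @param bitmap Optional 28x28 bitmap (required when `source = "mnist"`).
#' @return `list(canvas, mask)`.
#' @export
render_glyph <- function(canvas, glyph, threshold = 0.5, bitmap = NULL) {
  stopifnot(inherits(glyph, "glyph_spec"), !is.null(glyph$center))
  if (is.null(bitmap)) {
    if (glyph$source == "mnist")
      stop("render_glyph: source='mnist' requires a bitmap")
    bitmap <- synth_glyph(glyph$digit_class, glyph$seed)
  }
  s <- max(1L, round(28 * glyph$scale))
  bm <- .resize_bilinear(bitmap, s, s)
  stroke <- bm > threshold
  H <- nrow(canvas); W <- ncol(canvas)
  r0 <- round(glyph$center[1] - s / 2); c0 <- round(glyph$center[2] - s / 2)
  mask <- matrix(FALSE, H, W)
  if (!any(stroke)) return(list(canvas = canvas, mask = mask))
  sr <- which(stroke, arr.ind = TRUE)
  rr <- r0 + sr[, 1]; cc <- c0 + sr[, 2]
  if (any(rr < 1 | rr > H | cc < 1 | cc > W))
    stop("render_glyph: glyph clipped by the canvas boundary")
  canvas[cbind(rr, cc)] <- bm[sr]
  mask[cbind(rr, cc)] <- TRUE
  list(canvas = canvas, mask = mask)
}

# ---------------------------------------------------------------------------
# Scenes and datasets

.spec_class_index <- function(spec) {
  if (inherits(spec, "figure_spec")) return(if (spec$shape == "square") 1L else 2L)
  if (inherits(spec, "glyph_spec")) return(3L + spec$digit_class)
  stop("unknown object spec")
}

# Sample a center so the object fits the canvas with the given half extent.
.sample_center <- function(H, W, half_h, half_w) {
  c(stats::runif(1, 1 + half_h, H - half_h), stats::runif(1, 1 + half_w, W - half_w))
}

.object_half_extent <- function(spec) {
  if (inherits(spec, "figure_spec")) {
    th <- spec$rotation * pi / 180
    h <- spec$side_lengths[1]; w <- spec$side_lengths[2]
    hh <- (abs(h * cos(th)) + abs(w * sin(th))) / 2 + 1
    hw <- (abs(w * cos(th)) + abs(h * sin(th))) / 2 + 1
    c(hh, hw)
  } else {
    s <- round(28 * spec$scale) / 2 + 1
    c(s, s)
  }
}

#' Compose a full stimulus from object specifications
#'
#' Renders the background texture, then each object in turn.  Objects with
#' `center = NULL` are placed uniformly at random; placements whose masks
#' would overlap an earlier object are resampled (up to `max_tries`).
#' Explicitly centered objects that overlap raise an error.
#'
#' @param scene List of 1-3 [figure_spec()] / [glyph_spec()] objects.
#' @param background A [texture_spec()] for the background.
#' @param seed Integer seed.
#' @param size Canvas size, default `c(56, 56)`.
#' @param max_tries Placement attempts per object.
#' @return An object of class `stimulus`: `list(image, labels, masks, scene)`
#'   with `labels` a multi-hot length-12 vector and `masks` a
#'   `H x W x 12` logical array.
#' @export
compose_scene <- function(scene, background, seed, size = c(56, 56),
                          max_tries = 100) {
  stopifnot(inherits(background, "texture_spec"))
  if (length(scene) < 1 || length(scene) > 3)
    stop("compose_scene: a scene holds 1 to 3 objects")
  H <- size[1]; W <- size[2]
  with_seed(seed, {
    canvas <- make_background_texture(size, background, seed = sample.int(2^30, 1))
    masks <- array(FALSE, c(H, W, 12))
    occupied <- matrix(FALSE, H, W)
    placed <- vector("list", length(scene))
    for (i in seq_along(scene)) {
      sp <- scene[[i]]
      if (inherits(sp, "figure_spec") &&
          isTRUE(all.equal(sp$texture$orientation %% 180,
                           background$orientation %% 180)))
        stop("compose_scene: figure texture orientation equals the background")
      fixed <- !is.null(sp$center)
      ok <- FALSE
      for (try in seq_len(if (fixed) 1L else max_tries)) {
        spi <- sp
        if (!fixed) {
          he <- .object_half_extent(sp)
          spi$center <- .sample_center(H, W, he[1], he[2])
        }
        res <- if (inherits(spi, "figure_spec"))
          render_texture_figure(canvas, spi, seed = sample.int(2^30, 1))
        else render_glyph(canvas, spi, bitmap = attr(spi, "bitmap"))
        if (!any(res$mask & occupied)) {
          ok <- TRUE
          canvas <- res$canvas
          k <- .spec_class_index(spi)
          masks[, , k] <- masks[, , k] | res$mask
          occupied <- occupied | res$mask
          placed[[i]] <- spi
          break
        }
      }
      if (!ok) stop("compose_scene: could not place object ", i,
                    " without overlap")
    }
    labels <- as.numeric(apply(masks, 3, any))
    canvas <- pmin(1, pmax(0, canvas))
    dim(canvas) <- c(H, W)
    structure(list(image = canvas, labels = labels,
                   masks = masks, scene = placed),
              class = "stimulus")
  })
}

#' @export
print.stimulus <- function(x, ...) {
  present <- CLASS_NAMES[x$labels > 0]
  cat(sprintf("<stimulus> %dx%d, objects: %s\n", nrow(x$image), ncol(x$image),
              paste(present, collapse = ", ")))
  invisible(x)
}

# Random object spec for one class index under the default study conditions.
.random_spec <- function(class_idx, bg_orientation) {
  fig_tex <- texture_spec(orientation = bg_orientation + 90)
  if (class_idx == 1L) {
    s <- stats::runif(1, 14, 28)
    figure_spec("square", NULL, c(s, s), rotation = stats::runif(1, 0, 180),
                texture = fig_tex)
  } else if (class_idx == 2L) {
    # clearly elongated: aspect ratio 1.5-2, sides within the 14-28 range
    h <- stats::runif(1, 14, 18)
    w <- h * stats::runif(1, 1.5, min(2, 28 / h))
    figure_spec("rectangle", NULL, c(h, w), rotation = stats::runif(1, 0, 180),
                texture = fig_tex)
  } else {
    glyph_spec(class_idx - 3L, NULL, scale = stats::runif(1, 0.75, 1.5),
               seed = sample.int(2^30, 1))
  }
}

#' Generate a reproducible stimulus dataset
#'
#' Each stimulus holds 1-3 objects (uniform count, capped at the pool
#' size) with classes drawn without replacement from `class_pool`, on an
#' oriented texture background whose orientation is uniform in [0, 180);
#' figure textures are orthogonal to the background.
#'
#' @param n Number of stimuli.
#' @param class_pool Character vector of class names (subset of
#'   `c("square", "rectangle", "0".."9")`) or integer indices 1..12.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param size Canvas size.
#' @param mnist_dir Optional directory with MNIST IDX files
#'   (`train-images-idx3-ubyte`, `train-labels-idx1-ubyte`); when given,
#'   digit bitmaps are drawn from MNIST instead of the procedural glyphs.
#' @return A list of [compose_scene()] stimuli.
#' @export
generate_dataset <- function(n, class_pool = CLASS_NAMES, seed,
                             size = c(56, 56), mnist_dir = NULL) {
  stopifnot(n > 0)
  if (is.character(class_pool)) {
    pool <- match(class_pool, CLASS_NAMES)
    if (anyNA(pool)) stop("generate_dataset: unknown class names")
  } else pool <- as.integer(class_pool)
  if (length(pool) == 0) stop("generate_dataset: empty class pool")
  mnist <- if (!is.null(mnist_dir)) read_mnist(mnist_dir) else NULL
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      n_obj <- sample.int(min(3L, length(pool)), 1)
      # crowded scenes (e.g. several large figures) may be impossible to
      # place disjointly; resample the scene geometry a bounded number of
      # times before giving up
      for (attempt in 1:25) {
        classes <- if (length(pool) == 1) pool else sample(pool, n_obj)
        # orientations follow the texture-segregation convention of the
        # monkey experiments these stimuli emulate: one of four discrete
        # axes, with figure textures orthogonal to the background
        bg_or <- sample(c(0, 45, 90, 135), 1)
        scene <- lapply(classes, .random_spec, bg_orientation = bg_or)
        if (!is.null(mnist)) {
          for (j in seq_along(scene)) {
            if (inherits(scene[[j]], "glyph_spec")) {
              cand <- which(mnist$labels == scene[[j]]$digit_class)
              pick <- cand[sample.int(length(cand), 1)]
              scene[[j]]$source <- "mnist"
              attr(scene[[j]], "bitmap") <- mnist$images[, , pick]
            }
          }
        }
        stim <- tryCatch(
          compose_scene(scene, texture_spec(orientation = bg_or),
                        seed = sample.int(2^30, 1), size = size),
          error = function(e) NULL)
        if (!is.null(stim)) return(stim)
      }
      stop("generate_dataset: could not compose stimulus ", i)
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read MNIST IDX-format image and label files
#'
#' @param dir Directory holding `train-images-idx3-ubyte` and
#'   `train-labels-idx1-ubyte` (uncompressed).
#' @return `list(images = 28x28xN array in [0,1], labels = integer vector)`.
#' @export
read_mnist <- function(dir) {
  imf <- file.path(dir, "train-images-idx3-ubyte")
  lbf <- file.path(dir, "train-labels-idx1-ubyte")
  if (!file.exists(imf) || !file.exists(lbf))
    stop("read_mnist: IDX files not found in ", dir)
  con <- file(imf, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, integer(), 1, size = 4, endian = "big")
  if (magic != 2051L) stop("read_mnist: bad image file magic")
  dims <- readBin(con, integer(), 3, size = 4, endian = "big")
  px <- readBin(con, integer(), prod(dims), size = 1, signed = FALSE)
  images <- aperm(array(px / 255, dim = c(dims[3], dims[2], dims[1])), c(2, 1, 3))
  con2 <- file(lbf, "rb"); on.exit(close(con2), add = TRUE)
  magic2 <- readBin(con2, integer(), 1, size = 4, endian = "big")
  if (magic2 != 2049L) stop("read_mnist: bad label file magic")
  nl <- readBin(con2, integer(), 1, size = 4, endian = "big")
  labels <- readBin(con2, integer(), nl, size = 1, signed = FALSE)
  list(images = images, labels = labels)
}

# ---------------------------------------------------------------------------
# Region maps

# Box dilation/erosion with Chebyshev radius w (shift-OR / shift-AND).
.dilate_box <- function(mask, w) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (dy in -w:w) for (dx in -w:w) {
    rs <- max(1, 1 + dy):min(H, H + dy)
    rt <- rs - dy
    cs <- max(1, 1 + dx):min(W, W + dx)
    ct <- cs - dx
    out[rt, ct] <- out[rt, ct] | mask[rs, cs]
  }
  out
}

.erode_box <- function(mask, w) !.dilate_box(!mask, w)

#' Assign figure / edge / ground / excluded regions for one object
#'
#' The edge band is `dilate(mask, w) \ erode(mask, w)` (box structuring
#' element, Chebyshev radius `w` on each side), the figure region is the
#' eroded mask, pixels of other objects are `excluded`, and everything
#' else is ground.
#'
#' @param mask Logical matrix of the object of interest (non-empty).
#' @param edge_width Band half-width in px (>= 1).
#' @param other_masks List of logical matrices for the other objects.
#' @return Object of class `region_map`: `list(assignment, edge_width)` with
#'   `assignment` a character matrix over
#'   `"figure"`, `"edge"`, `"ground"`, `"excluded"`.
#' @export
region_map <- function(mask, edge_width = 2, other_masks = list()) {
  if (edge_width < 1) stop("region_map: edge_width must be >= 1")
  if (!any(mask)) stop("region_map: empty object mask")
  dil <- .dilate_box(mask, edge_width)
  ero <- .erode_box(mask, edge_width)
  others <- Reduce(`|`, other_masks, matrix(FALSE, nrow(mask), ncol(mask)))
  assignment <- matrix("ground", nrow(mask), ncol(mask))
  assignment[others & !dil] <- "excluded"
  assignment[dil & !ero] <- "edge"
  assignment[ero] <- "figure"
  structure(list(assignment = assignment, edge_width = edge_width),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  tb <- table(factor(x$assignment, c("figure", "edge", "ground", "excluded")))
  cat("<region_map>", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Export

#' Write stimuli to disk (PNG + JSON sidecar + mask CSVs + manifest)
#'
#' @param stimuli List of stimuli from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_stimuli <- function(stimuli, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(stimuli), function(i) {
    st <- stimuli[[i]]
    base <- sprintf("stim_%05d", i)
    if (requireNamespace("png", quietly = TRUE))
      png::writePNG(st$image, file.path(dir, paste0(base, ".png")))
    meta <- list(labels = st$labels,
                 classes = CLASS_NAMES[st$labels > 0],
                 scene = lapply(st$scene, function(sp) {
                   o <- unclass(sp)
                   o$type <- class(sp)
                   lapply(o, function(v) if (is.object(v)) unclass(v) else v)
                 }))
    jsonlite::write_json(meta, file.path(dir, paste0(base, ".json")),
                         auto_unbox = TRUE, digits = NA)
    for (k in which(st$labels > 0))
      utils::write.csv(st$masks[, , k] * 1L,
                       file.path(dir, sprintf("%s_mask_%s.csv", base,
                                              CLASS_NAMES[k])),
                       row.names = FALSE)
    data.frame(id = base, n_objects = length(st$scene),
               classes = paste(CLASS_NAMES[st$labels > 0], collapse = ";"))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
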