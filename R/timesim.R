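# Time-stepped propagation of activity through the network.
#
# Wavefront semantics: the network is a directed graph of nodes; at every
# step each node recomputes its value from the PREVIOUS step's values of
# its parents, so new information crosses exactly one connection per step.
# The image is static; the feedforward chain therefore settles to its
# stimulus-driven value at a step equal to its distance from the input,
# while feedback quantities keep evolving until class information has
# looped through FCm and back down.
#
# The network is initialized at the activity elicited by a white-noise
# image, with the attention template pre-activated, and the stimulus is
# then switched on at step 0.

#' Simulation schedule
#'
#' @param granularity `"area"` (one step per between-area connection; the
#'   three blocks inside an area are computed within a step) or `"layer"`
#'   (every convolutional / fully connected layer is its own step).
#' @param total_steps Number of steps after stimulus onset; default is
#'   twice the input-to-V1m-mirror path length plus 4 margin steps.
#' @param noise_mean,noise_sd White-noise image statistics; defaults match
#'   the mean and standard deviation of the default background texture.
#' @param attention_preactivation Activate the attention template already
#'   during noise initialization (default), as opposed to at onset.
#' @export
schedule_config <- function(granularity = c("area", "layer"),
                            total_steps = NULL, noise_mean = NULL,
                            noise_sd = NULL, attention_preactivation = TRUE) {
  granularity <- match.arg(granularity)
  structure(list(granularity = granularity, total_steps = total_steps,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 attention_preactivation = isTRUE(attention_preactivation)),
            class = "schedule_config")
}

# Default white-noise statistics: first two moments of the default
# background texture (fixed internal seed; computed once and cached).
.noise_stats <- function() {
  st <- .idx_cache[["noise_stats"]]
  if (is.null(st)) {
    tex <- make_background_texture(c(56, 56), texture_spec(orientation = 45),
                                   seed = 960321L)
    st <- c(mean = mean(tex), sd = stats::sd(as.vector(tex)))
    assign("noise_stats", st, envir = .idx_cache)
  }
  st
}

# ---------------------------------------------------------------------------
# Evaluation-mode pieces shared by the graph nodes

.ffblock_eval <- function(net, x, nm, H, W, N) {
  .block_fwd(x, net$params, net$bn, nm, H, W, N, train = FALSE)$y
}

.area_ff_eval <- function(net, x, i, N) {
  s <- net$config$sizes[i]
  a1 <- .ffblock_eval(net, x, sprintf("ff.%s.b1", .AREAS[i]), s, s, N)
  a2 <- .ffblock_eval(net, a1, sprintf("ff.%s.b2", .AREAS[i]), s, s, N)
  a3 <- .ffblock_eval(net, a2, sprintf("ff.%s.b3", .AREAS[i]), s, s, N)
  list(a1 = a1, a2 = a2, a3 = a3)
}

.down_eval <- function(net, h, i, N) {
  s <- net$config$sizes[i]
  down2_fwd(h, net$params[[sprintf("ff.down%d.W", i)]],
            net$params[[sprintf("ff.down%d.b", i)]], s, s, N)
}

.itm_eval <- function(net, a_d3, N) {
  cfg <- net$config
  flat <- flatten_conv(a_d3, cfg$top^2, N)
  relu(flat %*% net$params[["ff.itm.W"]] +
         matrix(net$params[["ff.itm.b"]], N, cfg$itm, byrow = TRUE))
}

.fcm_eval <- function(net, itm, N) {
  logits <- itm %*% net$params[["ff.fcm.W"]] +
    matrix(net$params[["ff.fcm.b"]], N, net$config$n_classes, byrow = TRUE)
  sigmoid(logits)
}

.head_fc1_eval <- function(net, gated, N) {
  relu(gated %*% net$params[["fb.head.fc1.W"]] +
         matrix(net$params[["fb.head.fc1.b"]], N, net$config$itm, byrow = TRUE))
}

.head_deconv_eval <- function(net, h1, N) {
  cfg <- net$config
  F3 <- cfg$features[3]
  hd <- relu(h1 %*% net$params[["fb.head.deconv.W"]] +
               matrix(net$params[["fb.head.deconv.b"]], N, F3 * cfg$top^2,
                      byrow = TRUE))
  unflatten_conv(hd, cfg$top^2, N, F3)
}

.head_fuse_eval <- function(net, t_hd, a_d3) {
  conv1_fwd(cbind(t_hd, a_d3), net$params[["fb.head.fuse.W"]],
            net$params[["fb.head.fuse.b"]])
}

.up_eval <- function(net, c_in, which, h, N) {
  up2_fwd(c_in, net$params[[sprintf("fb.up.%s.W", which)]],
          net$params[[sprintf("fb.up.%s.b", which)]], h, h, N)
}

.mirror_eval <- function(net, ar, l, z, a) {
  b <- modulate(a, z, net$params[[sprintf("beta.%s.%d", ar, l)]])
  list(z = z, b = b, c = b - a)
}

.mix_eval <- function(net, ar, which, c_in, hw, N) {
  conv3_fwd(c_in, net$params[[sprintf("fb.%s.%s.W", ar, which)]],
            net$params[[sprintf("fb.%s.%s.b", ar, which)]], hw, hw, N)
}

.readout_eval <- function(net, v1mirror) {
  src <- if (net$config$readout_source == "b") v1mirror$b else v1mirror$c
  sigmoid(conv1_fwd(src, net$params[["fb.readout.W"]],
                    net$params[["fb.readout.b"]]))
}

# ---------------------------------------------------------------------------
# Graph construction

# A node: list(name, deps, fn(vals, net, x, attend, N)).
.node <- function(name, deps, fn) list(name = name, deps = deps, fn = fn)

.build_graph <- function(granularity) {
  if (granularity == "area") {
    list(
      .node("v1", "x", function(v, net, x, A, N) .area_ff_eval(net, x, 1, N)),
      .node("v2", "v1", function(v, net, x, A, N)
        .area_ff_eval(net, .down_eval(net, v$v1$a3, 1, N), 2, N)),
      .node("v4", "v2", function(v, net, x, A, N)
        .area_ff_eval(net, .down_eval(net, v$v2$a3, 2, N), 3, N)),
      .node("itm", "v4", function(v, net, x, A, N) {
        a_d3 <- .down_eval(net, v$v4$a3, 3, N)
        list(a_d3 = a_d3, itm = .itm_eval(net, a_d3, N))
      }),
      .node("fcm", "itm", function(v, net, x, A, N) {
        scores <- .fcm_eval(net, v$itm$itm, N)
        list(scores = scores, gated = scores * A)
      }),
      .node("mv4", c("fcm", "itm", "v4"), function(v, net, x, A, N) {
        h1 <- .head_fc1_eval(net, v$fcm$gated, N)
        t_hd <- .head_deconv_eval(net, h1, N)
        z_top <- .head_fuse_eval(net, t_hd, v$itm$a_d3)
        hw <- net$config$sizes[3]
        z3 <- .up_eval(net, z_top, "v4", net$config$top, N)
        m3 <- .mirror_eval(net, "v4", 3, z3, v$v4$a3)
        m2 <- .mirror_eval(net, "v4", 2, .mix_eval(net, "v4", "l32", m3$c, hw, N), v$v4$a2)
        m1 <- .mirror_eval(net, "v4", 1, .mix_eval(net, "v4", "l21", m2$c, hw, N), v$v4$a1)
        list(l3 = m3, l2 = m2, l1 = m1)
      }),
      .node("mv2", c("mv4", "v2"), function(v, net, x, A, N) {
        hw <- net$config$sizes[2]
        z3 <- .up_eval(net, v$mv4$l1$c, "v2", net$config$sizes[3], N)
        m3 <- .mirror_eval(net, "v2", 3, z3, v$v2$a3)
        m2 <- .mirror_eval(net, "v2", 2, .mix_eval(net, "v2", "l32", m3$c, hw, N), v$v2$a2)
        m1 <- .mirror_eval(net, "v2", 1, .mix_eval(net, "v2", "l21", m2$c, hw, N), v$v2$a1)
        list(l3 = m3, l2 = m2, l1 = m1)
      }),
      .node("mv1", c("mv2", "v1"), function(v, net, x, A, N) {
        hw <- net$config$sizes[1]
        z3 <- .up_eval(net, v$mv2$l1$c, "v1", net$config$sizes[2], N)
        m3 <- .mirror_eval(net, "v1", 3, z3, v$v1$a3)
        m2 <- .mirror_eval(net, "v1", 2, .mix_eval(net, "v1", "l32", m3$c, hw, N), v$v1$a2)
        m1 <- .mirror_eval(net, "v1", 1, .mix_eval(net, "v1", "l21", m2$c, hw, N), v$v1$a1)
        list(l3 = m3, l2 = m2, l1 = m1, map = .readout_eval(net, m1))
      }))
  } else {
    g <- list(
      .node("v1.b1", "x", function(v, net, x, A, N)
        .ffblock_eval(net, x, "ff.v1.b1", 56, 56, N)),
      .node("v1.b2", "v1.b1", function(v, net, x, A, N)
        .ffblock_eval(net, v$`v1.b1`, "ff.v1.b2", 56, 56, N)),
      .node("v1.b3", "v1.b2", function(v, net, x, A, N)
        .ffblock_eval(net, v$`v1.b2`, "ff.v1.b3", 56, 56, N)),
      .node("v2.b1", "v1.b3", function(v, net, x, A, N)
        .ffblock_eval(net, .down_eval(net, v$`v1.b3`, 1, N), "ff.v2.b1", 28, 28, N)),
      .node("v2.b2", "v2.b1", function(v, net, x, A, N)
        .ffblock_eval(net, v$`v2.b1`, "ff.v2.b2", 28, 28, N)),
      .node("v2.b3", "v2.b2", function(v, net, x, A, N)
        .ffblock_eval(net, v$`v2.b2`, "ff.v2.b3", 28, 28, N)),
      .node("v4.b1", "v2.b3", function(v, net, x, A, N)
        .ffblock_eval(net, .down_eval(net, v$`v2.b3`, 2, N), "ff.v4.b1", 14, 14, N)),
      .node("v4.b2", "v4.b1", function(v, net, x, A, N)
        .ffblock_eval(net, v$`v4.b1`, "ff.v4.b2", 14, 14, N)),
      .node("v4.b3", "v4.b2", function(v, net, x, A, N)
        .ffblock_eval(net, v$`v4.b2`, "ff.v4.b3", 14, 14, N)),
      .node("d3", "v4.b3", function(v, net, x, A, N)
        .down_eval(net, v$`v4.b3`, 3, N)),
      .node("itm", "d3", function(v, net, x, A, N)
        .itm_eval(net, v$d3, N)),
      .node("fcm", "itm", function(v, net, x, A, N) {
        scores <- .fcm_eval(net, v$itm, N)
        list(scores = scores, gated = scores * A)
      }),
      .node("hfc1", "fcm", function(v, net, x, A, N)
        .head_fc1_eval(net, v$fcm$gated, N)),
      .node("hdec", "hfc1", function(v, net, x, A, N)
        .head_deconv_eval(net, v$hfc1, N)),
      .node("ztop", c("hdec", "d3"), function(v, net, x, A, N)
        .head_fuse_eval(net, v$hdec, v$d3)),
      .node("mv4.3", c("ztop", "v4.b3"), function(v, net, x, A, N)
        .mirror_eval(net, "v4", 3, .up_eval(net, v$ztop, "v4", net$config$top, N),
                     v$`v4.b3`)),
      .node("mv4.2", c("mv4.3", "v4.b2"), function(v, net, x, A, N)
        .mirror_eval(net, "v4", 2, .mix_eval(net, "v4", "l32", v$`mv4.3`$c,
                                             net$config$sizes[3], N), v$`v4.b2`)),
      .node("mv4.1", c("mv4.2", "v4.b1"), function(v, net, x, A, N)
        .mirror_eval(net, "v4", 1, .mix_eval(net, "v4", "l21", v$`mv4.2`$c,
                                             net$config$sizes[3], N), v$`v4.b1`)),
      .node("mv2.3", c("mv4.1", "v2.b3"), function(v, net, x, A, N)
        .mirror_eval(net, "v2", 3, .up_eval(net, v$`mv4.1`$c, "v2", 14, N), v$`v2.b3`)),
      .node("mv2.2", c("mv2.3", "v2.b2"), function(v, net, x, A, N)
        .mirror_eval(net, "v2", 2, .mix_eval(net, "v2", "l32", v$`mv2.3`$c,
                                             net$config$sizes[2], N), v$`v2.b2`)),
      .node("mv2.1", c("mv2.2", "v2.b1"), function(v, net, x, A, N)
        .mirror_eval(net, "v2", 1, .mix_eval(net, "v2", "l21", v$`mv2.2`$c,
                                             net$config$sizes[2], N), v$`v2.b1`)),
      .node("mv1.3", c("mv2.1", "v1.b3"), function(v, net, x, A, N)
        .mirror_eval(net, "v1", 3, .up_eval(net, v$`mv2.1`$c, "v1", 28, N), v$`v1.b3`)),
      .node("mv1.2", c("mv1.3", "v1.b2"), function(v, net, x, A, N)
        .mirror_eval(net, "v1", 2, .mix_eval(net, "v1", "l32", v$`mv1.3`$c,
                                             net$config$sizes[1], N), v$`v1.b2`)),
      .node("mv1.1", c("mv1.2", "v1.b1"), function(v, net, x, A, N) {
        m1 <- .mirror_eval(net, "v1", 1, .mix_eval(net, "v1", "l21", v$`mv1.2`$c,
                                                   net$config$sizes[1], N),
                           v$`v1.b1`)
        c(m1, list(map = .readout_eval(net, m1)))
      }))
    g
  }
}

.graph_path_length <- function(granularity) {
  if (granularity == "area") 8L else 24L
}

# ---------------------------------------------------------------------------
# State initialization and stepping

#' Initialize the network state from a white-noise stimulus
#'
#' Runs the propagation graph on i.i.d. uniform pixel noise (matched in
#' mean and variance to the background textures) until every node has
#' settled, with the attention template already active (unless
#' `attention_preactivation = FALSE`).
#'
#' @param net Trained `segnet_model`.
#' @param attend One-hot length-12 vector or N x 12 matrix.
#' @param schedule A [schedule_config()].
#' @param seed Integer seed for the noise.
#' @param n Number of parallel simulations (ignored when `attend` is a
#'   matrix).
#' @return Object of class `network_state`.
#' @export
init_state <- function(net, attend, schedule = schedule_config(), seed = 1L,
                       n = 1L) {
  if (!any(grepl("^fb\\.", names(net$params))))
    stop("init_state: model has no feedback parameters")
  A <- if (is.matrix(attend)) attend else
    matrix(attend, n, length(attend), byrow = TRUE)
  N <- nrow(A)
  sz <- net$config$input_size
  ns <- .noise_stats()
  nm <- schedule$noise_mean %||% ns[["mean"]]
  nsd <- schedule$noise_sd %||% ns[["sd"]]
  half <- sqrt(3) * nsd
  noise <- with_seed(seed, matrix(
    pmin(1, pmax(0, stats::runif(N * sz * sz, nm - half, nm + half))), ncol = 1))
  graph <- .build_graph(schedule$granularity)
  A_init <- if (schedule$attention_preactivation) A else A * 0
  vals <- list()
  # run to the noise-driven fixed point (path length + margin steps)
  for (i in seq_len(.graph_path_length(schedule$granularity) + 2L))
    vals <- .graph_step(graph, vals, net, noise, A_init, N)
  structure(list(values = vals, attend = A, schedule = schedule, n = N,
                 noise = noise, step = 0L), class = "network_state")
}

# One synchronous graph update: every node recomputes from the previous
# values.  Nodes whose parents are still absent keep value NULL.
.graph_step <- function(graph, vals, net, x, A, N) {
  new_vals <- vals
  for (nd in graph) {
    deps_ok <- all(vapply(nd$deps, function(d)
      d == "x" || !is.null(vals[[d]]), logical(1)))
    if (deps_ok) new_vals[[nd$name]] <- nd$fn(vals, net, x, A, N)
  }
  new_vals
}

#' Advance the simulation by one step
#'
#' Every connection transmits its source's previous-step value once, so
#' stimulus information crosses exactly one connection per step.
#'
#' @param state A `network_state`. @param image 56x56 matrix, a `stimulus`,
#'   a list of either (batch), or the internal stacked column matrix.
#' @param net The `segnet_model` used to create the state.
#' @return The updated `network_state`.
#' @export
sim_step <- function(state, image, net) {
  stopifnot(inherits(state, "network_state"))
  x <- if (is.matrix(image) && ncol(image) == 1 &&
           nrow(image) == state$n * net$config$input_size^2) image
  else .stack_images(image, net$config$input_size)
  graph <- .build_graph(state$schedule$granularity)
  state$values <- .graph_step(graph, state$values, net, x, state$attend, state$n)
  state$step <- state$step + 1L
  state
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> %d simulation(s), %s granularity, step %d\n",
              x$n, x$schedule$granularity, x$step))
  invisible(x)
}

# Name of the node holding the V1m mirror, and extractor for the recorded
# quantity (b, c of its lowest layer, or the feedforward a).
.v1_mirror_value <- function(vals, granularity, what = "b") {
  nd <- if (granularity == "area") vals$mv1 else vals$`mv1.1`
  if (granularity == "area") nd <- nd$l1
  if (what == "map") return(nd$map %||% vals$mv1$map)
  nd[[what]]
}

.v1_ff_value <- function(vals, granularity) {
  if (granularity == "area") vals$v1$a1 else vals$`v1.b1`
}

# ---------------------------------------------------------------------------
# Time-courses

# Core simulation: returns means[group, step+1, stim] for per-stimulus
# pixel groups, recording the channel-averaged V1m mirror quantity.
.simulate_groups <- function(net, stimuli, attend_mat, schedule, seed,
                             groups, record = "b", chunk = 64L) {
  sz <- net$config$input_size
  steps <- schedule$total_steps %||%
    (2L * .graph_path_length(schedule$granularity) + 4L)
  n <- length(stimuli)
  gmax <- max(vapply(groups, length, integer(1)))
  out <- array(NA_real_, c(gmax, steps + 1L, n))
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1)
    B <- length(idx)
    st <- init_state(net, attend_mat[idx, , drop = FALSE], schedule,
                     seed = seed + start)
    x <- .stack_images(stimuli[idx], sz)
    for (tstep in 0:steps) {
      if (tstep > 0) st <- sim_step(st, x, net)
      val <- if (record == "a")
        .v1_ff_value(st$values, schedule$granularity)
      else .v1_mirror_value(st$values, schedule$granularity, record)
      pixmean <- rowMeans(val)
      for (j in seq_len(B)) {
        rows <- (j - 1) * sz * sz
        gs <- groups[[idx[j]]]
        for (gi in seq_along(gs))
          out[gi, tstep + 1L, idx[j]] <- mean(pixmean[rows + gs[[gi]]])
      }
    }
  }
  out
}

# Row-major flat pixel indices of a region label for one stimulus.
.region_groups <- function(stim, analyze_class, edge_width = 2) {
  k <- analyze_class
  other <- lapply(setdiff(which(stim$labels > 0), k),
                  function(j) stim$masks[, , j])
  rm <- region_map(stim$masks[, , k], edge_width, other)
  lapply(c("figure", "edge", "ground"), function(rg)
    which(t(rm$assignment == rg)))   # t(): row-major flat order
}

#' Simulate region-resolved V1m time-courses over a stimulus set
#'
#' For each stimulus the figure of interest is partitioned into
#' figure/edge/ground regions ([region_map()]); the channel-averaged
#' activity of the V1m mirror (feedback units, `record = "b"` by default)
#' is recorded per region at every step and aggregated across stimuli
#' (mean and SEM).
#'
#' @param net Trained model.
#' @param stimuli List of stimuli.
#' @param attend Attended class per stimulus: an integer vector, a single
#'   class index/name, or a function `stimulus -> class index`.
#' @param schedule A [schedule_config()].
#' @param seed Seed for noise initialization.
#' @param analyze_class Class whose mask defines the regions; default is
#'   the first texture-figure class present (square, else rectangle).
#'   Stimuli lacking it are skipped with a message.
#' @param record `"b"` (default), `"c"` or `"a"`.
#' @param condition Label stored in the output (e.g. `"attended"`).
#' @param edge_width Region-map edge half-width in px.
#' @return A `trace_set`: data frame with columns layer, region, condition,
#'   step, mean, sem, n; the per-stimulus raw traces are kept in
#'   `attr(, "raw")`.
#' @export
run_timecourse <- function(net, stimuli, attend, schedule = schedule_config(),
                           seed = 1L, analyze_class = NULL, record = "b",
                           condition = "default", edge_width = 2) {
  stopifnot(length(stimuli) >= 1)
  att <- .resolve_attend(stimuli, attend)
  keep <- logical(length(stimuli))
  groups <- vector("list", length(stimuli))
  acls <- integer(length(stimuli))
  for (i in seq_along(stimuli)) {
    k <- analyze_class %||% intersect(1:2, which(stimuli[[i]]$labels > 0))[1]
    if (is.character(k)) k <- match(k, CLASS_NAMES)
    if (is.na(k) || stimuli[[i]]$labels[k] == 0) {
      message("run_timecourse: stimulus ", i, " lacks the analyzed figure; skipped")
      next
    }
    keep[i] <- TRUE
    acls[i] <- k
    groups[[i]] <- .region_groups(stimuli[[i]], k, edge_width)
  }
  if (!any(keep)) stop("run_timecourse: no stimulus with the analyzed figure")
  stimuli <- stimuli[keep]; groups <- groups[keep]
  A <- matrix(0, length(stimuli), net$config$n_classes)
  A[cbind(seq_along(stimuli), att[keep])] <- 1
  raw <- .simulate_groups(net, stimuli, A, schedule, seed, groups, record)
  regions <- c("figure", "edge", "ground")
  steps <- dim(raw)[2] - 1L
  n <- dim(raw)[3]
  rows <- do.call(rbind, lapply(seq_along(regions), function(gi) {
    m <- raw[gi, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    data.frame(layer = "v1m.mirror1", region = regions[gi],
               condition = condition, step = 0:steps,
               mean = rowMeans(m),
               sem = if (n > 1) apply(m, 1, stats::sd) / sqrt(n) else NA_real_,
               n = n)
  }))
  class(rows) <- c("trace_set", "data.frame")
  attr(rows, "raw") <- raw
  attr(rows, "record") <- record
  rows
}

.resolve_attend <- function(stimuli, attend) {
  if (is.function(attend))
    return(vapply(stimuli, function(s) {
      k <- attend(s); if (is.character(k)) match(k, CLASS_NAMES) else as.integer(k)
    }, integer(1)))
  if (is.character(attend)) attend <- match(attend, CLASS_NAMES)
  if (length(attend) == 1) rep(as.integer(attend), length(stimuli))
  else as.integer(attend)
}

#' Figure-ground modulation from a trace set
#'
#' FGM is the excess response to figure (or edge) elements over matched
#' ground elements: `figure - ground` and `edge - ground` per step.
#'
#' @param traces A `trace_set` from [run_timecourse()].
#' @return Data frame with columns step, fgm_figure, fgm_edge.
#' @export
fgm <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  need <- c("figure", "edge", "ground")
  if (!all(need %in% traces$region)) stop("fgm: missing region traces")
  w <- function(rg) traces$mean[traces$region == rg]
  data.frame(step = sort(unique(traces$step)),
             fgm_figure = w("figure") - w("ground"),
             fgm_edge = w("edge") - w("ground"))
}

#' Up-sample and Savitzky-Golay smooth a trace (display only)
#'
#' Linear up-sampling to `upsample_to` points followed by a
#' Savitzky-Golay polynomial filter.  Intended purely for presentation;
#' statistics are computed on raw step-resolution traces.
#'
#' @param trace Numeric vector.
#' @param upsample_to Target length (default 160).
#' @param order Polynomial order (default 3).
#' @param window Filter window in samples (odd, default 7).
#' @export
smooth_trace <- function(trace, upsample_to = 160, order = 3, window = 7) {
  if (window %% 2 != 1) stop("smooth_trace: window must be odd")
  if (order >= window) stop("smooth_trace: order must be < window")
  up <- stats::approx(seq_along(trace), trace, n = upsample_to)$y
  if (window >= length(up)) stop("smooth_trace: window >= trace length")
  as.numeric(signal::sgolayfilt(up, p = order, n = window))
}

# ---------------------------------------------------------------------------
# Space-time profiles

# Signed Chebyshev distance to the mask boundary, capped at `maxd`:
# +k = k erosions deep inside the figure, -k = k dilations outside.
.signed_distance <- function(mask, maxd) {
  d <- matrix(NA_integer_, nrow(mask), ncol(mask))
  cur <- mask
  for (k in seq_len(maxd)) {
    nxt <- .erode_box(cur, 1)
    d[cur & !nxt] <- k
    cur <- nxt
  }
  d[cur] <- maxd
  cur <- mask
  for (k in seq_len(maxd)) {
    nxt <- .dilate_box(cur, 1)
    d[nxt & !cur] <- -k
    cur <- nxt
  }
  d[is.na(d)] <- -maxd
  d
}

#' Space-time profile of figure-ground modulation
#'
#' Pixels are binned by signed Chebyshev distance to the figure boundary
#' (positive inside, negative outside, capped at `max_distance`); the
#' V1m-mirror response per bin and step, minus the ground-region response,
#' gives FGM over (position, time).
#'
#' @param net Trained model.
#' @param stimuli Stimuli with the analyzed figure at varied positions.
#' @param attend Attended class (as in [run_timecourse()]).
#' @param schedule A [schedule_config()].
#' @param seed Noise seed.
#' @param analyze_class Figure class (default: first of square/rectangle).
#' @param max_distance Distance cap in px (default 8).
#' @param record `"b"` or `"c"`.
#' @return Object of class `spacetime_profile`: `list(fgm, n, bins,
#'   steps)` where `fgm` is a bins x steps matrix (rows ordered from deep
#'   ground to figure center); empty bins are `NA`.
#' @export
spacetime_profile <- function(net, stimuli, attend,
                              schedule = schedule_config(), seed = 1L,
                              analyze_class = NULL, max_distance = 8L,
                              record = "b") {
  att <- .resolve_attend(stimuli, attend)
  bins <- seq(-max_distance, max_distance)
  groups <- vector("list", length(stimuli))
  for (i in seq_along(stimuli)) {
    st <- stimuli[[i]]
    k <- analyze_class %||% intersect(1:2, which(st$labels > 0))[1]
    if (is.character(k)) k <- match(k, CLASS_NAMES)
    if (is.na(k) || st$labels[k] == 0)
      stop("spacetime_profile: stimulus ", i, " lacks the analyzed figure")
    sd_ <- .signed_distance(st$masks[, , k], max_distance)
    other <- Reduce(`|`, lapply(setdiff(which(st$labels > 0), k),
                                function(j) st$masks[, , j]),
                    matrix(FALSE, nrow(sd_), ncol(sd_)))
    sd_[other] <- NA   # other objects never count as ground or figure
    groups[[i]] <- lapply(bins, function(b) which(t(sd_ == b)))
  }
  A <- matrix(0, length(stimuli), net$config$n_classes)
  A[cbind(seq_along(stimuli), att)] <- 1
  raw <- .simulate_groups(net, stimuli, A, schedule, seed, groups, record)
  steps <- dim(raw)[2]
  prof <- matrix(NA_real_, length(bins), steps,
                 dimnames = list(bins, 0:(steps - 1L)))
  # ground reference: mean over bins at least 3 px outside the figure
  gr <- apply(raw[which(bins <= -3), , , drop = FALSE], c(2, 3), mean,
              na.rm = TRUE)                        # steps x stim
  for (bi in seq_along(bins)) {
    resp <- matrix(raw[bi, , ], nrow = steps)
    prof[bi, ] <- rowMeans(resp - gr, na.rm = TRUE)
  }
  structure(list(fgm = prof, n = length(stimuli), bins = bins,
                 steps = steps - 1L), class = "spacetime_profile")
}

#' @export
print.spacetime_profile <- function(x, ...) {
  cat(sprintf("<spacetime_profile> %d bins x %d steps, %d stimuli\n",
              length(x$bins), x$steps + 1L, x$n))
  invisible(x)
}

#' Write a trace set to a tidy CSV file
#' @param traces A `trace_set`. @param path Output file.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE)
  invisible(path)
}
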