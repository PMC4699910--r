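# Run code with a private RNG stream: the global .Random.seed is saved and
# restored, so generators have no hidden effect on the caller's randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification of a simulated trajectory
#'
#' Models: `"brownian"` — correlated random walk with per-sample turn drawn
#' from a wrapped normal and per-sample speed from a Rayleigh distribution;
#' `"levy"` — straight relocation segments whose lengths follow a Pareto
#' (power-law) distribution with exponent `alpha`, directions uniform, walked
#' at constant speed; `"ballistic"` — a straight constant-velocity course;
#' `"two_phase"` — an initial local phase (tight, curvy CRW) switching at
#' `switch_time` to a global phase (fast, straight CRW), emulating the
#' area-restricted-search to dispersal transition of a food-deprived worm.
#'
#' Default speeds (~0.15 mm/s) and the 20-minute duration match freely moving
#' adult worms freshly removed from food; the Pareto cut-off (0.3 mm) puts
#' the bulk of relocations between fractions of a millimetre and a few tens
#' of millimetres, the range observed on a 150 mm plate. The walk is
#' reflected at the walls of a square arena so it stays on the plate.
#'
#' @param model one of `"brownian"`, `"levy"`, `"ballistic"`, `"two_phase"`.
#' @param duration seconds of simulated behavior (default 1200 = 20 min).
#' @param dt sampling interval of the output path in seconds.
#' @param speed mean speed in mm/s.
#' @param alpha Levy exponent in (1, 3] (levy model).
#' @param min_segment Pareto lower cut-off in mm (levy model).
#' @param turn_sd wrapped-normal turn s.d. in degrees per sample (brownian).
#' @param switch_time phase switch in seconds (two_phase; default half).
#' @param arena arena side in mm (walk reflected at the walls).
#' @param start start position `c(x, y)` in mm (default arena center).
#' @param seed integer seed fixing all randomness.
#' @return named list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(model = c("brownian", "levy", "ballistic", "two_phase"),
                            duration = 1200, dt = 1, speed = 0.15,
                            alpha = 2, min_segment = 0.3, turn_sd = 30,
                            switch_time = NULL, arena = 100, start = NULL,
                            seed = 1L) {
  model <- match.arg(model)
  if (duration <= 0 || dt <= 0 || speed <= 0 || arena <= 0)
    stop("duration, dt, speed and arena must be positive")
  if (model == "levy" && (alpha <= 1 || alpha > 3))
    stop("`alpha` must lie in (1, 3] for a levy spec")
  if (is.null(switch_time)) switch_time <- duration / 2
  if (is.null(start)) start <- c(arena / 2, arena / 2)
  structure(list(model = model, duration = duration, dt = dt, speed = speed,
                 alpha = alpha, min_segment = min_segment, turn_sd = turn_sd,
                 switch_time = switch_time, arena = arena, start = start,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

# reflect a coordinate into [lo, hi]
.reflect <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  lo + ifelse(v > span, 2 * span - v, v)
}

.sim_crw <- function(n, dt, speed, turn_sd, heading0) {
  heading <- heading0 + cumsum(c(0, wrap_angle(stats::rnorm(n - 1, 0, turn_sd))))
  v <- stats::rweibull(n, shape = 2, scale = speed * 2 / sqrt(pi))  # Rayleigh with mean `speed`
  dx <- v * dt * cos(heading * pi / 180)
  dy <- v * dt * sin(heading * pi / 180)
  list(dx = dx, dy = dy)
}

#' Simulate a trajectory with known ground truth
#'
#' Continuous-time walk sampled at `spec$dt`. For the levy model the drawn
#' relocation segment lengths and turning points are returned as ground
#' truth. Identical seeds give identical paths.
#'
#' @param spec a [trajectory_spec()].
#' @return list with `path` (a `worm_path`, all samples valid), `segments`
#'   (data.frame `length`, `heading` of generator relocations; levy and
#'   ballistic models), and `spec`.
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  with_seed(spec$seed, {
    n <- floor(spec$duration / spec$dt) + 1L
    t <- (seq_len(n) - 1L) * spec$dt
    segments <- NULL
    if (spec$model == "ballistic") {
      heading <- stats::runif(1, -180, 180)
      dx <- rep(spec$speed * spec$dt * cos(heading * pi / 180), n - 1L)
      dy <- rep(spec$speed * spec$dt * sin(heading * pi / 180), n - 1L)
      segments <- data.frame(length = spec$speed * spec$duration, heading = heading)
    } else if (spec$model == "brownian") {
      d <- .sim_crw(n - 1L, spec$dt, spec$speed, spec$turn_sd, stats::runif(1, -180, 180))
      dx <- d$dx; dy <- d$dy
    } else if (spec$model == "levy") {
      # draw Pareto segments until they cover the full duration at constant speed
      total <- spec$speed * spec$duration
      lens <- numeric(0)
      while (sum(lens) < total)
        lens <- c(lens, rpareto(64L, spec$alpha, spec$min_segment))
      lens <- lens[seq_len(which(cumsum(lens) >= total)[[1L]])]
      heads <- stats::runif(length(lens), -180, 180)
      segments <- data.frame(length = lens, heading = heads)
      # walk the segments at constant speed, emitting a sample every dt
      step_mm <- spec$speed * spec$dt
      m <- n - 1L
      dx <- numeric(m); dy <- numeric(m)
      si <- 1L; rem <- lens[[1L]]
      for (i in seq_len(m)) {
        need <- step_mm; ddx <- 0; ddy <- 0
        while (need > 0 && si <= length(lens)) {
          take <- min(need, rem)
          ddx <- ddx + take * cos(heads[[si]] * pi / 180)
          ddy <- ddy + take * sin(heads[[si]] * pi / 180)
          rem <- rem - take; need <- need - take
          if (rem <= 1e-12 && si < length(lens)) { si <- si + 1L; rem <- lens[[si]] }
          else if (rem <= 1e-12) break
        }
        dx[[i]] <- ddx; dy[[i]] <- ddy
      }
    } else { # two_phase
      n1 <- floor(spec$switch_time / spec$dt)
      n2 <- (n - 1L) - n1
      h0 <- stats::runif(1, -180, 180)
      d1 <- .sim_crw(max(n1, 1L), spec$dt, spec$speed * 0.7, 70, h0)
      d2 <- .sim_crw(max(n2, 1L), spec$dt, spec$speed * 1.5, 8, h0)
      dx <- c(d1$dx[seq_len(n1)], d2$dx[seq_len(n2)])
      dy <- c(d1$dy[seq_len(n1)], d2$dy[seq_len(n2)])
    }
    x <- spec$start[[1L]] + cumsum(c(0, dx))
    y <- spec$start[[2L]] + cumsum(c(0, dy))
    x <- .reflect(x, 0, spec$arena)
    y <- .reflect(y, 0, spec$arena)
    list(path = worm_path(t, x, y, rep(TRUE, n)), segments = segments, spec = spec)
  })
}

#' Specification of a synthetic plate world
#'
#' Describes the rendered scene: a lighter noisy agar background, a dark
#' elongated worm (a thickened, sinusoid-perturbed centerline oriented along
#' the instantaneous heading), and immobile dark artifacts emulating salt
#' precipitates and air bubbles.
#'
#' @param arena arena (world) side in mm.
#' @param calibration pixels per mm of the rendered image.
#' @param view_px camera view size `c(width, height)` in px.
#' @param worm_length,worm_width worm dimensions in mm.
#' @param bg background mean intensity (0-255).
#' @param worm_intensity worm body intensity (darker than `bg`).
#' @param noise_sd Gaussian sensor noise s.d. (intensity units).
#' @param artifacts data.frame `x`, `y` (mm), `r` (px), `intensity`; NULL for
#'   none.
#' @param wiggle_amp lateral sinusoid amplitude in mm.
#' @param seed seed for the sensor noise stream.
#' @return named list of class `world_spec`.
#' @export
world_spec <- function(arena = 100, calibration = 20, view_px = c(200L, 150L),
                       worm_length = 1.5, worm_width = 0.25, bg = 180,
                       worm_intensity = 70, noise_sd = 3, artifacts = NULL,
                       wiggle_amp = 0.08, seed = 1L) {
  stopifnot(arena > 0, calibration > 0, worm_length > 0, worm_width > 0,
            worm_length < arena)
  structure(list(arena = arena, calibration = calibration,
                 view_px = as.integer(view_px), worm_length = worm_length,
                 worm_width = worm_width, bg = bg, worm_intensity = worm_intensity,
                 noise_sd = noise_sd, artifacts = artifacts,
                 wiggle_amp = wiggle_amp, seed = as.integer(seed)),
            class = "world_spec")
}

#' Scatter immobile dark artifacts over the world
#'
#' @param world a [world_spec()].
#' @param n number of artifacts.
#' @param seed seed.
#' @return the world with an `artifacts` data.frame filled in.
#' @export
add_artifacts <- function(world, n = 5L, seed = 1L) {
  world$artifacts <- with_seed(seed, data.frame(
    x = stats::runif(n, 0, world$arena),
    y = stats::runif(n, 0, world$arena),
    r = stats::runif(n, 1.2, 2.5),
    intensity = stats::runif(n, 30, 60)))
  world
}

# Worm body pixels for a pose, in world px coordinates (0-based).
# Returns data.frame col, row of stamped pixels plus the true centroid.
.worm_pixels <- function(world, pos_mm, heading_deg, phase = 0) {
  cal <- world$calibration
  L <- world$worm_length; W <- world$worm_width
  s <- seq(-L / 2, L / 2, by = 0.5 / cal)         # centerline arclength (mm)
  lat <- world$wiggle_amp * sin(2 * pi * s / (L / 1.5) + phase)
  th <- heading_deg * pi / 180
  cx <- pos_mm[[1L]] + s * cos(th) - lat * sin(th)
  cy <- pos_mm[[2L]] + s * sin(th) + lat * cos(th)
  px <- cx * cal; py <- cy * cal                  # world px (0-based, continuous)
  r_px <- W * cal / 2
  x0 <- floor(min(px) - r_px - 1); x1 <- ceiling(max(px) + r_px + 1)
  y0 <- floor(min(py) - r_px - 1); y1 <- ceiling(max(py) + r_px + 1)
  gx <- x0:x1; gy <- y0:y1
  # min over centerline points of squared distance to each bbox pixel
  nb_r <- length(gy); nb_c <- length(gx)
  mind <- matrix(Inf, nb_r, nb_c)
  for (k in seq_along(px)) {
    dd <- outer((gy - py[[k]])^2, (gx - px[[k]])^2, `+`)
    mind <- pmin(mind, dd)
  }
  on <- which(mind <= r_px^2, arr.ind = TRUE)
  data.frame(col = gx[on[, 2L]], row = gy[on[, 1L]])
}

#' Render a single camera view of the world
#'
#' @param world a [world_spec()].
#' @param pos_mm worm position (centroid) `c(x, y)` in mm.
#' @param heading_deg worm orientation in degrees.
#' @param cam camera offset `c(x, y)` in world px (view top-left).
#' @param index,t frame index and timestamp attached to the frame.
#' @param phase sinusoid phase of the body wiggle (advances with time).
#' @param noise logical; add sensor noise.
#' @param edge_margin px guard band used for the `fully_in_view` ground-truth
#'   flag: smoothing and closing widen the apparent body by up to the closing
#'   disc radius, so a worm closer than this to the border counts as "at the
#'   image edge" (default 2 px, the radius of the default disc).
#' @return a `worm_frame` with attribute `truth`: list `x`, `y` (true worm
#'   pixel centroid in view px), `n_pixels`, `edge_dist` (min px distance of
#'   the body to the view border; -Inf when no pixel is in view) and
#'   `fully_in_view`.
#' @export
render_view <- function(world, pos_mm, heading_deg, cam = c(0, 0),
                        index = NA_integer_, t = NA_real_, phase = 0,
                        noise = TRUE, edge_margin = 2) {
  vw <- world$view_px[[1L]]; vh <- world$view_px[[2L]]
  img <- matrix(world$bg, vh, vw)
  if (noise && world$noise_sd > 0)
    img <- img + matrix(stats::rnorm(vh * vw, 0, world$noise_sd), vh, vw)
  # artifacts (immobile, world-anchored)
  if (!is.null(world$artifacts)) {
    for (a in seq_len(nrow(world$artifacts))) {
      ax <- world$artifacts$x[[a]] * world$calibration - cam[[1L]]
      ay <- world$artifacts$y[[a]] * world$calibration - cam[[2L]]
      r <- world$artifacts$r[[a]]
      if (ax < -r - 1 || ax > vw + r || ay < -r - 1 || ay > vh + r) next
      xs <- max(0, floor(ax - r)):min(vw - 1, ceiling(ax + r))
      ys <- max(0, floor(ay - r)):min(vh - 1, ceiling(ay + r))
      hit <- outer((ys - ay)^2, (xs - ax)^2, `+`) <= r^2
      img[ys + 1L, xs + 1L][hit] <- world$artifacts$intensity[[a]]
    }
  }
  wp <- .worm_pixels(world, pos_mm, heading_deg, phase)
  vx <- wp$col - cam[[1L]]; vy <- wp$row - cam[[2L]]
  inside <- vx >= 0 & vx < vw & vy >= 0 & vy < vh
  if (any(inside))
    img[cbind(vy[inside] + 1L, vx[inside] + 1L)] <- world$worm_intensity +
      if (noise && world$noise_sd > 0) stats::rnorm(sum(inside), 0, world$noise_sd) else 0
  img <- pmin(pmax(round(img), 0), 255)
  m <- edge_margin
  edge_dist <- if (any(inside))
    min(vx[inside], vy[inside], vw - 1 - vx[inside], vh - 1 - vy[inside]) else
    -Inf
  truth <- list(
    x = if (any(inside)) mean(vx[inside]) else NA_real_,
    y = if (any(inside)) mean(vy[inside]) else NA_real_,
    n_pixels = sum(inside),
    edge_dist = edge_dist,
    fully_in_view = nrow(wp) > 0L &&
      all(vx >= m & vx < vw - m & vy >= m & vy < vh - m))
  f <- worm_frame(img, index = index, timestamp = t)
  attr(f, "truth") <- truth
  f
}

#' Lazy world source for the tracking loop
#'
#' Wraps a world and a trajectory into a `function(i, cam)` suitable for
#' [track_stream()]: frame `i` renders the worm at path point `i`, oriented
#' along its instantaneous heading, viewed from camera offset `cam` (clamped
#' to the world). Per-frame ground-truth centroids (world px) are accumulated
#' in the returned function's environment (`attr(fn, "truth")()`).
#'
#' @param world a [world_spec()].
#' @param path a `worm_path` in mm, inside the arena.
#' @param seed seed for the per-frame sensor noise.
#' @return function `(i, cam) -> matrix`, with attributes `timestamps` and
#'   `truth` (a function returning the accumulated ground-truth data.frame).
#' @export
make_world_source <- function(world, path, seed = 1L) {
  if (any(path$x < 0 | path$x > world$arena | path$y < 0 | path$y > world$arena,
          na.rm = TRUE)) {
    bad <- which(path$x < 0 | path$x > world$arena | path$y < 0 | path$y > world$arena)[[1L]]
    stop("path exits the arena at t = ", path$t[[bad]], " s")
  }
  hx <- c(diff(path$x), NA); hy <- c(diff(path$y), NA)
  headings <- atan2(hy, hx) * 180 / pi
  headings[is.na(headings)] <- 0
  wpx <- world$arena * world$calibration
  vw <- world$view_px[[1L]]; vh <- world$view_px[[2L]]
  truth_env <- new.env(parent = emptyenv())
  truth_env$rows <- list()
  fn <- function(i, cam) {
    cam <- c(max(0, min(round(cam[[1L]]), wpx - vw)),
             max(0, min(round(cam[[2L]]), wpx - vh)))
    f <- with_seed(seed + i, render_view(
      world, c(path$x[[i]], path$y[[i]]), headings[[i]], cam = cam,
      index = i, t = path$t[[i]], phase = 0.7 * i))
    tr <- attr(f, "truth")
    truth_env$rows[[as.character(i)]] <- data.frame(
      frame = i, t = path$t[[i]],
      x_world = tr$x + cam[[1L]], y_world = tr$y + cam[[2L]],
      fully_in_view = tr$fully_in_view)
    f
  }
  attr(fn, "timestamps") <- path$t
  attr(fn, "truth") <- function() do.call(rbind, unname(truth_env$rows))
  fn
}

#' Pre-render a frame stack along a path
#'
#' Renders one view per path sample with a camera that follows the worm
#' (re-anchoring the view whenever the worm approaches the view edge), or a
#' fixed camera. Mainly a fixture generator; the tracking loop itself is
#' exercised through [make_world_source()] + [track_stream()].
#'
#' @param world a [world_spec()].
#' @param path a `worm_path` in mm.
#' @param camera `"follow"` or `"fixed"`.
#' @param seed noise seed.
#' @return list with `stack` (a [frame_stack()]), `camera_log` (data.frame
#'   `frame`, `t`, `cam_x`, `cam_y`) and `truth` (data.frame of world-px
#'   ground-truth centroids).
#' @export
render_frames <- function(world, path, camera = c("follow", "fixed"), seed = 1L) {
  camera <- match.arg(camera)
  n <- nrow(path)
  vw <- world$view_px[[1L]]; vh <- world$view_px[[2L]]
  wpx <- world$arena * world$calibration
  hx <- c(diff(path$x), NA); hy <- c(diff(path$y), NA)
  headings <- atan2(hy, hx) * 180 / pi
  headings[is.na(headings)] <- 0
  cam <- c(path$x[[1L]] * world$calibration - vw / 2,
           path$y[[1L]] * world$calibration - vh / 2)
  cam <- pmax(c(0, 0), pmin(round(cam), c(wpx - vw, wpx - vh)))
  frames <- vector("list", n)
  log <- data.frame(frame = seq_len(n), t = path$t, cam_x = NA_real_, cam_y = NA_real_)
  truth <- data.frame(frame = seq_len(n), t = path$t, x_world = NA_real_,
                      y_world = NA_real_, fully_in_view = NA)
  for (i in seq_len(n)) {
    wx <- path$x[[i]] * world$calibration; wy <- path$y[[i]] * world$calibration
    if (camera == "follow") {
      margin <- 0.2
      if (wx - cam[[1L]] < margin * vw || wx - cam[[1L]] > (1 - margin) * vw ||
          wy - cam[[2L]] < margin * vh || wy - cam[[2L]] > (1 - margin) * vh) {
        cam <- pmax(c(0, 0), pmin(round(c(wx - vw / 2, wy - vh / 2)),
                                  c(wpx - vw, wpx - vh)))
      }
    }
    f <- with_seed(seed + i, render_view(
      world, c(path$x[[i]], path$y[[i]]), headings[[i]], cam = cam,
      index = i, t = path$t[[i]], phase = 0.7 * i))
    tr <- attr(f, "truth")
    frames[[i]] <- f
    log$cam_x[[i]] <- cam[[1L]]; log$cam_y[[i]] <- cam[[2L]]
    truth$x_world[[i]] <- tr$x + cam[[1L]]
    truth$y_world[[i]] <- tr$y + cam[[2L]]
    truth$fully_in_view[[i]] <- tr$fully_in_view
  }
  list(stack = frame_stack(frames), camera_log = log, truth = truth)
}
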