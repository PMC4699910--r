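#' Locate the worm from a difference image
#'
#' Subtracts a reference frame (captured after the last camera move) from the
#' current frame: immobile background artifacts such as salt precipitates and
#' air bubbles cancel to zero, leaving the moving worm. The absolute
#' difference is Gaussian-smoothed and the location of the maximum taken as
#' the worm estimate. When `crop_size` is given, the search is restricted to
#' a crop window centered on the last known location.
#'
#' @param current,reference `worm_frame`s or intensity matrices of equal shape.
#' @param last_location list/vector with `x`, `y` (0-based px) of the previous
#'   estimate; returned unchanged when the difference image is all zero.
#' @param crop_size side of the square crop window in px, or `NULL` for the
#'   whole frame.
#' @param sigma Gaussian smoothing sigma applied to the difference image.
#' @param polarity `"dark"` (default): the worm is darker than the
#'   background, so only pixels that darkened since the reference
#'   (`reference - current`, clipped at zero) are considered — this
#'   suppresses the bright "ghost" left at the worm's reference position,
#'   which would otherwise be as strong as the worm itself. `"light"` is the
#'   mirror case; `"abs"` uses the absolute difference.
#' @return list with `x`, `y` (0-based px) and `value` (peak smoothed
#'   difference; 0 when the frames are identical).
#' @export
difference_locate <- function(current, reference, last_location = NULL,
                              crop_size = NULL, sigma = 2,
                              polarity = c("dark", "light", "abs")) {
  polarity <- match.arg(polarity)
  cur <- frame_pixels(current); ref <- frame_pixels(reference)
  if (!all(dim(cur) == dim(ref))) stop("current and reference frames differ in shape")
  d <- switch(polarity,
              dark = pmax(ref - cur, 0),
              light = pmax(cur - ref, 0),
              abs = abs(cur - ref))
  storage.mode(d) <- "double"
  nr <- nrow(d); nc <- ncol(d)
  r0 <- 1L; c0 <- 1L
  if (!is.null(crop_size) && !is.null(last_location)) {
    h <- as.integer(crop_size) %/% 2L
    rc <- as.integer(round(last_location$y)) + 1L
    cc <- as.integer(round(last_location$x)) + 1L
    r0 <- max(1L, rc - h); r1 <- min(nr, rc + h)
    c0 <- max(1L, cc - h); c1 <- min(nc, cc + h)
    d <- d[r0:r1, c0:c1, drop = FALSE]
  }
  if (all(d == 0)) {
    loc <- if (is.null(last_location))
      list(x = (nc - 1) / 2, y = (nr - 1) / 2) else
      list(x = last_location$x, y = last_location$y)
    return(c(loc, list(value = 0)))
  }
  sm <- gaussian_smooth(d, sigma)
  k <- which.max(sm)
  row <- (k - 1L) %% nrow(sm) + 1L
  col <- (k - 1L) %/% nrow(sm) + 1L
  list(x = (c0 + col - 1L) - 1, y = (r0 + row - 1L) - 1, value = max(sm))
}

#' Tracker configuration
#'
#' @param subsample_hz rate at which frames are taken from the stream for the
#'   difference-image step (default 10 Hz); the interval ensures the worm has
#'   moved enough not to subtract itself out.
#' @param view_width,view_height size of the camera view in px; defaults to
#'   the full frame (no virtual camera movement possible for same-size
#'   worlds).
#' @param recenter_frac emit a camera move when the worm estimate is farther
#'   than this fraction of the view width/height from the view center.
#' @param crop_size side of the crop window used by [difference_locate()]
#'   once cropping is enabled (after 20 frames and the first camera move).
#' @param crop_delay number of frames before cropping can engage.
#' @param diff_sigma Gaussian sigma for the difference image.
#' @param polarity difference polarity, see [difference_locate()].
#' @return named list of class `tracker_config`.
#' @export
tracker_config <- function(subsample_hz = 10, view_width = NULL, view_height = NULL,
                           recenter_frac = 0.25, crop_size = 128L,
                           crop_delay = 20L, diff_sigma = 2,
                           polarity = c("dark", "light", "abs")) {
  stopifnot(subsample_hz > 0, recenter_frac > 0, recenter_frac < 0.5,
            crop_size >= 8, crop_delay >= 0)
  structure(list(subsample_hz = subsample_hz, view_width = view_width,
                 view_height = view_height, recenter_frac = recenter_frac,
                 crop_size = as.integer(crop_size), crop_delay = as.integer(crop_delay),
                 diff_sigma = diff_sigma, polarity = match.arg(polarity)),
            class = "tracker_config")
}

# Crop the camera view out of a full world frame at camera offset (cam_x,
# cam_y) = world px of the view's top-left corner, clamped to the world.
.crop_view <- function(world_px, cam, vw, vh) {
  nr <- nrow(world_px); nc <- ncol(world_px)
  cx <- max(0L, min(as.integer(round(cam[[1L]])), nc - vw))
  cy <- max(0L, min(as.integer(round(cam[[2L]])), nr - vh))
  list(view = world_px[(cy + 1L):(cy + vh), (cx + 1L):(cx + vw), drop = FALSE],
       cam = c(cx, cy))
}

#' Run the difference-image tracking loop over a frame stream
#'
#' Offline re-implementation of the tracker's control loop: subsample the
#' stream, locate the worm by reference-frame subtraction, and when the
#' estimate drifts beyond a margin from the view center emit a virtual camera
#' move that re-centers the view and refreshes the reference frame. Global
#' worm position is recovered downstream as in-view location plus camera
#' offset.
#'
#' `frames` may be a [frame_stack()] whose frames are *world* images larger
#' than (or equal to) the camera view, or a function `function(i, cam)`
#' returning the view matrix for frame `i` at camera offset `cam = c(x, y)`
#' (lazy world rendering); in the latter case `timestamps` must be supplied.
#'
#' @param frames frame stack or world-view function.
#' @param cfg a [tracker_config()].
#' @param timestamps required when `frames` is a function.
#' @param cam_start initial camera offset `c(x, y)` in world px.
#' @param frame_callback optional `function(view, frame, cam, t)` invoked for
#'   every processed frame (e.g. to segment on the fly without retaining
#'   frames in memory).
#' @return list with `camera_log` (data.frame `frame`, `t`, `cam_x`, `cam_y`),
#'   `locations` (data.frame `frame`, `t`, `x`, `y` in view px), and
#'   `n_moves`.
#' @export
track_stream <- function(frames, cfg = tracker_config(), timestamps = NULL,
                         cam_start = c(0, 0), frame_callback = NULL) {
  lazy <- is.function(frames)
  if (lazy) {
    if (is.null(timestamps)) stop("`timestamps` required for a world function")
    ts_all <- as.numeric(timestamps)
    if (is.null(cfg$view_width) || is.null(cfg$view_height))
      stop("view dimensions must be set in the tracker config for a world function")
  } else {
    if (!inherits(frames, "worm_frame_stack")) stop("`frames` must be a worm_frame_stack or a function")
    if (length(frames$frames) == 0L) stop("empty frame stream")
    ts_all <- frames$timestamps
  }
  n_all <- length(ts_all)
  # subsample: keep frames at least 1/subsample_hz apart
  keep <- logical(n_all); last_t <- -Inf
  for (i in seq_len(n_all)) {
    if (ts_all[[i]] - last_t >= 1 / cfg$subsample_hz - 1e-9) {
      keep[[i]] <- TRUE; last_t <- ts_all[[i]]
    }
  }
  sel <- which(keep)

  get_view <- function(i, cam) {
    if (lazy) {
      v <- frames(i, cam)
      list(view = frame_pixels(v), cam = cam)
    } else {
      wpx <- frame_pixels(frames$frames[[i]])
      vw <- if (is.null(cfg$view_width)) ncol(wpx) else cfg$view_width
      vh <- if (is.null(cfg$view_height)) nrow(wpx) else cfg$view_height
      .crop_view(wpx, cam, vw, vh)
    }
  }

  cam <- as.numeric(cam_start)
  reference <- NULL
  last_loc <- NULL
  n_moves <- 0L
  frames_seen <- 0L
  log <- data.frame(frame = sel, t = ts_all[sel], cam_x = NA_real_, cam_y = NA_real_)
  locs <- data.frame(frame = sel, t = ts_all[sel], x = NA_real_, y = NA_real_)

  for (k in seq_along(sel)) {
    i <- sel[[k]]
    gv <- get_view(i, cam); view <- gv$view; cam <- as.numeric(gv$cam)
    vw <- ncol(view); vh <- nrow(view)
    center <- c((vw - 1) / 2, (vh - 1) / 2)
    frames_seen <- frames_seen + 1L
    if (is.null(reference)) {
      reference <- view
      loc <- list(x = center[[1L]], y = center[[2L]])
    } else {
      crop <- if (frames_seen > cfg$crop_delay && n_moves > 0L) cfg$crop_size else NULL
      loc <- difference_locate(view, reference, last_loc, crop_size = crop,
                               sigma = cfg$diff_sigma, polarity = cfg$polarity)
    }
    off <- c(loc$x - center[[1L]], loc$y - center[[2L]])
    if (abs(off[[1L]]) > cfg$recenter_frac * vw ||
        abs(off[[2L]]) > cfg$recenter_frac * vh) {
      cam <- cam + round(off)
      gv <- get_view(i, cam); view <- gv$view; cam <- as.numeric(gv$cam)
      reference <- view
      n_moves <- n_moves + 1L
      loc <- list(x = center[[1L]], y = center[[2L]])
    }
    last_loc <- loc
    log$cam_x[[k]] <- cam[[1L]]; log$cam_y[[k]] <- cam[[2L]]
    locs$x[[k]] <- loc$x; locs$y[[k]] <- loc$y
    if (!is.null(frame_callback))
      frame_callback(view, i, cam, ts_all[[i]])
  }
  list(camera_log = log, locations = locs, n_moves = n_moves)
}

#' Read / write a camera log CSV
#'
#' Plain CSV with columns `frame`, `cam_x`, `cam_y` (pixels) and optionally
#' `t` (seconds).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_camera_log <- function(path) {
  log <- utils::read.csv(path)
  need <- c("frame", "cam_x", "cam_y")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("camera log is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(log$cam_x) | !is.finite(log$cam_y))
  if (length(bad)) stop("camera log has non-numeric entries, first bad line: ", bad[[1L]] + 1L)
  if (any(diff(log$frame) <= 0)) stop("camera log frame indices must be strictly increasing")
  log
}

#' @rdname read_camera_log
#' @param log camera log data.frame.
#' @export
write_camera_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
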