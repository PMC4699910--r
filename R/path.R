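#' Wrap angles to (-180, 180] degrees
#'
#' Angular differences (turning detection, angular speed) are wrapped to the
#' principal range before use so that a left turn of 10 degrees never shows up
#' as a right turn of 350.
#'
#' @param deg numeric vector of angles in degrees.
#' @return wrapped angles in (-180, 180].
#' @export
wrap_angle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Reconstruct the global centroid path
#'
#' Per-frame centroids are only positions within the current camera view; the
#' global path (relative to the initial camera position) is recovered by
#' adding the camera offset recorded for that frame and scaling by the
#' pixels-per-mm calibration. Invalid centroids become gaps (NA coordinates)
#' rather than being interpolated.
#'
#' @param centroids data.frame with columns `frame`, `cx`, `cy`, `valid` and
#'   optionally `t` (as produced by [segment_stack()]).
#' @param camera_log data.frame with `frame`, `cam_x`, `cam_y` (px), one entry
#'   per centroid frame.
#' @param calibration pixels per millimetre (> 0); default 128 px/mm, the
#'   native optics of a 1280x960 sensor imaging a ~10 x 7.5 mm field.
#' @return data.frame of class `worm_path`: `t` (s), `x`, `y` (mm), `valid`;
#'   attribute `calibration`.
#' @export
reconstruct_global <- function(centroids, camera_log, calibration = 128) {
  if (!is.numeric(calibration) || calibration <= 0) stop("`calibration` must be > 0")
  m <- match(centroids$frame, camera_log$frame)
  if (anyNA(m)) {
    miss <- centroids$frame[is.na(m)]
    stop("camera log is missing entries for frames: ",
         paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) " ..." else "")
  }
  t <- if (!is.null(centroids$t)) centroids$t else
    if (!is.null(camera_log$t)) camera_log$t[m] else as.numeric(centroids$frame)
  valid <- centroids$valid & is.finite(centroids$cx) & is.finite(centroids$cy)
  x <- ifelse(valid, (centroids$cx + camera_log$cam_x[m]) / calibration, NA_real_)
  y <- ifelse(valid, (centroids$cy + camera_log$cam_y[m]) / calibration, NA_real_)
  worm_path(t, x, y, valid, calibration = calibration)
}

#' Construct a centroid path
#'
#' @param t seconds from recording start (strictly increasing).
#' @param x,y global coordinates in mm (NA where invalid).
#' @param valid logical validity flags.
#' @param calibration pixels per mm used to produce the coordinates.
#' @return data.frame of class `worm_path`.
#' @export
worm_path <- function(t, x, y, valid = is.finite(x) & is.finite(y),
                      calibration = NA_real_) {
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  structure(data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                       valid = as.logical(valid)),
            calibration = calibration,
            class = c("worm_path", "data.frame"))
}

#' @export
plot.worm_path <- function(x, ...) {
  ok <- x$valid
  graphics::plot(x$x[ok], x$y[ok], type = "l", asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}

#' Read / write a centroid path CSV
#'
#' Columns `t`, `x_mm`, `y_mm`, `valid`.
#'
#' @param path file path.
#' @param calibration optional calibration to attach.
#' @return a `worm_path`.
#' @export
read_path_csv <- function(path, calibration = NA_real_) {
  d <- utils::read.csv(path)
  need <- c("t", "x_mm", "y_mm", "valid")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("path CSV is missing columns: ", paste(miss, collapse = ", "))
  worm_path(d$t, d$x_mm, d$y_mm, as.logical(d$valid), calibration = calibration)
}

#' @rdname read_path_csv
#' @param p a `worm_path`.
#' @export
write_path_csv <- function(p, path) {
  utils::write.csv(data.frame(t = p$t, x_mm = p$x, y_mm = p$y, valid = p$valid),
                   path, row.names = FALSE)
  invisible(path)
}

#' Movement features: speed, acceleration, heading and angular speed
#'
#' Windowed finite differences over the sample interval `delta`:
#' speed `s_t = sqrt((x_t-x_{t-d})^2 + (y_t-y_{t-d})^2)/d`, acceleration
#' `a_t = (s_t - s_{t-d})/d`, heading `phi_t` is the direction of the
#' displacement vector with respect to the horizontal (computed with the
#' quadrant-aware two-argument arctangent so leftward and rightward motion are
#' distinguished, in (-180, 180] degrees), and angular speed
#' `w_t = wrap(phi_t - phi_{t-d})/d`. `delta` trades noise reduction against
#' fidelity; features are only defined where both samples of each difference
#' are valid, and heading is NA for zero displacement.
#'
#' @param path a `worm_path`.
#' @param delta sample interval in seconds; must be (close to) a positive
#'   multiple of the path's sampling period.
#' @return data.frame `t`, `speed` (mm/s), `accel` (mm/s^2), `angle` (deg),
#'   `ang_speed` (deg/s); attribute `delta`. Empty when the path is shorter
#'   than `2*delta`.
#' @export
movement_features <- function(path, delta = 1) {
  if (delta <= 0) stop("`delta` must be positive")
  n <- nrow(path)
  empty <- data.frame(t = numeric(0), speed = numeric(0), accel = numeric(0),
                      angle = numeric(0), ang_speed = numeric(0))
  attr(empty, "delta") <- delta
  if (n < 2L) return(empty)
  period <- stats::median(diff(path$t))
  k <- round(delta / period)
  if (k < 1L || abs(k * period - delta) > 0.05 * delta)
    stop("`delta` must be a positive multiple of the sampling period (", signif(period, 4), " s)")
  if (n < 2L * k + 1L && n < k + 1L) return(empty)
  idx <- (k + 1L):n
  if (length(idx) == 0L) return(empty)
  ok <- path$valid[idx] & path$valid[idx - k]
  dx <- path$x[idx] - path$x[idx - k]
  dy <- path$y[idx] - path$y[idx - k]
  speed <- ifelse(ok, sqrt(dx^2 + dy^2) / delta, NA_real_)
  disp0 <- ok & (dx != 0 | dy != 0)
  angle <- ifelse(disp0, atan2(dy, dx) * 180 / pi, NA_real_)
  feat <- data.frame(t = path$t[idx], speed = speed, angle = angle)
  # second differences, aligned on the same time grid
  m <- nrow(feat)
  accel <- rep(NA_real_, m); ang_speed <- rep(NA_real_, m)
  if (m > k) {
    j <- (k + 1L):m
    accel[j] <- (feat$speed[j] - feat$speed[j - k]) / delta
    ang_speed[j] <- wrap_angle(feat$angle[j] - feat$angle[j - k]) / delta
  }
  feat$accel <- accel
  feat$ang_speed <- ang_speed
  feat <- feat[, c("t", "speed", "accel", "angle", "ang_speed")]
  attr(feat, "delta") <- delta
  feat
}
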