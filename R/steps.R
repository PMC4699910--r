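#' Resample a centroid path onto a regular time grid
#'
#' Step-length analysis samples the centroid at a regular interval (default
#' 1 s). For each grid time the nearest valid sample within half a grid step
#' is chosen; grid slots with no valid sample nearby produce path breaks, and
#' steps never span a break. Contiguous runs between breaks are numbered by a
#' `segment` column.
#'
#' @param path a `worm_path`.
#' @param dt sampling interval in seconds (> 0).
#' @return data.frame of class `sampled_path`: `t` (grid time), `x`, `y`,
#'   `segment`; attribute `dt`.
#' @export
resample_path <- function(path, dt = 1) {
  if (dt <= 0) stop("`dt` must be positive")
  ok <- path$valid & is.finite(path$x) & is.finite(path$y)
  if (!any(ok)) stop("path contains no valid samples")
  if (diff(range(path$t)) < 2 * dt) stop("path duration must be at least 2*dt")
  tv <- path$t[ok]; xv <- path$x[ok]; yv <- path$y[ok]
  t0 <- path$t[[1L]]
  grid <- seq(t0, path$t[[nrow(path)]], by = dt)
  # nearest valid sample to each grid time
  pos <- findInterval(grid, tv)
  lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(tv))
  d_lo <- abs(grid - tv[lo]); d_hi <- abs(grid - tv[hi])
  use <- ifelse(pos < 1L, hi, ifelse(d_lo <= d_hi, lo, hi))
  dist <- abs(grid - tv[use])
  good <- dist <= dt / 2 + 1e-9
  seg <- cumsum(!good)[good] + 1L
  seg <- as.integer(factor(seg, levels = unique(seg)))  # renumber 1..n
  out <- data.frame(t = grid[good], x = xv[use[good]], y = yv[use[good]],
                    segment = seg)
  structure(out, dt = dt, class = c("sampled_path", "data.frame"))
}

# headings (deg) of inter-sample segments; zero displacement carries the
# previous heading forward (heading is undefined on a zero vector)
.segment_headings <- function(x, y) {
  dx <- diff(x); dy <- diff(y)
  h <- ifelse(dx == 0 & dy == 0, NA_real_, atan2(dy, dx) * 180 / pi)
  if (length(h) > 1L) {
    for (i in 2:length(h)) if (is.na(h[[i]])) h[[i]] <- h[[i - 1L]]
  }
  h
}

#' Identify turning events along a sampled path
#'
#' Walks the sampled path keeping the reference heading `phi_p` set at the
#' most recent turning event; at each subsequent inter-sample segment with
#' heading `phi_c`, a turning event is declared at the segment's starting
#' vertex when `|wrap(phi_c - phi_p)| > theta`. The first point of every
#' contiguous path segment is a turning event (TE_0). With
#' `reference = "outbound"` (default) `phi_p` is the heading of the first
#' inter-sample segment leaving the previous turning event — the direction
#' the step sets out in; `"inbound"` uses the heading of the segment arriving
#' at the event instead.
#'
#' @param sampled a [resample_path()] result (or data.frame `t`, `x`, `y`,
#'   optionally `segment`).
#' @param theta threshold angle in degrees, in (0, 180); default 40 deg
#'   (head-swing of a straight-moving worm stays within +/-30 deg, so 40
#'   separates genuine course changes from gait wiggle).
#' @param reference `"outbound"` or `"inbound"` definition of the heading at
#'   the previous turning event.
#' @return data.frame: `j` (event index within its segment, 0-based), `t`,
#'   `x`, `y`, `heading_prev`, `heading_curr` (deg; NA for TE_0), `segment`.
#' @export
find_turning_events <- function(sampled, theta = 40,
                                reference = c("outbound", "inbound")) {
  if (!is.numeric(theta) || theta <= 0 || theta >= 180)
    stop("`theta` must lie in (0, 180)")
  reference <- match.arg(reference)
  if (is.null(sampled$segment)) sampled$segment <- 1L
  res <- list()
  for (s in unique(sampled$segment)) {
    p <- sampled[sampled$segment == s, , drop = FALSE]
    m <- nrow(p)
    if (m < 1L) next
    ev_idx <- 1L; prev_h <- numeric(0); curr_h <- numeric(0)
    if (m >= 2L) {
      h <- .segment_headings(p$x, p$y)       # h[i]: heading of p_i -> p_{i+1}
      te <- 1L
      phi_p <- h[[te]]                       # outbound heading of TE_0
      i <- 2L
      while (i <= m - 1L) {
        phi_c <- h[[i]]
        if (!is.na(phi_c) && !is.na(phi_p) &&
            abs(wrap_angle(phi_c - phi_p)) > theta) {
          ev_idx <- c(ev_idx, i)
          prev_h <- c(prev_h, phi_p); curr_h <- c(curr_h, phi_c)
          te <- i
          phi_p <- if (reference == "outbound") h[[i]] else h[[i - 1L]]
        } else if (is.na(phi_p) && !is.na(phi_c)) {
          phi_p <- phi_c                     # first defined heading after TE
        }
        i <- i + 1L
      }
    }
    res[[length(res) + 1L]] <- data.frame(
      j = seq_along(ev_idx) - 1L, t = p$t[ev_idx], x = p$x[ev_idx], y = p$y[ev_idx],
      heading_prev = c(NA_real_, prev_h), heading_curr = c(NA_real_, curr_h),
      segment = s)
  }
  do.call(rbind, res)
}

#' Step lengths between consecutive turning events
#'
#' A step is the straight line segment between two consecutive turning
#' events; its length is the Euclidean distance between them. A terminal step
#' from the last turning event to the final sampled point is appended so the
#' path is fully partitioned — without it, a long final relocation would be
#' silently dropped, biasing the tail of the step-length distribution.
#'
#' @param events a [find_turning_events()] result for one path segment.
#' @param terminal the final sampled point, list/row with `t`, `x`, `y`; omit
#'   (NULL) to use only inter-event steps.
#' @return data.frame of class `step_series`: `j`, `t_start`, `t_end`, `x0`,
#'   `y0`, `x1`, `y1`, `length` (mm).
#' @export
step_lengths <- function(events, terminal = NULL) {
  if (is.null(events) || nrow(events) == 0L) stop("at least one turning event is required")
  xs <- events$x; ys <- events$y; ts <- events$t
  if (!is.null(terminal) &&
      !(terminal$x == xs[[length(xs)]] && terminal$y == ys[[length(ys)]] &&
        terminal$t == ts[[length(ts)]])) {
    xs <- c(xs, terminal$x); ys <- c(ys, terminal$y); ts <- c(ts, terminal$t)
  }
  n <- length(xs)
  if (n < 2L) {
    out <- data.frame(j = 1L, t_start = ts[[1L]], t_end = ts[[1L]],
                      x0 = xs[[1L]], y0 = ys[[1L]], x1 = xs[[1L]], y1 = ys[[1L]],
                      length = 0)
    return(structure(out, class = c("step_series", "data.frame")))
  }
  i <- 2:n
  out <- data.frame(j = i - 1L, t_start = ts[i - 1L], t_end = ts[i],
                    x0 = xs[i - 1L], y0 = ys[i - 1L], x1 = xs[i], y1 = ys[i],
                    length = sqrt((xs[i] - xs[i - 1L])^2 + (ys[i] - ys[i - 1L])^2))
  structure(out, class = c("step_series", "data.frame"))
}

#' Turning events and step lengths for a whole path
#'
#' Convenience wrapper: resamples the path at `dt`, finds turning events at
#' threshold `theta` within each contiguous segment, and computes step
#' lengths including the terminal step of each segment (steps never span
#' breaks).
#'
#' @inheritParams resample_path
#' @inheritParams find_turning_events
#' @return a `step_series` data.frame (see [step_lengths()]) with a `segment`
#'   column; attributes `theta`, `dt`.
#' @export
path_steps <- function(path, dt = 1, theta = 40,
                       reference = c("outbound", "inbound")) {
  reference <- match.arg(reference)
  sp <- resample_path(path, dt)
  ev <- find_turning_events(sp, theta, reference)
  res <- list()
  for (s in unique(ev$segment)) {
    p <- sp[sp$segment == s, , drop = FALSE]
    st <- step_lengths(ev[ev$segment == s, , drop = FALSE],
                       terminal = list(t = p$t[[nrow(p)]], x = p$x[[nrow(p)]],
                                       y = p$y[[nrow(p)]]))
    st$segment <- s
    res[[length(res) + 1L]] <- st
  }
  out <- do.call(rbind, res)
  structure(out, theta = theta, dt = dt, class = c("step_series", "data.frame"))
}

#' Mean step length over time
#'
#' Mean of the step lengths whose terminating turning event falls in each
#' time window; windows containing no step are flagged NA (missing), not
#' zero.
#'
#' @param steps a `step_series`.
#' @param window window length in seconds (> 0).
#' @return data.frame: `window` (k), `t_start`, `t_end`, `mean_length`, `n`.
#' @export
mean_step_length_series <- function(steps, window = 60) {
  if (window <= 0) stop("`window` must be positive")
  t0 <- min(steps$t_start)
  k <- pmax(1L, ceiling((steps$t_end - t0) / window))
  nk <- max(k)
  out <- data.frame(window = seq_len(nk),
                    t_start = t0 + (seq_len(nk) - 1L) * window,
                    t_end = t0 + seq_len(nk) * window,
                    mean_length = NA_real_, n = 0L)
  for (kk in seq_len(nk)) {
    s <- steps$length[k == kk]
    out$n[[kk]] <- length(s)
    if (length(s)) out$mean_length[[kk]] <- mean(s)
  }
  out
}

#' Read / write a step series CSV
#'
#' Columns `j,t_start,t_end,x0,y0,x1,y1,length_mm` (plus `segment`).
#'
#' @param path file path.
#' @return a `step_series`.
#' @export
read_steps_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!"length_mm" %in% names(d)) stop("steps CSV is missing column length_mm")
  names(d)[names(d) == "length_mm"] <- "length"
  structure(d, class = c("step_series", "data.frame"))
}

#' @rdname read_steps_csv
#' @param steps a `step_series`.
#' @export
write_steps_csv <- function(steps, path) {
  d <- as.data.frame(steps)
  names(d)[names(d) == "length"] <- "length_mm"
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
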