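#' Grid cell occupancy
#'
#' Divides the plate into a grid of square cells (default 1 mm^2, about the
#' length of an adult worm) and counts the number of unique cells the
#' centroid visits during each time interval (default 60 s). High per-interval
#' occupancy means the worm covers fresh ground; low occupancy with sustained
#' speed means it is re-searching the same area. Visitation is sample-based: a
#' cell crossed between two samples without a sample landing in it is not
#' counted.
#'
#' The grid is anchored at the floor of the path's minimum x and y by default
#' (`anchor = NULL`), or at an explicit `anchor = c(x0, y0)` in mm; anchoring
#' can shift counts by a boundary cell.
#'
#' @param path a `worm_path` (mm).
#' @param cell_size cell side in mm (> 0).
#' @param interval interval length tau in seconds (> 0).
#' @param anchor optional grid origin `c(x0, y0)` in mm.
#' @return data.frame of class `occupancy_series`: `interval` (k, 1-based),
#'   `t_start`, `t_end`, `n_cells` (O_k), `cumulative_unique`; attributes
#'   `cell_size`, `interval`, `t0`. Empty path gives an empty series.
#' @export
cell_occupancy <- function(path, cell_size = 1, interval = 60, anchor = NULL) {
  if (cell_size <= 0) stop("`cell_size` must be > 0")
  if (interval <= 0) stop("`interval` must be > 0")
  ok <- path$valid & is.finite(path$x) & is.finite(path$y)
  empty <- data.frame(interval = integer(0), t_start = numeric(0), t_end = numeric(0),
                      n_cells = integer(0), cumulative_unique = integer(0))
  if (nrow(path) == 0L || !any(ok)) {
    return(structure(empty, cell_size = cell_size, interval = interval,
                     t0 = NA_real_, class = c("occupancy_series", "data.frame")))
  }
  x <- path$x[ok]; y <- path$y[ok]; t <- path$t[ok]
  origin <- if (is.null(anchor)) c(floor(min(x)), floor(min(y))) else as.numeric(anchor)
  ci <- floor((x - origin[[1L]]) / cell_size)
  cj <- floor((y - origin[[2L]]) / cell_size)
  cell <- paste(ci, cj)
  t0 <- path$t[[1L]]
  k <- pmax(1L, ceiling((t - t0) / interval))
  k[t == t0] <- 1L
  nk <- max(k)
  seen <- character(0)
  out <- data.frame(interval = seq_len(nk),
                    t_start = t0 + (seq_len(nk) - 1L) * interval,
                    t_end = t0 + seq_len(nk) * interval,
                    n_cells = 0L, cumulative_unique = 0L)
  for (kk in seq_len(nk)) {
    cells_k <- unique(cell[k == kk])
    out$n_cells[[kk]] <- length(cells_k)
    seen <- union(seen, cells_k)
    out$cumulative_unique[[kk]] <- length(seen)
  }
  structure(out, cell_size = cell_size, interval = interval, t0 = t0,
            class = c("occupancy_series", "data.frame"))
}

#' Locality index
#'
#' Locality `L(tau_k) = E[v_k] / O_k`: the mean instantaneous speed over
#' interval k divided by the number of unique grid cells visited in that
#' interval. Because intervals have equal length, `E[v_k]` is proportional to
#' the distance travelled, so L contrasts distance covered with fresh area
#' searched: a worm circling fast inside one cell scores high (local search),
#' a worm dispersing in a straight line scores low (global search).
#'
#' @param features output of [movement_features()] (per-frame speeds).
#' @param occupancy output of [cell_occupancy()] on the same path.
#' @return data.frame: `interval`, `t_start`, `mean_speed` (mm/s), `n_cells`,
#'   `locality` (mm/s per cell; NA flagged where O_k = 0 or no speed samples).
#' @export
locality <- function(features, occupancy) {
  t0 <- attr(occupancy, "t0")
  tau <- attr(occupancy, "interval")
  if (is.null(t0) || is.null(tau)) stop("`occupancy` must come from cell_occupancy()")
  out <- data.frame(interval = occupancy$interval, t_start = occupancy$t_start,
                    mean_speed = NA_real_, n_cells = occupancy$n_cells,
                    locality = NA_real_)
  for (i in seq_len(nrow(out))) {
    kk <- occupancy$interval[[i]]
    in_k <- features$t > t0 + (kk - 1L) * tau & features$t <= t0 + kk * tau
    v <- features$speed[in_k]
    v <- v[is.finite(v)]
    if (length(v)) out$mean_speed[[i]] <- mean(v)
    if (length(v) && occupancy$n_cells[[i]] > 0L)
      out$locality[[i]] <- out$mean_speed[[i]] / occupancy$n_cells[[i]]
  }
  out
}
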