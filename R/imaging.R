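#' @useDynLib wormpath, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Cache of sparse Gaussian band operators keyed by (n, sigma). Row-normalised
# so a constant image is exactly invariant and intensity is conserved away
# from borders (border rows renormalise the truncated kernel mass).
.gauss_cache <- new.env(parent = emptyenv())

.gauss_operator <- function(n, sigma) {
  key <- sprintf("%d_%.6g", n, sigma)
  op <- .gauss_cache[[key]]
  if (!is.null(op)) return(op)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  diags <- lapply(-r:r, function(off) rep(k[[off + r + 1L]], n - abs(off)))
  op <- Matrix::bandSparse(n, n, k = -r:r, diagonals = diags)
  rs <- Matrix::rowSums(op)
  op <- Matrix::Diagonal(n, 1 / rs) %*% op
  .gauss_cache[[key]] <- op
  op
}

#' Gaussian smoothing of a frame
#'
#' Separable Gaussian filter (kernel truncated at 3 sigma) used to reduce
#' sensor noise and homogenize intensities across the worm body before
#' thresholding. Border windows renormalise the truncated kernel, so constant
#' images are exactly invariant.
#'
#' @param frame `worm_frame` or numeric matrix.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return numeric matrix of the same shape (not re-quantized to integers).
#' @export
gaussian_smooth <- function(frame, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number")
  px <- frame_pixels(frame)
  storage.mode(px) <- "double"
  R <- .gauss_operator(nrow(px), sigma)
  C <- .gauss_operator(ncol(px), sigma)
  out <- as.matrix(R %*% px %*% Matrix::t(C))
  dimnames(out) <- NULL
  out
}

# Local window means via an integral image; the window is intersected with the
# image at borders, i.e. means are taken over the in-image part only.
.local_mean <- function(px, window) {
  nr <- nrow(px); nc <- ncol(px)
  r <- (window - 1L) %/% 2L
  # padded cumulative sums: S[i+1, j+1] = sum px[1:i, 1:j]
  cs <- apply(px, 2L, cumsum)                       # down rows
  if (nr == 1L) cs <- matrix(cs, 1L, nc)
  cs2 <- t(apply(cs, 1L, cumsum))                   # then across columns
  if (nc == 1L) cs2 <- matrix(cs, nr, 1L)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- cs2
  i0 <- pmax(seq_len(nr) - r, 1L); i1 <- pmin(seq_len(nr) + r, nr)
  j0 <- pmax(seq_len(nc) - r, 1L); j1 <- pmin(seq_len(nc) + r, nc)
  A <- S[i1 + 1L, j1 + 1L, drop = FALSE] - S[i0, j1 + 1L, drop = FALSE] -
       S[i1 + 1L, j0, drop = FALSE] + S[i0, j0, drop = FALSE]
  cnt <- outer(i1 - i0 + 1L, j1 - j0 + 1L)
  A / cnt
}

#' Adaptive ratio thresholding
#'
#' Marks a pixel as on-worm when the ratio of its intensity to the mean
#' intensity of its local square neighborhood falls below `ratio` (default
#' 80%). The worm is darker than the agar background, so the test selects
#' locally dark pixels regardless of uneven illumination. Windows are
#' intersected with the image at borders.
#'
#' @param frame `worm_frame` or numeric matrix.
#' @param window odd window side length in pixels (>= 3).
#' @param ratio threshold ratio in (0, 1); default 0.80.
#' @return logical matrix (`TRUE` = on-worm) of class `worm_mask`.
#' @export
adaptive_threshold <- function(frame, window = 25L, ratio = 0.80) {
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3")
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1)
    stop("`ratio` must lie in (0, 1)")
  px <- frame_pixels(frame)
  storage.mode(px) <- "double"
  if (window > nrow(px) && window > ncol(px))
    stop("`window` is larger than both image dimensions")
  mu <- .local_mean(px, window)
  # px / mu < ratio, written multiplicatively so an all-black window is off
  mask <- px < ratio * mu
  structure(mask, class = c("worm_mask", class(mask)))
}

# Offsets of a disc structuring element of the given diameter (odd width).
.disc_offsets <- function(width) {
  r <- (width - 1L) / 2L
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

.dilate <- function(mask, offs) {
  .morph_cpp(mask, as.integer(offs$dr), as.integer(offs$dc), TRUE)
}

.erode <- function(mask, offs) {
  .morph_cpp(mask, as.integer(offs$dr), as.integer(offs$dc), FALSE)
}

#' Morphological closing with a disc element
#'
#' Dilation followed by erosion with a disc structuring element of diameter
#' `disk_width` pixels (default 5, roughly the worm's body width). Fills
#' interior holes in the worm segmentation smaller than the disc. Pixels
#' outside the image are treated as background for both operations, so the
#' result need not be a superset of the input at the border.
#'
#' @param mask logical matrix / `worm_mask`.
#' @param disk_width disc diameter in pixels (odd integer >= 1).
#' @return `worm_mask` of the same shape.
#' @export
close_mask <- function(mask, disk_width = 5L) {
  disk_width <- as.integer(disk_width)
  if (is.na(disk_width) || disk_width < 1L || disk_width %% 2L == 0L)
    stop("`disk_width` must be an odd integer >= 1")
  m <- unclass(mask)
  if (!is.logical(m)) stop("`mask` must be logical")
  offs <- .disc_offsets(disk_width)
  out <- .erode(.dilate(m, offs), offs)
  structure(out, class = c("worm_mask", class(out)))
}

#' Largest connected component of a mask
#'
#' Labels 8-connected components (diagonally touching body pixels stay
#' connected) and retains only the component of maximal area; ties are broken
#' toward the component first encountered in raster-scan order. An empty mask
#' is returned unchanged.
#'
#' @param mask logical matrix / `worm_mask`.
#' @param connectivity 8 (default) or 4.
#' @return `worm_mask` containing only the largest component, with attribute
#'   `area` (its pixel count, 0 when empty).
#' @export
largest_component <- function(mask, connectivity = 8L) {
  m <- unclass(mask)
  if (!is.logical(m)) stop("`mask` must be logical")
  if (!any(m)) {
    out <- m & FALSE
    return(structure(out, area = 0L, class = c("worm_mask", class(out))))
  }
  lab <- .label_components_cpp(m, as.integer(connectivity))
  areas <- tabulate(lab[lab > 0L])
  best <- which.max(areas)  # lowest label wins ties (raster-scan order)
  out <- lab == best
  structure(out, area = areas[[best]], class = c("worm_mask", class(out)))
}

#' Centroid of a binary mask
#'
#' The centroid is the arithmetic mean of the x (column) and y (row)
#' coordinates of all on-pixels, 0-based. An empty mask yields an invalid
#' centroid rather than an error.
#'
#' @param mask logical matrix / `worm_mask`.
#' @param frame_index optional frame number carried into the result.
#' @return list with `x`, `y`, `frame_index`, `valid`, `area`.
#' @export
centroid <- function(mask, frame_index = NA_integer_) {
  m <- unclass(mask)
  if (!is.logical(m)) stop("`mask` must be logical")
  idx <- which(m)
  if (length(idx) == 0L)
    return(list(x = NA_real_, y = NA_real_, frame_index = frame_index,
                valid = FALSE, area = 0L))
  nr <- nrow(m)
  rows <- (idx - 1L) %% nr          # 0-based row = y
  cols <- (idx - 1L) %/% nr         # 0-based col = x
  list(x = mean(cols), y = mean(rows), frame_index = frame_index,
       valid = TRUE, area = length(idx))
}

#' Segmentation configuration
#'
#' Defaults: Gaussian sigma 1 px; ratio threshold 0.80; 25 px square
#' neighborhood; disc diameter 5 px; plausible worm area 50--5000 px^2;
#' components touching the image border rejected (worm against the plate edge
#' is unreliable).
#'
#' @param sigma Gaussian smoothing sigma (px).
#' @param threshold_ratio adaptive threshold ratio in (0,1).
#' @param window adaptive threshold neighborhood side (odd px).
#' @param disk_width closing disc diameter (odd px).
#' @param min_area,max_area plausibility bounds on worm area (px^2).
#' @param reject_border flag frames whose component touches the border.
#' @return named list of class `segmentation_config`.
#' @export
segmentation_config <- function(sigma = 1, threshold_ratio = 0.80, window = 25L,
                                disk_width = 5L, min_area = 50L, max_area = 5000L,
                                reject_border = TRUE) {
  cfg <- list(sigma = sigma, threshold_ratio = threshold_ratio,
              window = as.integer(window), disk_width = as.integer(disk_width),
              min_area = as.integer(min_area), max_area = as.integer(max_area),
              reject_border = isTRUE(reject_border))
  if (cfg$min_area < 0L || cfg$max_area < cfg$min_area)
    stop("need 0 <= min_area <= max_area")
  structure(cfg, class = "segmentation_config")
}

.touches_border <- function(mask) {
  any(mask[1L, ]) || any(mask[nrow(mask), ]) || any(mask[, 1L]) || any(mask[, ncol(mask)])
}

#' Segment a single frame and extract the worm centroid
#'
#' Full segmentation chain: Gaussian smoothing, adaptive ratio thresholding,
#' disc closing, largest connected component, centroid. The frame is flagged
#' invalid when the component's area falls outside the configured plausibility
#' bounds or (optionally) when it touches the image border — such frames are
#' discarded downstream rather than interpolated.
#'
#' @param frame `worm_frame` or intensity matrix.
#' @param config a [segmentation_config()].
#' @return list with `mask` (`worm_mask`) and `centroid` (see [centroid()];
#'   `valid = FALSE` on rejection).
#' @export
segment_frame <- function(frame, config = segmentation_config()) {
  sm <- gaussian_smooth(frame, config$sigma)
  thr <- adaptive_threshold(sm, config$window, config$threshold_ratio)
  mask <- close_mask(thr, config$disk_width)
  mask <- largest_component(mask)
  cen <- centroid(mask, frame_index = attr(frame, "index"))
  area <- attr(mask, "area")
  if (cen$valid) {
    border <- FALSE
    if (config$reject_border) {
      # closing erodes the mask away from the border, so border contact is
      # judged on the raw threshold pixels in the worm's neighborhood
      near <- .dilate(unclass(mask), .disc_offsets(config$disk_width)) & unclass(thr)
      border <- .touches_border(near)
    }
    if (area < config$min_area || area > config$max_area || border)
      cen$valid <- FALSE
  }
  cen$area <- area
  list(mask = mask, centroid = cen)
}

#' Segment every frame of a stack
#'
#' @param stack a [frame_stack()].
#' @param config a [segmentation_config()].
#' @return data.frame with columns `frame`, `t`, `cx`, `cy`, `area`, `valid`
#'   (coordinates in frame pixels, 0-based; NA where invalid).
#' @export
segment_stack <- function(stack, config = segmentation_config()) {
  n <- length(stack$frames)
  out <- data.frame(frame = integer(n), t = numeric(n), cx = numeric(n),
                    cy = numeric(n), area = integer(n), valid = logical(n))
  for (i in seq_len(n)) {
    f <- stack$frames[[i]]
    idx <- attr(f, "index")
    seg <- segment_frame(f, config)
    cen <- seg$centroid
    out$frame[[i]] <- if (is.null(idx) || is.na(idx)) i - 1L else idx
    out$t[[i]] <- stack$timestamps[[i]]
    out$cx[[i]] <- if (cen$valid) cen$x else NA_real_
    out$cy[[i]] <- if (cen$valid) cen$y else NA_real_
    out$area[[i]] <- cen$area
    out$valid[[i]] <- cen$valid
  }
  out
}
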