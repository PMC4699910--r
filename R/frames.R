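#' Grayscale video frames
#'
#' A frame is stored as an integer matrix of 8-bit intensities in `[0, 255]`,
#' indexed `[row, col]` with the image coordinate convention x = column,
#' y = row, origin at the top-left, 0-based. Frame number and acquisition time
#' are kept as attributes so frames can travel through the pipeline on their
#' own.
#'
#' @param pixels numeric or integer matrix of intensities in `[0, 255]`.
#' @param index frame number (integer, 0-based or 1-based as the source uses;
#'   carried through unchanged).
#' @param timestamp seconds from the start of the recording.
#' @return an object of class `worm_frame` (an integer matrix with `index` and
#'   `timestamp` attributes).
#' @export
worm_frame <- function(pixels, index = NA_integer_, timestamp = NA_real_) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("frame intensities must lie in [0, 255]")
  m <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  structure(m, index = as.integer(index), timestamp = as.numeric(timestamp),
            class = c("worm_frame", class(m)))
}

frame_pixels <- function(frame) {
  if (inherits(frame, "worm_frame")) unclass(frame) else frame
}

#' @export
print.worm_frame <- function(x, ...) {
  cat(sprintf("<worm_frame %dx%d px, index %s, t = %s s>\n",
              ncol(x), nrow(x), attr(x, "index"), format(attr(x, "timestamp"))))
  invisible(x)
}

#' Ordered stack of frames
#'
#' @param frames list of `worm_frame` objects or plain intensity matrices.
#' @param timestamps seconds from recording start, one per frame, strictly
#'   increasing. Defaults to timestamps carried by the frames.
#' @return object of class `worm_frame_stack`: list with elements `frames` and
#'   `timestamps`.
#' @export
frame_stack <- function(frames, timestamps = NULL) {
  if (!is.list(frames) || length(frames) == 0L) stop("`frames` must be a non-empty list")
  if (is.null(timestamps))
    timestamps <- vapply(frames, function(f) as.numeric(attr(f, "timestamp")), numeric(1))
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != length(frames) || anyNA(timestamps))
    stop("one finite timestamp is required per frame")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(frames = frames, timestamps = timestamps), class = "worm_frame_stack")
}

#' @export
length.worm_frame_stack <- function(x) length(x$frames)

#' @export
print.worm_frame_stack <- function(x, ...) {
  cat(sprintf("<worm_frame_stack of %d frames, %.1f s>\n", length(x$frames),
              diff(range(x$timestamps))))
  invisible(x)
}

#' Read a directory of PNG frames as a stack
#'
#' Files are taken in lexicographic order; RGB images are converted to
#' grayscale by averaging channels. Timestamps are assigned at a fixed frame
#' rate unless given explicitly.
#'
#' @param dir directory containing `.png` files.
#' @param fps frames per second used to assign timestamps.
#' @param timestamps optional explicit timestamps (seconds), overrides `fps`.
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(dir, fps = 1, timestamps = NULL) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no .png files found in ", dir)
  frames <- lapply(seq_along(files), function(i) {
    a <- png::readPNG(files[[i]])
    if (length(dim(a)) == 3L) a <- rowMeans(a, dims = 2L)
    worm_frame(round(a * 255), index = i - 1L,
               timestamp = if (is.null(timestamps)) (i - 1) / fps else timestamps[[i]])
  })
  frame_stack(frames)
}

#' Write a frame to a PNG file
#'
#' @param frame a `worm_frame` or intensity matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame_pixels(frame) / 255, path)
  invisible(path)
}
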