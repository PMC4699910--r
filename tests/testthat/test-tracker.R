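# small synthetic two-frame fixtures: dark blobs on a light background
blob_frame <- function(nr, nc, blobs, bg = 180) {
  px <- matrix(bg, nr, nc)
  for (b in blobs) {
    ys <- max(1, b$y - 2):min(nr, b$y + 2)
    xs <- max(1, b$x - 2):min(nc, b$x + 2)
    px[ys, xs] <- b$int
  }
  px
}

test_that("identical frames give zero difference and keep the last location", {
  f <- blob_frame(60, 80, list(list(x = 30, y = 30, int = 60)))
  loc <- difference_locate(f, f, last_location = list(x = 12, y = 34))
  expect_equal(loc$value, 0)
  expect_equal(c(loc$x, loc$y), c(12, 34))
})

test_that("a moved blob is found while a static artifact cancels", {
  art <- list(x = 51, y = 6, int = 40)   # immobile dark artifact
  ref <- blob_frame(60, 80, list(list(x = 11, y = 11, int = 60), art))
  cur <- blob_frame(60, 80, list(list(x = 41, y = 41, int = 60), art))
  loc <- difference_locate(cur, ref, polarity = "dark")
  expect_lt(abs(loc$x - 40), 3)  # 0-based: blob center col 41 -> x = 40
  expect_lt(abs(loc$y - 40), 3)
  # artifact site has exactly zero difference
  d <- abs(cur - ref)
  expect_true(all(d[4:8, 49:53] == 0))
})

test_that("cropping restricts the search to the window around the last location", {
  # in-window blob moves a little; decoy blob moves far outside the window
  ref <- blob_frame(80, 80, list(list(x = 40, y = 40, int = 60),
                                 list(x = 10, y = 70, int = 30)))
  cur <- blob_frame(80, 80, list(list(x = 44, y = 42, int = 60),
                                 list(x = 70, y = 10, int = 30)))
  loc <- difference_locate(cur, ref, last_location = list(x = 40, y = 40),
                           crop_size = 24, polarity = "dark")
  expect_lt(abs(loc$x - 43), 4)
  expect_lt(abs(loc$y - 41), 4)
})

test_that("a static scene with immobile artifacts never reports an artifact", {
  set.seed(5)
  arts <- lapply(1:6, function(i)
    list(x = sample(5:75, 1), y = sample(5:55, 1), int = 40))
  f <- blob_frame(60, 80, arts)
  for (rep in 1:5) {
    loc <- difference_locate(f, f, last_location = list(x = 2, y = 2))
    expect_equal(c(loc$x, loc$y, loc$value), c(2, 2, 0))
  }
})

test_that("tracking a stationary blob emits no camera moves", {
  frames <- lapply(0:9, function(i)
    worm_frame(blob_frame(60, 80, list(list(x = 40, y = 30, int = 60))),
               index = i, timestamp = i))
  st <- frame_stack(frames)
  tr <- track_stream(st, tracker_config(subsample_hz = 1))
  expect_equal(tr$n_moves, 0L)
  expect_equal(length(unique(tr$camera_log$cam_x)), 1L)
  expect_error(track_stream(frame_stack(frames[0])), "non-empty")
})

test_that("the tracking loop follows a moving worm across a large world", {
  w <- world_spec(arena = 40, view_px = c(120L, 90L), noise_sd = 2)
  spec <- trajectory_spec("ballistic", duration = 240, speed = 0.25,
                          arena = 40, seed = 9)
  sim <- simulate_trajectory(spec)
  src <- make_world_source(w, sim$path, seed = 9)
  cfg <- tracker_config(subsample_hz = 1, view_width = 120L, view_height = 90L,
                        crop_size = 60L)
  start <- round(c(sim$path$x[[1]] * w$calibration - 60,
                   sim$path$y[[1]] * w$calibration - 45))
  tr <- track_stream(src, cfg, timestamps = attr(src, "timestamps"),
                     cam_start = start)
  expect_gt(tr$n_moves, 0L)
  # the difference-image peak rides the moving end of the body, so the raw
  # estimate tracks the course within about a body length (30 px here); the
  # precise position comes from segmentation downstream
  truth <- attr(src, "truth")()
  gx <- tr$camera_log$cam_x + tr$locations$x
  gy <- tr$camera_log$cam_y + tr$locations$y
  err <- sqrt((gx - truth$x_world)^2 + (gy - truth$y_world)^2)
  expect_lt(stats::median(err, na.rm = TRUE), 30)
})

test_that("reconstructed paths are invariant to when re-centering happens", {
  w <- world_spec(arena = 40, view_px = c(120L, 90L), noise_sd = 1)
  spec <- trajectory_spec("brownian", duration = 180, speed = 0.25,
                          turn_sd = 20, arena = 40, seed = 21)
  sim <- simulate_trajectory(spec)
  run_with <- function(frac) {
    src <- make_world_source(w, sim$path, seed = 21)
    cfg <- tracker_config(subsample_hz = 1, view_width = 120L, view_height = 90L,
                          recenter_frac = frac, crop_size = 60L)
    scfg <- segmentation_config(min_area = 20L, max_area = 2000L)
    rows <- new.env(); rows$d <- list()
    cb <- function(view, frame, cam, t) {
      cen <- segment_frame(worm_frame(view, index = frame, timestamp = t), scfg)$centroid
      rows$d[[as.character(frame)]] <- data.frame(
        frame = frame, t = t, cx = ifelse(cen$valid, cen$x, NA),
        cy = ifelse(cen$valid, cen$y, NA), valid = cen$valid)
    }
    start <- round(c(sim$path$x[[1]] * 20 - 60, sim$path$y[[1]] * 20 - 45))
    tr <- track_stream(src, cfg, timestamps = attr(src, "timestamps"),
                       cam_start = start, frame_callback = cb)
    cens <- do.call(rbind, unname(rows$d))
    cens <- cens[order(cens$frame), ]
    reconstruct_global(cens, tr$camera_log, 20)
  }
  p1 <- run_with(0.15)
  p2 <- run_with(0.35)
  ok <- p1$valid & p2$valid
  expect_gt(mean(ok), 0.9)
  err <- sqrt((p1$x - p2$x)^2 + (p1$y - p2$y)^2)[ok]
  expect_lt(stats::median(err), 0.1)  # mm
})

test_that("camera log reader validates structure", {
  tmp <- tempfile(fileext = ".csv")
  log <- data.frame(frame = 1:5, cam_x = c(0, 0, 10, 10, 10), cam_y = 0)
  write_camera_log(log, tmp)
  expect_equal(read_camera_log(tmp)$cam_x, log$cam_x)
  bad <- data.frame(frame = 1:3, cam_x = c(0, NA, 1), cam_y = 0)
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_camera_log(tmp), "first bad line: 3")
})
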