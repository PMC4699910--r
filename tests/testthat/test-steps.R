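test_that("resampling decimates, breaks on gaps, and picks nearest samples", {
  # 10 Hz path, dt = 1 -> every 10th sample
  t <- seq(0, 20, by = 0.1)
  p <- worm_path(t, t * 0.2, rep(0, length(t)))
  sp <- resample_path(p, 1)
  expect_equal(sp$t, 0:20)
  expect_equal(sp$x, 0.2 * (0:20), tolerance = 1e-12)
  expect_equal(unique(sp$segment), 1L)
  # 5 s invalid gap -> two segments, no step across
  valid <- !(t > 8 & t < 13)
  p2 <- worm_path(t, t * 0.2, rep(0, length(t)), valid)
  sp2 <- resample_path(p2, 1)
  expect_equal(length(unique(sp2$segment)), 2L)
  st2 <- path_steps(p2, dt = 1, theta = 40)
  expect_true(all(st2$length < 2))  # no 5 s jump bridged
  # jittered timestamps: chosen samples minimize |t - grid|
  set.seed(47)
  tj <- sort(runif(200, 0, 40))
  pj <- worm_path(tj, tj, rep(0, 200))
  spj <- resample_path(pj, 1)
  for (i in seq_len(nrow(spj))) {
    expect_equal(abs(spj$x[[i]] - spj$t[[i]]), min(abs(tj - spj$t[[i]])),
                 tolerance = 1e-9)
  }
  expect_error(resample_path(worm_path(c(0, 10), c(0, 1), c(0, 1), c(FALSE, FALSE)), 1),
               "no valid samples")
})

test_that("straight paths yield no internal turning events; corners yield one", {
  sp <- data.frame(t = 0:10, x = 0.5 * (0:10), y = rep(0, 11), segment = 1L)
  ev <- find_turning_events(sp, 40)
  expect_equal(nrow(ev), 1L)  # only TE_0
  st <- step_lengths(ev, terminal = list(t = 10, x = 5, y = 0))
  expect_equal(nrow(st), 1L)
  expect_equal(st$length, 5)
  # right-angle L: one internal event exactly at the corner
  L <- data.frame(t = 0:6, x = c(0, 1, 2, 3, 3, 3, 3), y = c(0, 0, 0, 0, 1, 2, 3),
                  segment = 1L)
  evL <- find_turning_events(L, 40)
  expect_equal(nrow(evL), 2L)
  expect_equal(c(evL$x[[2]], evL$y[[2]]), c(3, 0))
  stL <- step_lengths(evL, terminal = list(t = 6, x = 3, y = 3))
  expect_equal(stL$length, c(3, 3))
})

test_that("turning events match an independent walker on sinuous paths", {
  set.seed(53)
  for (rep in 1:10) {
    n <- 60
    heading <- cumsum(rnorm(n, 0, 35))
    x <- cumsum(cos(heading * pi / 180)); y <- cumsum(sin(heading * pi / 180))
    sp <- data.frame(t = seq_len(n) - 1, x = x, y = y, segment = 1L)
    ev <- find_turning_events(sp, 40)
    idx <- oracle_turning_events(x, y, 40)
    expect_equal(ev$t, sp$t[idx])
  }
})

test_that("step lengths are Euclidean distances plus a terminal step", {
  ev <- data.frame(j = 0:1, t = c(0, 5), x = c(0, 3), y = c(0, 4),
                   heading_prev = NA, heading_curr = NA, segment = 1L)
  st <- step_lengths(ev, terminal = list(t = 9, x = 3, y = 4))
  expect_equal(st$length[[1]], 5)        # 3-4-5 triangle
  # terminal at the last event's position: degenerate zero step, emitted
  expect_equal(st$length, c(5, 0))
  # degenerate: single event, terminal at the same point -> zero step emitted
  ev1 <- ev[1, ]
  st1 <- step_lengths(ev1, terminal = list(t = 0, x = 0, y = 0))
  expect_equal(st1$length, 0)
})

test_that("lowering the threshold angle never removes turning events", {
  set.seed(59)
  for (rep in 1:5) {
    n <- 80
    heading <- cumsum(rnorm(n, 0, 30))
    sp <- data.frame(t = seq_len(n) - 1,
                     x = cumsum(cos(heading * pi / 180)),
                     y = cumsum(sin(heading * pi / 180)), segment = 1L)
    counts <- vapply(c(100, 70, 40, 20, 10), function(th)
      nrow(find_turning_events(sp, th)), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("rotating a path leaves the step-length multiset unchanged", {
  sim <- simulate_trajectory(trajectory_spec("levy", duration = 400, seed = 61))
  p <- sim$path
  th <- 77 * pi / 180
  pr <- worm_path(p$t, p$x * cos(th) - p$y * sin(th),
                  p$x * sin(th) + p$y * cos(th))
  s1 <- sort(path_steps(p, 1, 40)$length)
  s2 <- sort(path_steps(pr, 1, 40)$length)
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("steps are chords: their sum never exceeds the sampled arc length", {
  for (seed in 1:5) {
    sim <- simulate_trajectory(trajectory_spec("brownian", duration = 300,
                                               seed = seed))
    sp <- resample_path(sim$path, 1)
    arc <- sum(sqrt(diff(sp$x)^2 + diff(sp$y)^2))
    st <- path_steps(sim$path, 1, 40)
    expect_lte(sum(st$length), arc + 1e-9)
  }
})

test_that("curvy paths produce more, shorter steps than straight ones", {
  n <- 301
  t <- seq_len(n) - 1
  # matched arc length: same per-sample displacement
  set.seed(67)
  curvy_heading <- cumsum(rnorm(n - 1, 0, 50))
  curvy <- worm_path(t, c(0, cumsum(0.2 * cos(curvy_heading * pi / 180))),
                     c(0, cumsum(0.2 * sin(curvy_heading * pi / 180))))
  straight <- worm_path(t, 0.2 * t, rep(0, n))
  sc <- path_steps(curvy, 1, 40); ss <- path_steps(straight, 1, 40)
  expect_gt(nrow(sc), nrow(ss))
  expect_lt(mean(sc$length), mean(ss$length))
})

test_that("mean step length series tracks phases and flags empty windows", {
  st <- structure(data.frame(j = 1:4, t_start = c(0, 10, 130, 140),
                             t_end = c(10, 20, 140, 150),
                             x0 = 0, y0 = 0, x1 = 0, y1 = 0,
                             length = c(2, 2, 6, 6)),
                  class = c("step_series", "data.frame"))
  ser <- mean_step_length_series(st, window = 60)
  expect_equal(ser$mean_length[[1]], 2)
  expect_equal(ser$mean_length[[3]], 6)
  expect_true(is.na(ser$mean_length[[2]]))  # empty window flagged, not zero
  expect_equal(ser$n[[2]], 0L)
  # constant steps -> constant series
  stc <- structure(data.frame(j = 1:6, t_start = seq(0, 50, 10),
                              t_end = seq(10, 60, 10), x0 = 0, y0 = 0,
                              x1 = 0, y1 = 0, length = 2),
                   class = c("step_series", "data.frame"))
  expect_true(all(mean_step_length_series(stc, 30)$mean_length == 2))
})

test_that("simulated two-phase recordings switch mean step length mid-way", {
  sim <- simulate_trajectory(trajectory_spec("two_phase", duration = 1200, seed = 71))
  st <- path_steps(sim$path, 1, 40)
  ser <- mean_step_length_series(st, 60)
  first <- mean(ser$mean_length[ser$t_start < 600], na.rm = TRUE)
  second <- mean(ser$mean_length[ser$t_start >= 600], na.rm = TRUE)
  expect_gt(second, first)
})

test_that("steps CSV round-trips", {
  sim <- simulate_trajectory(trajectory_spec("levy", duration = 200, seed = 73))
  st <- path_steps(sim$path, 1, 40)
  tmp <- tempfile(fileext = ".csv")
  write_steps_csv(st, tmp)
  st2 <- read_steps_csv(tmp)
  expect_equal(st2$length, st$length)
})
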