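test_that("gaussian smoothing preserves constants and peaks at point sources", {
  const <- matrix(120, 20, 30)
  expect_equal(gaussian_smooth(const, 1.5), const)
  point <- matrix(0, 21, 21); point[11, 11] <- 255
  sm <- gaussian_smooth(point, 1)
  expect_equal(which.max(sm), which.max(point))
  expect_true(sm[11, 11] < 255)           # mass spread out
  expect_equal(sum(sm), 255, tolerance = 1e-6)  # conserved away from borders
  expect_equal(sm[10, 11], sm[12, 11])    # kernel symmetry
  expect_equal(sm[11, 10], sm[11, 12])
  expect_error(gaussian_smooth(const, 0), "sigma")
})

test_that("gaussian smoothing matches a brute-force convolution oracle", {
  set.seed(42)
  px <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_equal(gaussian_smooth(px, 2), oracle_gaussian(px, 2), tolerance = 1e-8)
  px2 <- matrix(runif(16 * 24, 0, 255), 16, 24)
  expect_equal(gaussian_smooth(px2, 1), oracle_gaussian(px2, 1), tolerance = 1e-8)
})

test_that("adaptive threshold implements the intensity-to-local-mean ratio rule", {
  # pixel at 70 inside a window averaging 100 with ratio 0.8: 0.70 < 0.80 -> on
  px <- matrix(100, 25, 25)
  px[13, 13] <- 70
  px <- px + (70 - mean(px)) * 0  # keep exact values
  m <- adaptive_threshold(px, window = 25L, ratio = 0.8)
  mu <- mean(px)  # window covers whole image at the center pixel
  expect_true(70 / mu < 0.8)
  expect_true(m[13, 13])
  # perfectly uniform frame: ratio is exactly 1 everywhere, never < 0.8
  expect_false(any(adaptive_threshold(matrix(200, 30, 30), 9L, 0.8)))
  expect_error(adaptive_threshold(px, window = 8L), "odd")
  expect_error(adaptive_threshold(px, window = 101L), "larger")
})

test_that("adaptive threshold matches the windowed-mean oracle on random frames", {
  set.seed(7)
  for (rep in 1:3) {
    px <- matrix(sample(0:255, 20 * 28, replace = TRUE), 20, 28)
    got <- adaptive_threshold(px, window = 7L, ratio = 0.8)
    expect_identical(unclass(got), oracle_adaptive_threshold(px, 7L, 0.8))
  }
})

test_that("closing fills small holes, leaves solids, and is idempotent", {
  solid <- matrix(FALSE, 20, 20); solid[5:15, 4:16] <- TRUE
  expect_identical(unclass(close_mask(solid, 5L)), solid)
  # annulus with a 3 px hole, disc width 5: hole filled
  ring <- matrix(FALSE, 21, 21)
  ring[8:14, 8:14] <- TRUE
  ring[10:12, 10:12] <- FALSE
  closed <- close_mask(ring, 5L)
  expect_true(all(closed[10:12, 10:12]))
  # idempotence
  set.seed(11)
  m <- random_mask(24, 24)
  once <- close_mask(m, 5L)
  expect_identical(unclass(close_mask(once, 5L)), unclass(once))
})

test_that("closing equals the brute-force structuring-element oracle", {
  set.seed(13)
  for (rep in 1:3) {
    m <- random_mask(18, 22, n_blobs = 4L)
    expect_identical(unclass(close_mask(m, 5L)), oracle_close(m, 5L))
    expect_identical(unclass(close_mask(m, 3L)), oracle_close(m, 3L))
  }
})

test_that("largest component keeps only the maximal blob", {
  m <- matrix(FALSE, 30, 30)
  m[2:13, 2:11] <- TRUE          # 120 px
  m[20:26, 20] <- TRUE           # 7 px
  out <- largest_component(m)
  expect_equal(attr(out, "area"), 120L)
  expect_false(any(out[20:26, 20]))
  empty <- matrix(FALSE, 5, 5)
  out2 <- largest_component(empty)
  expect_false(any(out2))
  expect_equal(attr(out2, "area"), 0L)
})

test_that("largest component agrees with a flood-fill oracle on random blobs", {
  set.seed(19)
  for (rep in 1:10) {
    m <- random_mask(16, 16, n_blobs = 5L, len = 8L)
    got <- largest_component(m)
    expect_identical(plain(got), oracle_largest(m))
    expect_equal(attr(got, "area"), max(tabulate(oracle_label(m))))
  }
})

test_that("8-connectivity keeps diagonal bodies connected", {
  m <- matrix(FALSE, 6, 6)
  for (i in 1:6) m[i, i] <- TRUE
  expect_equal(attr(largest_component(m, 8L), "area"), 6L)
  expect_equal(attr(largest_component(m, 4L), "area"), 1L)
})

test_that("centroid is the mean of on-pixel coordinates", {
  m <- matrix(FALSE, 10, 10)
  m[6, 4] <- TRUE   # 0-based (x = 3, y = 5)
  cen <- centroid(m)
  expect_equal(c(cen$x, cen$y), c(3, 5))
  m2 <- matrix(FALSE, 4, 4); m2[1:2, 1:2] <- TRUE
  cen2 <- centroid(m2)
  expect_equal(c(cen2$x, cen2$y), c(0.5, 0.5))
  # empty mask: invalid, never an error
  cen3 <- centroid(matrix(FALSE, 3, 3))
  expect_false(cen3$valid)
  # random blobs vs brute force
  set.seed(23)
  for (rep in 1:10) {
    m <- random_mask(16, 16)
    cen <- centroid(m)
    expect_equal(c(cen$x, cen$y), unname(oracle_centroid(m)))
  }
})

test_that("segment_frame recovers rendered worm centroids and rejects junk", {
  w <- add_artifacts(world_spec(noise_sd = 2), n = 3L, seed = 2)
  cfg <- segmentation_config(min_area = 20L, max_area = 2000L)
  set.seed(3)
  f <- render_view(w, c(5, 3.75), 35, cam = c(0, 0), index = 0L, t = 0)
  tr <- attr(f, "truth")
  seg <- segment_frame(f, cfg)
  expect_true(seg$centroid$valid)
  expect_lt(sqrt((seg$centroid$x - tr$x)^2 + (seg$centroid$y - tr$y)^2), 1)
  # all-background frame: nothing to segment
  bg <- worm_frame(matrix(180, 150, 200) + matrix(rnorm(30000, 0, 2), 150, 200))
  expect_false(segment_frame(bg, cfg)$centroid$valid)
  # worm plus small dark artifacts: artifacts removed by largest component
  wa <- w
  wa$artifacts <- data.frame(x = c(2, 8, 3), y = c(1, 6, 6), r = c(2, 2, 2),
                             intensity = c(40, 40, 40))
  f2 <- render_view(wa, c(5, 3.75), -10, cam = c(0, 0))
  tr2 <- attr(f2, "truth")
  seg2 <- segment_frame(f2, cfg)
  expect_true(seg2$centroid$valid)
  expect_lt(sqrt((seg2$centroid$x - tr2$x)^2 + (seg2$centroid$y - tr2$y)^2), 1)
})
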