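test_that("binocular_points averages eyes and tolerates missing ones", {
  tr <- data.frame(t_ms = c(0, 18, 36),
                   lx = c(100, 50, NA), ly = c(100, 60, NA),
                   rx = c(110, NA, NA), ry = c(100, NA, NA),
                   valid = TRUE)
  p <- binocular_points(tr)
  expect_equal(p$x, c(105, 50, NA_real_))
  expect_equal(p$y, c(100, 60, NA_real_))
})

test_that("fixation counts accumulate retained on-screen samples", {
  tr <- const_gaze_trace(10, 10, n = 165)
  fm <- build_fixation_map(tr, exclude_initial_ms = 0, sigma_px = 2)
  expect_identical(fm$counts[11, 11], 165L) # 0-based (10,10)
  expect_identical(sum(fm$counts), 165L)
  # 55 Hz sampling: 11 samples fall in [0, 200) ms
  fm200 <- build_fixation_map(tr, exclude_initial_ms = 200, sigma_px = 2)
  expect_identical(sum(fm200$counts), 154L)
})

test_that("smoothing conserves count mass exactly, even at borders", {
  # samples hugging a corner stress the truncated-kernel renormalization
  tr <- const_gaze_trace(1, 1, n = 40, screen = c(64, 48))
  fm <- build_fixation_map(tr, exclude_initial_ms = 0, sigma_px = 6)
  expect_equal(sum(fm$smoothed), sum(fm$counts), tolerance = 1e-6)
  set.seed(31)
  tr2 <- simulate_gaze(data.frame(x = 320, y = 240, weight = 1),
                       screen = c(640, 480), noise_px = 40, seed = 5)
  fm2 <- build_fixation_map(tr2, sigma_px = 10)
  expect_equal(sum(fm2$smoothed), sum(fm2$counts), tolerance = 1e-6)
})

test_that("off-screen and invalid samples are dropped", {
  tr <- gaze_trace(data.frame(
    t_ms = c(0, 10, 20, 30),
    lx = c(5, -20, 10, 8), ly = c(5, 5, 700, 8),
    rx = c(5, -20, 10, 8), ry = c(5, 5, 700, NA),
    valid = c(TRUE, TRUE, TRUE, FALSE)),
    screen = c(100, 100))
  fm <- build_fixation_map(tr, exclude_initial_ms = 0, sigma_px = 1)
  expect_identical(sum(fm$counts), 1L) # only the first survives
})

test_that("increasing the exclusion window never adds counts", {
  set.seed(41)
  tr <- simulate_gaze(data.frame(x = c(100, 400), y = c(120, 300),
                                 weight = c(1, 2)),
                      screen = c(640, 480), seed = 9)
  sums <- vapply(c(0, 100, 200, 500, 1000),
                 function(ex) sum(build_fixation_map(
                   tr, exclude_initial_ms = ex, sigma_px = 3)$counts),
                 numeric(1))
  expect_true(all(diff(sums) <= 0))
})

test_that("simulate_gaze respects rate, determinism and degenerate noise", {
  tr <- simulate_gaze(data.frame(x = 50, y = 50, weight = 1),
                      screen = c(200, 200), duration_ms = 3000,
                      rate_hz = 55, seed = 2)
  expect_identical(nrow(tr), 165L)
  tr_b <- simulate_gaze(data.frame(x = 50, y = 50, weight = 1),
                        screen = c(200, 200), duration_ms = 3000,
                        rate_hz = 55, seed = 2)
  expect_identical(tr, tr_b)
  tr_c <- simulate_gaze(data.frame(x = 50, y = 50, weight = 1),
                        screen = c(200, 200), seed = 3)
  expect_false(identical(tr, tr_c))
  # zero noise, no center bias: every sample sits on the hotspot
  tr0 <- simulate_gaze(data.frame(x = 70, y = 40, weight = 1),
                       screen = c(200, 200), noise_px = 0,
                       center_bias_ms = 0, seed = 4)
  expect_true(all(tr0$lx == 70 & tr0$ly == 40 & tr0$rx == 70 &
                    tr0$ry == 40))
})

test_that("hotspot recovery: smoothed map peaks at the hotspot", {
  tr <- simulate_gaze(data.frame(x = 200, y = 150, weight = 1),
                      screen = c(320, 240), duration_ms = 20000,
                      rate_hz = 500, noise_px = 5, center_bias_ms = 0,
                      seed = 6)
  fm <- build_fixation_map(tr, exclude_initial_ms = 0, sigma_px = 5)
  ix <- which(fm$smoothed == max(fm$smoothed), arr.ind = TRUE)
  expect_lt(sqrt((ix[1, 2] - 1 - 200)^2 + (ix[1, 1] - 1 - 150)^2), 2)
})

test_that("gaze CSV round trip preserves the trace", {
  tr <- simulate_gaze(data.frame(x = 10, y = 20, weight = 1),
                      screen = c(64, 64), duration_ms = 500, seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_gaze_csv(tr, f)
  back <- read_gaze_csv(f, screen = c(64, 64), duration_ms = 500)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-9)
})

test_that("the default smoothing scale matches the viewing geometry", {
  # 1 degree at 70 cm on a 22-inch 1920x1080 display is ~48 px
  expect_equal(visual_angle_px(1), 48.2, tolerance = 0.01)
})
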