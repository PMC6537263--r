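test_that("saliency_error handles identity, complement and random pairs", {
  s <- rand_map(16, 16, 3)
  expect_identical(saliency_error(s, s), matrix(0, 16, 16))
  b <- matrix(rep(c(0, 1), each = 8, times = 16), 16, 16)
  expect_identical(saliency_error(b, 1 - b), matrix(1, 16, 16))
  a <- rand_map(12, 10, 4); b2 <- rand_map(12, 10, 5)
  d <- abs(a - b2)
  expect_equal(saliency_error(a, b2), (d - min(d)) / (max(d) - min(d)),
               tolerance = 1e-12)
  expect_error(saliency_error(a, rand_map(10, 12, 6)), "shape")
})

test_that("weighted_difference weights each Lab channel pointwise", {
  set.seed(7)
  lo <- array(runif(8 * 8 * 3, 0, 100), c(8, 8, 3))
  ls <- array(runif(8 * 8 * 3, 0, 100), c(8, 8, 3))
  err <- rand_map(8, 8, 8)
  d <- weighted_difference(lo, ls, err)
  for (c in 1:3)
    expect_equal(d[, , c], err * (lo[, , c] - ls[, , c]),
                 tolerance = 1e-12)
  expect_identical(weighted_difference(lo, ls, matrix(0, 8, 8)),
                   array(0, c(8, 8, 3)))
  expect_equal(weighted_difference(lo, ls, matrix(1, 8, 8)), lo - ls,
               tolerance = 1e-12)
})

test_that("collapse_to_map averages weighted channel magnitudes", {
  set.seed(9)
  d <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  # oracle: explicit per-pixel loop
  oracle <- function(d, w) {
    m <- matrix(0, dim(d)[1], dim(d)[2])
    for (r in seq_len(dim(d)[1])) for (cc in seq_len(dim(d)[2]))
      m[r, cc] <- mean(w * abs(d[r, cc, ]))
    (m - min(m)) / (max(m) - min(m))
  }
  expect_equal(collapse_to_map(d, c(1, 1, 1)), oracle(d, c(1, 1, 1)),
               tolerance = 1e-12)
  expect_equal(collapse_to_map(d, c(2, 0, 0)), oracle(d, c(2, 0, 0)),
               tolerance = 1e-12)
  expect_identical(collapse_to_map(d, c(0, 0, 0)),
                   matrix(0, 6, 6))
  expect_error(collapse_to_map(d, c(-1, 1, 1)), "nonnegative")
})

test_that("smooth_3x3 is mass-preserving with unit-sum kernel", {
  const <- matrix(0.37, 9, 9)
  expect_lt(max(abs(smooth_3x3(const) - const)), 1e-12)
  # impulse response: the 3x3 kernel stamped at the impulse
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  sm <- smooth_3x3(imp)
  k1 <- exp(-(-1:1)^2 / (2 * 0.85^2)); k1 <- k1 / sum(k1)
  expect_equal(sm[4:6, 4:6], k1 %o% k1, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # total mass preserved under reflect padding
  for (seed in 1:3) {
    m <- rand_map(17, 13, seed)
    expect_equal(sum(smooth_3x3(m)), sum(m), tolerance = 1e-9)
  }
})

test_that("otsu_mask agrees with the exhaustive oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    # bimodal gaussian mixture map
    m <- matrix(c(rnorm(120, 0.25, 0.06), rnorm(136, 0.7, 0.08)), 16, 16)
    got <- otsu_mask(m)
    expect_equal(attr(got, "threshold"), otsu_oracle(m), tolerance = 1e-12)
    # mask is exactly the pixels above the threshold
    expect_identical(which(got), which(m > attr(got, "threshold")))
  }
})

test_that("otsu_mask splits a binary map and rejects constants", {
  b <- matrix(rep(c(0, 1), each = 32), 8, 8)
  mk <- otsu_mask(b)
  thr <- attr(mk, "threshold")
  expect_gt(thr, 0); expect_lt(thr, 1)
  expect_identical(which(mk), which(b == 1))
  expect_warning(mk0 <- otsu_mask(matrix(0.4, 8, 8)), "constant")
  expect_false(any(mk0))
})

test_that("recolor_mask is an exact involution fixing L*", {
  lab <- array(c(50, 30, -20), c(1, 1, 3))
  expect_identical(recolor_mask(lab, matrix(TRUE, 1, 1))[1, 1, ],
                   c(50, -30, 20))
  set.seed(13)
  lab2 <- array(runif(10 * 10 * 3, -60, 90), c(10, 10, 3))
  mask <- rand_map(10, 10, 14) > 0.5
  once <- recolor_mask(lab2, mask)
  expect_identical(recolor_mask(once, mask), lab2) # exact involution
  expect_identical(once[, , 1], lab2[, , 1])       # L* untouched
  # outside the mask nothing changes
  for (c in 2:3)
    expect_identical(once[, , c][!mask], lab2[, , c][!mask])
  expect_identical(recolor_mask(lab2, matrix(FALSE, 10, 10)), lab2)
  expect_error(recolor_mask(lab2, matrix(TRUE, 3, 3)), "shape")
})

test_that("enhance_image is the identity on achromatic scenes", {
  g <- make_redgreen_scene(c(64, 64), seed = 4, chroma = 0)
  res <- enhance_image(g, "protan")
  expect_lt(max(abs(res$enhanced - g)), 1 / 255)
})

test_that("enhance_image recolors the red disc for both deficiencies", {
  for (d in c("protan", "deutan")) {
    scene <- make_redgreen_scene(c(96, 96), seed = 1, deficiency = d)
    disc <- attr(scene, "disc_mask")
    res <- enhance_image(scene, d)
    expect_gte(sum(res$mask & disc) / sum(disc), 0.5)
    lab_o <- rgb_to_lab(scene)
    lab_e <- rgb_to_lab(res$enhanced)
    inmask <- res$mask & disc
    # formerly red pixels turn blue-cyan: a* flips sign
    expect_gt(mean(lab_o[, , 2][inmask]), 20)
    expect_lt(mean(lab_e[, , 2][inmask]), 0)
    # locality: outside the mask the image is untouched
    out <- !res$mask
    for (c in 1:3)
      expect_identical(res$enhanced[, , c][out], scene[, , c][out])
    expect_identical(dim(res$enhanced), dim(scene))
  }
})

test_that("debug intermediates and simulated view are exposed on demand", {
  scene <- make_redgreen_scene(c(64, 64), seed = 6)
  res <- enhance_image(scene, "deutan", simulate_result = TRUE,
                       keep_intermediates = TRUE)
  expect_named(res$intermediates,
               c("simulated", "saliency_orig", "saliency_sim",
                 "weighted_diff", "collapsed", "smoothed"))
  expect_identical(dim(res$simulated_view), dim(scene))
})
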