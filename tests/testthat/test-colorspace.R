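test_that("rgb_to_xyz_matrix reproduces the published sRGB/D65 matrix", {
  m <- rgb_to_xyz_matrix(colorspace_srgb())
  # reference: the standard sRGB/D65 matrix derived from the same
  # primaries and white point (published colorimetry tables)
  ref <- rbind(c(0.4124564, 0.3575761, 0.1804375),
               c(0.2126729, 0.7151522, 0.0721750),
               c(0.0193339, 0.1191920, 0.9503041))
  expect_equal(unname(m), ref, tolerance = 1e-6)
})

test_that("conversion matrix maps RGB white onto the white point", {
  # white-point fidelity is forced by the S-scaling construction
  spaces <- list(
    colorspace_srgb(),
    colorspace_def(rbind(c(0.7, 0.3), c(0.2, 0.7), c(0.14, 0.08)),
                   c(0.9, 1, 1.2), "wide"),
    colorspace_def(rbind(c(1, 1e-9), c(0, 1), c(0, 1e-9)) * 0 +
                     rbind(c(0.735, 0.265), c(0.274, 0.717),
                           c(0.167, 0.009)),
                   c(1, 1, 1), "cie-rgb-ee"))
  for (sp in spaces) {
    m <- rgb_to_xyz_matrix(sp)
    expect_lt(max(abs(m %*% c(1, 1, 1) - sp$white_point)), 1e-12)
  }
})

test_that("degenerate primaries are rejected by name", {
  sp <- colorspace_def(rbind(c(0.3, 0.3), c(0.3, 0.3), c(0.3, 0.3)),
                       c(0.95, 1, 1.05))
  expect_error(rgb_to_xyz_matrix(sp), "degenerate")
})

test_that("colorspace_def validates chromaticities and white point", {
  expect_error(colorspace_def(rbind(c(0.9, 0.3), c(0.3, 0.6), c(0.15, 0.06)),
                              c(0.95, 1, 1.09)), "x \\+ y")
  expect_error(colorspace_def(rbind(c(0.64, 0.33), c(0.3, 0.6), c(0.15, 0.06)),
                              c(0.95, 0.9, 1.09)), "Y_W")
})

test_that("color space definitions survive a JSON round trip", {
  sp <- colorspace_srgb()
  f <- withr::local_tempfile(fileext = ".json")
  colorspace_to_json(sp, f)
  back <- colorspace_from_json(f)
  expect_equal(back$primaries, sp$primaries)
  expect_equal(back$white_point, sp$white_point)
  expect_identical(back$name, sp$name)
  # string form too
  back2 <- colorspace_from_json(colorspace_to_json(sp))
  expect_equal(rgb_to_xyz_matrix(back2), rgb_to_xyz_matrix(sp))
})

test_that("gamma companding matches IEC sRGB at the junction and endpoints", {
  expect_identical(decode_gamma(0), 0)
  expect_identical(decode_gamma(1), 1)
  expect_equal(decode_gamma(0.04045), 0.04045 / 12.92, tolerance = 1e-12)
  # closed form at the junction
  expect_equal(decode_gamma(0.04045), 0.003130805, tolerance = 1e-6)
  expect_error(decode_gamma(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("encode_gamma clips and counts, and inverts decode_gamma", {
  out <- encode_gamma(c(0, 0.5, 1.2))
  expect_equal(as.numeric(out), c(0, encode_gamma(0.5)[1], 1))
  expect_identical(attr(out, "clipped"), 1L)
  x <- c(0, 0.25, 0.5, 0.75, 1)
  expect_equal(as.numeric(encode_gamma(decode_gamma(x))), x,
               tolerance = 1e-12)
  expect_equal(decode_gamma(as.numeric(encode_gamma(decode_gamma(x)))),
               decode_gamma(x), tolerance = 1e-12)
})

test_that("xyz_to_lab hits the anchor colors", {
  sp <- colorspace_srgb()
  white <- array(sp$white_point, c(1, 1, 3))
  expect_equal(xyz_to_lab(white, sp)[1, 1, ], c(100, 0, 0),
               tolerance = 1e-9)
  black <- array(0, c(1, 1, 3))
  expect_equal(xyz_to_lab(black, sp)[1, 1, ], c(0, 0, 0), tolerance = 1e-9)
  # 18% gray: L* = 116 * 0.18^(1/3) - 16, computed independently
  gray <- array(0.18 * sp$white_point, c(1, 1, 3))
  expect_equal(xyz_to_lab(gray, sp)[1, 1, 1], 116 * 0.18^(1 / 3) - 16,
               tolerance = 1e-9)
  expect_equal(xyz_to_lab(gray, sp)[1, 1, 1], 49.49611, tolerance = 1e-5)
  expect_equal(xyz_to_lab(gray, sp)[1, 1, 2:3], c(0, 0), tolerance = 1e-9)
  expect_error(xyz_to_lab(array(-0.1, c(1, 1, 3)), sp), "negative")
})

test_that("the Lab transfer branches agree at the junction", {
  cc <- cie_constants()
  # at ratio = epsilon both branches give exactly 6/29
  cube <- cc$epsilon^(1 / 3)
  lin <- (cc$kappa * cc$epsilon + 16) / 116
  expect_equal(cube, lin, tolerance = 1e-15)
  expect_equal(cube, 6 / 29, tolerance = 1e-15)
})

test_that("lab_to_xyz inverts xyz_to_lab over an in-gamut grid", {
  sp <- colorspace_srgb()
  g <- seq(0, 1, length.out = 17)
  grid <- as.matrix(expand.grid(g, g, g))
  xyz <- sweep(grid, 2L, sp$white_point, "*")
  lab <- xyz_to_lab(array(xyz, c(nrow(xyz), 1, 3)), sp)
  back <- lab_to_xyz(lab, sp)
  expect_lt(max(abs(back - array(xyz, c(nrow(xyz), 1, 3)))), 1e-10)
})

test_that("rgb/lab round trip is lossless for in-gamut colors", {
  sp <- colorspace_srgb()
  # every 8-bit gray: max channel error below half a code value
  grays <- array(rep((0:255) / 255, 3L), c(256, 1, 3))
  rt <- lab_to_rgb(rgb_to_lab(grays, sp), sp)
  expect_lt(max(abs(rt - grays)), 0.5 / 255)
  # neutral axis: a* = b* = 0
  lab <- rgb_to_lab(grays, sp)
  expect_lt(max(abs(lab[, , 2:3])), 1e-9)
  # white and black anchors
  expect_equal(rgb_to_lab(array(1, c(1, 1, 3)), sp)[1, 1, ], c(100, 0, 0),
               tolerance = 1e-9)
  expect_equal(rgb_to_lab(array(0, c(1, 1, 3)), sp)[1, 1, ], c(0, 0, 0),
               tolerance = 1e-9)
})
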