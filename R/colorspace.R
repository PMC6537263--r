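# RGB <-> XYZ <-> CIE L*a*b* conversions, parameterized by primaries and
# white point. The conversion matrix is built from chromaticities the
# standard way: per-primary tristimulus columns X_i = x_i/y_i, Y_i = 1,
# Z_i = (1 - x_i - y_i)/y_i, scaled by S = M0^-1 %*% white so that
# RGB (1,1,1) maps exactly onto the white point.
#
# Symbol note: chromaticity coordinates (x_r, y_r, ...) of the primaries and
# the white-relative ratios X/X_W, Y/Y_W, Z/Z_W used inside the Lab transfer
# function are distinct quantities even though much of the colorimetry
# literature writes both as "x_r"; here the former live in a ColorSpaceDef
# and the latter are unnamed intermediates of xyz_to_lab()/lab_to_xyz().

#' CIE constants for the L*a*b* transfer function
#'
#' The junction constant epsilon and scaling constant kappa of the CIE
#' L*a*b* piecewise transfer function, as exact rationals (216/24389 and
#' 24389/27) rather than the historically truncated 0.008856 / 903.3, so
#' that the two branches agree at the junction to better than 1e-9.
#'
#' @return list with elements `epsilon` and `kappa`.
#' @export
#' @examples
#' cie_constants()$epsilon * cie_constants()$kappa # = 8, the L* junction
cie_constants <- function() {
  list(epsilon = 216 / 24389, kappa = 24389 / 27)
}

#' Define an RGB color space by primaries and white point
#'
#' @param primaries 3x2 numeric matrix of (x, y) chromaticities for the red,
#'   green and blue primaries (rows in that order).
#' @param white_point length-3 tristimulus (X_W, Y_W, Z_W) with Y_W = 1.
#' @param name label for messages and reports.
#' @return object of class `colorspace_def`.
#' @export
colorspace_def <- function(primaries, white_point, name = "custom") {
  primaries <- matrix(as.numeric(primaries), 3L, 2L)
  white_point <- as.numeric(white_point)
  stopifnot(length(white_point) == 3L)
  if (abs(white_point[2] - 1) > 1e-12)
    stop("white point must be normalized to Y_W = 1", call. = FALSE)
  x <- primaries[, 1]; y <- primaries[, 2]
  if (any(x < 0) || any(y <= 0) || any(x + y > 1))
    stop("each primary must satisfy x >= 0, y > 0, x + y <= 1", call. = FALSE)
  structure(list(primaries = primaries, white_point = white_point,
                 name = name),
            class = "colorspace_def")
}

#' The sRGB / D65 color space
#'
#' sRGB primaries (0.64, 0.33), (0.30, 0.60), (0.15, 0.06) with the D65
#' white point (0.95047, 1, 1.08883). This is the package-wide default.
#' @return a [colorspace_def()].
#' @export
colorspace_srgb <- function() {
  colorspace_def(rbind(c(0.64, 0.33), c(0.30, 0.60), c(0.15, 0.06)),
                 c(0.95047, 1.0, 1.08883), name = "sRGB/D65")
}

#' Build the linear-RGB to XYZ conversion matrix
#'
#' Columns are the primaries' tristimulus vectors (X_i = x_i/y_i, Y_i = 1,
#' Z_i = (1 - x_i - y_i)/y_i) scaled so that RGB (1,1,1) maps to the white
#' point exactly.
#'
#' @param space a [colorspace_def()].
#' @return 3x3 numeric matrix mapping linear RGB column vectors to XYZ.
#' @export
#' @examples
#' m <- rgb_to_xyz_matrix(colorspace_srgb())
#' round(m[1, ], 4) # 0.4124 0.3576 0.1805
rgb_to_xyz_matrix <- function(space) {
  stopifnot(inherits(space, "colorspace_def"))
  x <- space$primaries[, 1]; y <- space$primaries[, 2]
  m0 <- rbind(x / y, rep(1, 3), (1 - x - y) / y)
  if (abs(det(m0)) < 1e-12)
    stop("degenerate (collinear) primaries: ",
         paste(sprintf("(%g, %g)", x, y), collapse = ", "), call. = FALSE)
  s <- solve(m0, space$white_point)
  m0 * rep(s, each = 3L)
}

#' Decode gamma-encoded sRGB values to linear light
#'
#' IEC 61966-2-1 companding: v <= 0.04045 maps to v/12.92, larger values to
#' ((v + 0.055)/1.055)^2.4.
#'
#' @param pixels numeric array/matrix/vector of encoded values in [0,1].
#' @return linear-light values, same shape.
#' @export
decode_gamma <- function(pixels) {
  stopifnot_unit_range(pixels, "encoded")
  out <- ifelse(pixels <= 0.04045, pixels / 12.92,
                ((pixels + 0.055) / 1.055)^2.4)
  if (is.array(pixels)) dim(out) <- dim(pixels)
  out
}

#' Encode linear-light values to gamma-encoded sRGB
#'
#' Exact inverse of [decode_gamma()]. Out-of-range inputs are clipped to
#' [0,1] first; the number of clipped samples is attached as attribute
#' `clipped` (the recoloring step can push colors out of gamut).
#'
#' @param pixels numeric array of linear values.
#' @return encoded values in [0,1] with attribute `clipped`.
#' @export
encode_gamma <- function(pixels) {
  # 1e-9 guard so round-trip floating-point dust is not reported as clipping
  n_clip <- sum(pixels < -1e-9 | pixels > 1 + 1e-9)
  v <- clamp01(pixels)
  out <- ifelse(v <= 0.04045 / 12.92, v * 12.92,
                1.055 * v^(1 / 2.4) - 0.055)
  if (is.array(pixels)) dim(out) <- dim(pixels)
  attr(out, "clipped") <- n_clip
  out
}

#' Convert XYZ to CIE L*a*b*
#'
#' Per pixel the white-relative ratios X/X_W, Y/Y_W, Z/Z_W go through the
#' piecewise transfer function f(t) = t^(1/3) for t > epsilon, else
#' (kappa t + 16)/116; then L* = 116 f_y - 16, a* = 500 (f_x - f_y),
#' b* = 200 (f_y - f_z).
#'
#' @param xyz H x W x 3 array (or n x 3 matrix) of nonnegative tristimulus
#'   values, Y relative to white.
#' @param space a [colorspace_def()] supplying the white point.
#' @return array of the same shape with channels L*, a*, b*.
#' @export
xyz_to_lab <- function(xyz, space = colorspace_srgb()) {
  if (any(xyz < 0))
    stop("negative XYZ values are not valid input", call. = FALSE)
  cc <- cie_constants()
  d <- dim(xyz)
  flat <- matrix(xyz, ncol = 3L)
  ratio <- sweep(flat, 2L, space$white_point, "/")
  f <- ifelse(ratio > cc$epsilon, ratio^(1 / 3),
              (cc$kappa * ratio + 16) / 116)
  lab <- cbind(116 * f[, 2] - 16,
               500 * (f[, 1] - f[, 2]),
               200 * (f[, 2] - f[, 3]))
  if (length(d) == 3L) array(lab, d) else lab
}

#' Convert CIE L*a*b* to XYZ
#'
#' Exact algebraic inverse of [xyz_to_lab()], including the two-branch
#' inversion (cube the f-value when f^3 > epsilon, otherwise invert the
#' linear branch).
#'
#' @param lab H x W x 3 array (or n x 3 matrix), channels L*, a*, b*.
#' @param space a [colorspace_def()].
#' @param check validate L* in [0, 100]; internal callers processing
#'   difference images disable this.
#' @return XYZ array of the same shape.
#' @export
lab_to_xyz <- function(lab, space = colorspace_srgb(), check = TRUE) {
  d <- dim(lab)
  flat <- matrix(lab, ncol = 3L)
  if (check && (min(flat[, 1]) < -1e-9 || max(flat[, 1]) > 100 + 1e-9))
    stop("L* must lie in [0, 100]", call. = FALSE)
  cc <- cie_constants()
  fy <- (flat[, 1] + 16) / 116
  fx <- fy + flat[, 2] / 500
  fz <- fy - flat[, 3] / 200
  inv_f <- function(f) ifelse(f^3 > cc$epsilon, f^3,
                              (116 * f - 16) / cc$kappa)
  xyz <- cbind(inv_f(fx), inv_f(fy), inv_f(fz))
  xyz <- sweep(xyz, 2L, space$white_point, "*")
  if (length(d) == 3L) array(xyz, d) else xyz
}

#' Convert encoded RGB to CIE L*a*b*
#'
#' Composition: gamma decode, linear-RGB-to-XYZ matrix, XYZ to Lab.
#'
#' @param pixels H x W x 3 encoded RGB in [0,1].
#' @param space a [colorspace_def()].
#' @return Lab array of the same shape.
#' @export
#' @examples
#' rgb_to_lab(array(1, c(1, 1, 3)))[1, 1, ] # white -> (100, 0, 0)
rgb_to_lab <- function(pixels, space = colorspace_srgb()) {
  stopifnot_image(pixels)
  lin <- decode_gamma(pixels)
  xyz <- apply_matrix3(lin, rgb_to_xyz_matrix(space))
  xyz[xyz < 0] <- 0 # guard tiny negatives from floating-point cancellation
  xyz_to_lab(xyz, space)
}

#' Convert CIE L*a*b* to encoded RGB
#'
#' Inverse composition with gamut handling: out-of-gamut linear RGB is
#' clipped to [0,1] before encoding; the clipped-sample count is attached as
#' attribute `clipped`.
#'
#' @param lab H x W x 3 Lab array.
#' @param space a [colorspace_def()].
#' @param check passed to [lab_to_xyz()].
#' @return encoded RGB array in [0,1] with attribute `clipped`.
#' @export
lab_to_rgb <- function(lab, space = colorspace_srgb(), check = TRUE) {
  xyz <- lab_to_xyz(lab, space, check = check)
  lin <- apply_matrix3(xyz, solve(rgb_to_xyz_matrix(space)))
  encode_gamma(lin)
}

#' Serialize a color space definition to JSON
#'
#' @param space a [colorspace_def()].
#' @param path optional file path; when NULL the JSON string is returned.
#' @return the path (invisibly) or a JSON string.
#' @export
colorspace_to_json <- function(space, path = NULL) {
  stopifnot(inherits(space, "colorspace_def"))
  obj <- list(name = space$name,
              primaries = lapply(1:3, function(i) space$primaries[i, ]),
              white_point = space$white_point)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = NA)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a color space definition from a JSON config block
#'
#' @param x a file path or a JSON string as produced by
#'   [colorspace_to_json()].
#' @return a [colorspace_def()].
#' @export
colorspace_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  primaries <- obj$primaries
  if (is.list(primaries)) primaries <- do.call(rbind, primaries)
  colorspace_def(primaries, obj$white_point,
                 name = obj$name %||% "custom")
}

# Inverse chain for difference images: Lab -> XYZ -> linear RGB with no
# domain checks, no clipping and no companding. The weighted Lab difference
# is not a color; only channel magnitudes are used downstream.
#' @keywords internal
lab_diff_to_linear_rgb <- function(lab, space = colorspace_srgb()) {
  xyz <- lab_to_xyz(lab, space, check = FALSE)
  apply_matrix3(xyz, solve(rgb_to_xyz_matrix(space)))
}
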