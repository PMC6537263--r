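# Internal numeric helpers shared across the pipeline.

#' @keywords internal
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Min-max normalize a raster to [0, 1]
#'
#' Constant rasters (no range to stretch) map to all zeros, the convention
#' used for empty saliency and error maps throughout the package.
#' @param x numeric matrix or array.
#' @return object of the same shape with range [0, 1], or all zeros.
#' @keywords internal
minmax01 <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo <= 0) {
    x[] <- 0
    return(x)
  }
  (x - lo) / (hi - lo)
}

#' Reflect-padded separable convolution of a matrix with a 1D kernel
#'
#' Applies the kernel along rows then columns. Reflection includes the edge
#' sample ("symmetric" padding: index sequence near the top edge is
#' 2, 1 | 1, 2, ...), which makes convolution with a unit-sum symmetric
#' kernel conserve total mass exactly.
#' @param mat numeric matrix.
#' @param kernel odd-length numeric vector.
#' @return filtered matrix, same dimensions.
#' @keywords internal
convolve_sep <- function(mat, kernel) {
  stopifnot(length(kernel) %% 2 == 1)
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(mat * kernel)
  conv1 <- function(m) { # filter along dim 1 (rows of the matrix)
    n <- nrow(m)
    # symmetric indices: top pad = rows r..1, bottom pad = rows n..n-r+1
    top <- pmin(n, rev(seq_len(r)))
    bot <- pmax(1L, n - seq_len(r) + 1L)
    pm <- m[c(top, seq_len(n), bot), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (k in seq_along(kernel)) {
      out <- out + kernel[k] * pm[(k - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat))))
}

#' Sampled, normalized 1D Gaussian kernel
#' @param sigma standard deviation in pixels.
#' @param radius half-width; default ceil(3 sigma).
#' @keywords internal
gauss_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' @keywords internal
gaussian_blur <- function(mat, sigma) {
  convolve_sep(mat, gauss_kernel1d(sigma))
}

#' @keywords internal
stopifnot_image <- function(pixels, name = "pixels") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop(name, " must be an H x W x 3 numeric array", call. = FALSE)
  if (!is.numeric(pixels) || anyNA(pixels) || any(!is.finite(pixels)))
    stop(name, " must be finite numeric", call. = FALSE)
  invisible(pixels)
}

#' @keywords internal
stopifnot_unit_range <- function(pixels, name = "pixels") {
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1)
    stop(name, " values must lie in [0,1]; observed range [",
         format(rng[1]), ", ", format(rng[2]), "]", call. = FALSE)
  invisible(pixels)
}

# Run an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards. All stochastic package code funnels through this
# so that library use never perturbs user RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Apply a 3x3 linear map to every pixel of an H x W x 3 array
#' @keywords internal
apply_matrix3 <- function(pixels, m) {
  d <- dim(pixels)
  flat <- matrix(pixels, ncol = 3L) %*% t(m)
  array(flat, d)
}
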