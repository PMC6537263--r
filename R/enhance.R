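# The enhancement chain: the original image and its dichromat-simulated
# version are compared through their saliency maps; where saliency is lost,
# the saliency error weights the Lab color difference, which — pushed back
# through the inverse color transform, collapsed across channels, smoothed
# and Otsu-thresholded — yields the regions to recolor. Recoloring negates
# a* and b* (a 180 degree rotation of the chroma plane), mapping
# indistinguishable red-green contrast into the blue-yellow range while
# leaving lightness untouched.

#' Saliency error between two saliency maps
#'
#' Elementwise absolute difference of the two maps, min-max normalized to
#' [0,1]. Identical maps give the all-zero map.
#'
#' @param s_orig,s_sim H x W matrices in [0,1] (or `saliency_map` objects).
#' @return H x W matrix in [0,1].
#' @export
saliency_error <- function(s_orig, s_sim) {
  a <- if (inherits(s_orig, "saliency_map")) s_orig$values else s_orig
  b <- if (inherits(s_sim, "saliency_map")) s_sim$values else s_sim
  if (!identical(dim(a), dim(b)))
    stop("saliency maps must have the same shape", call. = FALSE)
  d <- abs(a - b)
  # a constant |difference| carries its level, not zero: identical maps
  # give all zeros, exactly complementary binary maps give all ones
  if (max(d) - min(d) <= 0) return(clamp01(d))
  minmax01(d)
}

#' Saliency-weighted Lab difference
#'
#' Per channel c, D_c(p) = err(p) * (lab_orig_c(p) - lab_sim_c(p)). Signs
#' are retained; magnitudes only enter later at the collapse step.
#'
#' @param lab_orig,lab_sim H x W x 3 Lab arrays.
#' @param err H x W weight matrix in [0,1].
#' @return H x W x 3 signed difference raster.
#' @export
weighted_difference <- function(lab_orig, lab_sim, err) {
  if (!identical(dim(lab_orig), dim(lab_sim)) ||
      !identical(dim(err), dim(lab_orig)[1:2]))
    stop("shape mismatch between Lab images and error map", call. = FALSE)
  d <- lab_orig - lab_sim
  for (c in 1:3) d[, , c] <- d[, , c] * err
  d
}

#' Collapse a three-channel difference raster to a single map
#'
#' The difference raster (already mapped back to the RGB domain by the
#' caller) is weighted per channel by the correction vector, channel
#' magnitudes are averaged, and the result is min-max normalized.
#'
#' @param diff H x W x 3 signed raster.
#' @param correction nonnegative per-channel weights (w_R, w_G, w_B);
#'   default (1, 1, 1).
#' @return H x W matrix in [0,1].
#' @export
collapse_to_map <- function(diff, correction = c(1, 1, 1)) {
  stopifnot(length(dim(diff)) == 3L, dim(diff)[3] == 3L)
  correction <- as.numeric(correction)
  if (length(correction) != 3L || any(!is.finite(correction)) ||
      any(correction < 0))
    stop("correction vector must be three finite nonnegative weights",
         call. = FALSE)
  m <- (correction[1] * abs(diff[, , 1]) +
        correction[2] * abs(diff[, , 2]) +
        correction[3] * abs(diff[, , 3])) / 3
  minmax01(m)
}

#' Smooth a map with a normalized 3x3 Gaussian
#'
#' Fixed 3x3 kernel with sigma = 0.85 (approximately the binomial
#' [1 2 1] x [1 2 1] / 16), reflect padding; the kernel sums to one, so a
#' constant map is a fixed point.
#'
#' @param map numeric matrix.
#' @return smoothed matrix, same shape.
#' @export
smooth_3x3 <- function(map) {
  stopifnot(is.matrix(map))
  k <- exp(-(-1:1)^2 / (2 * 0.85^2))
  convolve_sep(map, k / sum(k))
}

#' Otsu threshold segmentation of a map
#'
#' Histograms the map into 256 equal-width bins over its range and picks
#' the inter-bin cut maximizing the between-class variance
#' w0 w1 (mu0 - mu1)^2; the mask is `map > threshold`. A constant map has
#' no variance to split: the mask is empty and a warning is raised.
#'
#' @param map numeric matrix with finite values.
#' @param n_bins histogram resolution (default 256).
#' @return logical H x W matrix with attribute `threshold`.
#' @export
otsu_mask <- function(map, n_bins = 256L) {
  stopifnot(is.matrix(map), all(is.finite(map)))
  lo <- min(map); hi <- max(map)
  if (hi - lo <= 0) {
    warning("constant map: no variance to split, returning empty mask")
    out <- matrix(FALSE, nrow(map), ncol(map))
    attr(out, "threshold") <- Inf
    return(out)
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(n_bins, findInterval(map, edges, rightmost.closed = TRUE))
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / sum(counts)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)[-n_bins]            # class {bins 1..t}
  mu0 <- cumsum(p * centers)[-n_bins]
  mu_t <- sum(p * centers)
  w1 <- 1 - w0
  bcv <- ifelse(w0 > 0 & w1 > 0, (mu_t * w0 - mu0)^2 / (w0 * w1), -Inf)
  t_star <- which.max(bcv)
  threshold <- edges[t_star + 1L]     # upper edge of the low class
  out <- map > threshold
  attr(out, "threshold") <- threshold
  out
}

#' Negate the chroma channels inside a mask
#'
#' Inside the mask L*' = L*, a*' = -a*, b*' = -b* (a 180 degree rotation of
#' the (a*, b*) plane); pixels outside the mask are untouched. Applying the
#' operation twice with the same mask is the identity.
#'
#' @param lab H x W x 3 Lab array.
#' @param mask logical H x W matrix.
#' @return recolored Lab array.
#' @export
#' @examples
#' lab <- array(c(50, 30, -20), c(1, 1, 3))
#' recolor_mask(lab, matrix(TRUE, 1, 1))[1, 1, ] # 50 -30 20
recolor_mask <- function(lab, mask) {
  if (!identical(dim(mask), dim(lab)[1:2]))
    stop("mask shape must match the image", call. = FALSE)
  out <- lab
  a <- out[, , 2]; b <- out[, , 3]
  a[mask] <- -a[mask]
  b[mask] <- -b[mask]
  out[, , 2] <- a
  out[, , 3] <- b
  out
}

#' Enhance an image for a dichromatic observer
#'
#' End-to-end pipeline: simulate the deficiency, compute keypoint-density
#' saliency of both versions, form the saliency error, weight the Lab color
#' difference by it, map the weighted difference back to the (linear) RGB
#' domain, collapse to a single magnitude map, smooth with a 3x3 Gaussian,
#' segment with Otsu's method, and negate a*/b* of the original image
#' inside the segmented regions. Pixels outside the mask are copied from
#' the input unchanged.
#'
#' @param pixels H x W x 3 encoded RGB array in [0,1].
#' @param deficiency `"protan"` or `"deutan"`.
#' @param space a [colorspace_def()].
#' @param correction per-channel correction vector (w_R, w_G, w_B).
#' @param bandwidth_frac saliency density bandwidth (fraction of diagonal).
#' @param contrast_threshold DoG contrast threshold for the detector.
#' @param min_component_frac if positive, drop mask components smaller than
#'   this fraction of the image area (cleanup; default 0 = off, the
#'   faithful pipeline).
#' @param simulate_result also render the enhanced image through the same
#'   deficiency (the "as seen by the observer" view).
#' @param keep_intermediates retain all intermediate maps for inspection.
#' @return list of class `enhanced_result`: `enhanced` (encoded RGB),
#'   `mask` (logical, attribute `threshold`), `error_map`, optionally
#'   `simulated_view` and `intermediates`.
#' @export
enhance_image <- function(pixels, deficiency, space = colorspace_srgb(),
                          correction = c(1, 1, 1), bandwidth_frac = 0.05,
                          contrast_threshold = 0.01,
                          min_component_frac = 0,
                          simulate_result = FALSE,
                          keep_intermediates = FALSE) {
  stopifnot_image(pixels)
  stopifnot_unit_range(pixels)
  deficiency <- deficiency_type(deficiency)

  sim <- simulate_dichromacy(pixels, deficiency)
  s_orig <- lab_saliency(pixels, space, bandwidth_frac, contrast_threshold)
  s_sim <- lab_saliency(sim, space, bandwidth_frac, contrast_threshold)
  err <- saliency_error(s_orig, s_sim)

  lab_orig <- rgb_to_lab(pixels, space)
  lab_sim <- rgb_to_lab(sim, space)
  wdiff <- weighted_difference(lab_orig, lab_sim, err)
  rgb_diff <- lab_diff_to_linear_rgb(wdiff, space)
  raw_map <- collapse_to_map(rgb_diff, correction)
  smooth <- smooth_3x3(raw_map)
  mask <- if (max(smooth) - min(smooth) <= 0) {
    m <- matrix(FALSE, nrow(smooth), ncol(smooth))
    attr(m, "threshold") <- Inf
    m
  } else otsu_mask(smooth)
  if (min_component_frac > 0) mask <- .prune_mask(mask, min_component_frac)

  enhanced <- pixels
  if (any(mask)) {
    lab_rec <- recolor_mask(lab_orig, mask)
    rec_rgb <- lab_to_rgb(lab_rec, space)
    sel <- which(rep(mask, 3L))
    enhanced[sel] <- rec_rgb[sel]
  }

  res <- structure(list(enhanced = enhanced, mask = mask, error_map = err,
                        deficiency = deficiency,
                        threshold = attr(mask, "threshold")),
                   class = "enhanced_result")
  if (simulate_result)
    res$simulated_view <- simulate_dichromacy(enhanced, deficiency)
  if (keep_intermediates)
    res$intermediates <- list(simulated = sim, saliency_orig = s_orig,
                              saliency_sim = s_sim,
                              weighted_diff = wdiff,
                              collapsed = raw_map, smoothed = smooth)
  res
}

# Remove 4-connected mask components smaller than frac of the image area.
#' @keywords internal
.prune_mask <- function(mask, frac) {
  thr <- attr(mask, "threshold")
  h <- nrow(mask); w <- ncol(mask)
  min_px <- frac * h * w
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    comp <- integer(0)
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      comp <- c(comp, p)
      r <- (p - 1L) %% h + 1L
      cl <- (p - 1L) %/% h + 1L
      if (r > 1L) stack <- c(stack, p - 1L)
      if (r < h) stack <- c(stack, p + 1L)
      if (cl > 1L) stack <- c(stack, p - h)
      if (cl < w) stack <- c(stack, p + h)
    }
    if (length(comp) < min_px) mask[comp] <- FALSE
  }
  attr(mask, "threshold") <- thr
  mask
}

#' @export
print.enhanced_result <- function(x, ...) {
  cat(sprintf(
    "<enhanced_result %s: %d x %d, mask %.1f%% of pixels, threshold %.4g>\n",
    x$deficiency, nrow(x$mask), ncol(x$mask), 100 * mean(x$mask),
    x$threshold))
  invisible(x)
}
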