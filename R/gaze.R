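# Fixation-map construction from binocular gaze logs, and a seeded gaze
# simulator emulating a ~55 Hz screen tracker over 3 s viewings. A gaze
# trace is a data.frame with columns t_ms, lx, ly, rx, ry, valid (missing
# coordinates as NA) plus attributes `screen` (width, height in px) and
# `duration_ms`. Pixel coordinates are 0-based, origin top-left.

#' Construct a gaze trace
#'
#' @param samples data.frame with columns `t_ms`, `lx`, `ly`, `rx`, `ry`,
#'   `valid` (logical or 0/1); missing eye coordinates as NA.
#' @param screen integer (width, height) in pixels.
#' @param duration_ms nominal stimulus duration.
#' @return the validated data.frame with class `gaze_trace`.
#' @export
gaze_trace <- function(samples, screen, duration_ms = 3000) {
  need <- c("t_ms", "lx", "ly", "rx", "ry", "valid")
  if (!all(need %in% names(samples)))
    stop("gaze samples need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(samples$t_ms < 0) || is.unsorted(samples$t_ms))
    stop("timestamps must be nonnegative and nondecreasing", call. = FALSE)
  if (length(screen) != 2L || any(screen <= 0))
    stop("screen must be positive (width, height)", call. = FALSE)
  structure(as.data.frame(samples),
            screen = as.integer(screen),
            duration_ms = duration_ms,
            class = c("gaze_trace", "data.frame"))
}

#' Read a gaze trace from CSV
#'
#' Dialect: header `t_ms,lx,ly,rx,ry,valid`, missing coordinates as empty
#' fields, one file per (subject, image).
#'
#' @param path CSV file path.
#' @param screen (width, height) in pixels.
#' @param duration_ms nominal stimulus duration.
#' @return a [gaze_trace()].
#' @export
read_gaze_csv <- function(path, screen, duration_ms = 3000) {
  df <- utils::read.csv(path, colClasses = c(
    t_ms = "numeric", lx = "numeric", ly = "numeric",
    rx = "numeric", ry = "numeric", valid = "integer"))
  df$valid <- df$valid != 0L
  gaze_trace(df, screen, duration_ms)
}

#' Write a gaze trace to CSV
#'
#' Inverse of [read_gaze_csv()]; missing coordinates become empty fields.
#'
#' @param trace a [gaze_trace()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_gaze_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$valid <- as.integer(df$valid)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Cyclopean gaze point of a binocular sample
#'
#' The fixation point is the mean of the left- and right-eye coordinates;
#' if one eye is missing, the other is used as-is; if both are missing the
#' result is NA.
#'
#' @param trace a [gaze_trace()] (or any data.frame with the gaze columns).
#' @return data.frame with columns `t_ms`, `x`, `y` (NA when unavailable).
#' @export
#' @examples
#' tr <- data.frame(t_ms = 0, lx = 100, ly = 100, rx = 110, ry = 100,
#'                  valid = TRUE)
#' binocular_points(tr) # x = 105, y = 100
binocular_points <- function(trace) {
  x <- rowMeans(cbind(trace$lx, trace$rx), na.rm = TRUE)
  y <- rowMeans(cbind(trace$ly, trace$ry), na.rm = TRUE)
  x[is.nan(x)] <- NA_real_
  y[is.nan(y)] <- NA_real_
  data.frame(t_ms = trace$t_ms, x = x, y = y)
}

#' Accumulate a fixation map from a gaze trace
#'
#' Drops samples earlier than `exclude_initial_ms` (the first ~200 ms of
#' free viewing is center-biased), averages the two eyes, drops
#' invalid/missing/off-screen points after rounding to the nearest pixel
#' (ties to even), increments a per-pixel counter, and smooths with a
#' mass-preserving Gaussian: each count distributes a total mass of exactly
#' one even at the map border (the truncated kernel is renormalized per
#' location).
#'
#' @param trace a [gaze_trace()].
#' @param exclude_initial_ms samples with t < this are dropped (default
#'   200; pass 0 for the center-bias-inclusive variant).
#' @param sigma_px Gaussian smoothing scale in pixels; the default, 48 px,
#'   is one degree of visual angle for a 22-inch 1920x1080 screen viewed at
#'   70 cm (see [visual_angle_px()]).
#' @return list of class `fixation_map`: `counts` (integer H x W, H =
#'   screen height), `smoothed` (same total mass), `points` (retained
#'   pixel coordinates, 0-based), `sigma_px`.
#' @export
build_fixation_map <- function(trace, exclude_initial_ms = 200,
                               sigma_px = 48) {
  stopifnot(exclude_initial_ms >= 0, sigma_px > 0)
  screen <- attr(trace, "screen")
  if (is.null(screen)) stop("trace lacks a screen attribute", call. = FALSE)
  w <- screen[1]; h <- screen[2]
  pts <- binocular_points(trace)
  keep <- trace$t_ms >= exclude_initial_ms & as.logical(trace$valid) &
    !is.na(pts$x) & !is.na(pts$y)
  px <- round(pts$x[keep])
  py <- round(pts$y[keep])
  on <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
  px <- px[on]; py <- py[on]
  counts <- matrix(0L, h, w)
  if (length(px) == 0L) {
    warning("no gaze samples retained; fixation map is empty")
    return(structure(list(counts = counts, smoothed = counts + 0,
                          points = cbind(x = px, y = py),
                          sigma_px = sigma_px),
                     class = "fixation_map"))
  }
  idx <- py + 1L + px * h
  tab <- table(idx)
  counts[as.integer(names(tab))] <- as.integer(tab)
  smoothed <- .stamp_blur(counts, sigma_px)
  structure(list(counts = counts, smoothed = smoothed,
                 points = cbind(x = px, y = py), sigma_px = sigma_px),
            class = "fixation_map")
}

# Mass-preserving blur: stamp a truncated, per-location renormalized
# Gaussian at every nonzero count cell. Counts are sparse (a few hundred
# cells), so stamping beats full convolution and conserves mass exactly.
#' @keywords internal
.stamp_blur <- function(counts, sigma) {
  h <- nrow(counts); w <- ncol(counts)
  r <- ceiling(3 * sigma)
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  out <- matrix(0, h, w)
  nz <- which(counts > 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(nz))) {
    ri <- nz[i, 1]; ci <- nz[i, 2]
    rr <- max(1L, ri - r):min(h, ri + r)
    cc <- max(1L, ci - r):min(w, ci + r)
    stamp <- k1[rr - ri + r + 1L] %o% k1[cc - ci + r + 1L]
    out[rr, cc] <- out[rr, cc] + counts[ri, ci] * stamp / sum(stamp)
  }
  out
}

#' Pixels per degree of visual angle
#'
#' @param degrees visual angle.
#' @param distance_cm eye-to-screen distance (default 70).
#' @param screen_px horizontal resolution (default 1920).
#' @param screen_diag_in screen diagonal in inches (default 22).
#' @param aspect width:height ratio (default 16/9).
#' @return size in pixels subtended by `degrees`.
#' @export
visual_angle_px <- function(degrees = 1, distance_cm = 70,
                            screen_px = 1920, screen_diag_in = 22,
                            aspect = 16 / 9) {
  diag_cm <- screen_diag_in * 2.54
  width_cm <- diag_cm * aspect / sqrt(1 + aspect^2)
  px_per_cm <- screen_px / width_cm
  2 * distance_cm * tan(degrees * pi / 360) * px_per_cm
}

#' Simulate a gaze trace over weighted hotspots
#'
#' Emulates a screen tracker sampling at `rate_hz` for `duration_ms`:
#' samples in the first `center_bias_ms` are drawn around the screen
#' center (the early center bias of free viewing), later samples pick a
#' hotspot with probability proportional to its weight and add isotropic
#' Gaussian jitter. Each eye gets independent jitter of the same scale
#' around the sample point. Deterministic given `seed`.
#'
#' @param hotspots matrix/data.frame with columns `x`, `y`, `weight`
#'   (weights nonnegative, summing > 0).
#' @param screen (width, height) pixels.
#' @param duration_ms viewing time (default 3000).
#' @param rate_hz sampling rate (default 55; 3000 ms at 55 Hz gives 165
#'   samples, the tracker's nominal "about 160 per 3 s").
#' @param noise_px jitter scale (default 5).
#' @param center_bias_ms duration of the initial center-biased phase
#'   (default 200).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a [gaze_trace()].
#' @export
simulate_gaze <- function(hotspots, screen, duration_ms = 3000,
                          rate_hz = 55, noise_px = 5,
                          center_bias_ms = 200, seed = 1L) {
  hotspots <- as.data.frame(hotspots)
  stopifnot(all(c("x", "y", "weight") %in% names(hotspots)))
  if (any(hotspots$weight < 0) || sum(hotspots$weight) <= 0)
    stop("hotspot weights must be nonnegative and sum > 0", call. = FALSE)
  if (rate_hz <= 0 || duration_ms <= 0 || noise_px < 0)
    stop("invalid rate, duration or noise", call. = FALSE)
  # sample instants i/rate in [0, duration): count them without
  # floating-point fencepost surprises (3000 ms at 55 Hz = exactly 165)
  n <- ceiling(duration_ms * rate_hz / 1000 - 1e-9)
  t_ms <- (seq_len(n) - 1) * 1000 / rate_hz
  with_seed(seed, {
    in_bias <- t_ms < center_bias_ms
    cx <- numeric(n); cy <- numeric(n)
    nb <- sum(in_bias)
    if (nb) {
      cx[in_bias] <- screen[1] / 2 + stats::rnorm(nb, 0, noise_px)
      cy[in_bias] <- screen[2] / 2 + stats::rnorm(nb, 0, noise_px)
    }
    nf <- n - nb
    if (nf) {
      pick <- sample.int(nrow(hotspots), nf, replace = TRUE,
                         prob = hotspots$weight)
      cx[!in_bias] <- hotspots$x[pick] + stats::rnorm(nf, 0, noise_px)
      cy[!in_bias] <- hotspots$y[pick] + stats::rnorm(nf, 0, noise_px)
    }
    eye_dx <- stats::rnorm(n, 0, noise_px / 2)
    eye_dy <- stats::rnorm(n, 0, noise_px / 2)
    samples <- data.frame(
      t_ms = t_ms,
      lx = cx - eye_dx, ly = cy - eye_dy,
      rx = cx + eye_dx, ry = cy + eye_dy,
      valid = TRUE)
    gaze_trace(samples, screen, duration_ms)
  })
}
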