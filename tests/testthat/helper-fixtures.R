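# Shared helpers: tiny deterministic inputs built in code.

rand_image <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3L))
}

rand_map <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# one Gaussian blob on a flat background
blob_channel <- function(h = 64, w = 64, cx = 30, cy = 32, sigma = 3,
                         amp = 1) {
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
}

# uniform-rate gaze trace with both eyes at fixed offsets around a path
const_gaze_trace <- function(x, y, n = 165, rate_hz = 55,
                             screen = c(640, 480)) {
  t_ms <- (seq_len(n) - 1L) * 1000 / rate_hz
  gaze_trace(data.frame(t_ms = t_ms, lx = x, ly = y, rx = x, ry = y,
                        valid = TRUE),
             screen = screen)
}

# brute-force keypoint density oracle: plain loop over (pixel, keypoint)
density_oracle <- function(points, h, w, bw) {
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    s <- 0
    if (nrow(points)) for (i in seq_len(nrow(points))) {
      s <- s + exp(-((cc - 1 - points$x[i])^2 + (r - 1 - points$y[i])^2) /
                     (2 * bw^2))
    }
    out[r, cc] <- s
  }
  lo <- min(out); hi <- max(out)
  if (hi - lo <= 0) out * 0 else (out - lo) / (hi - lo)
}

# exhaustive 256-bin Otsu oracle: recompute class stats at every cut
otsu_oracle <- function(map, n_bins = 256L) {
  lo <- min(map); hi <- max(map)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(n_bins, findInterval(map, edges, rightmost.closed = TRUE))
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  best <- -Inf; best_t <- NA_real_
  for (t in seq_len(n_bins - 1L)) {
    in0 <- bin <= t
    n0 <- sum(in0); n1 <- length(map) - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- mean(centers[bin[in0]])
    mu1 <- mean(centers[bin[!in0]])
    bcv <- (n0 / length(map)) * (n1 / length(map)) * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_t <- edges[t + 1L] }
  }
  best_t
}

# O(P*N) pairwise AUC oracle
auc_oracle <- function(map, fixations) {
  idx <- unique(round(fixations$y) + 1L + round(fixations$x) * nrow(map))
  pos <- map[idx]
  neg <- map[-idx]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}
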