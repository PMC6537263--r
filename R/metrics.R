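# Fixation-based saliency metrics. Both compare a map (computed saliency
# or a smoothed fixation map) against reference fixation pixel locations:
# NSS is the mean z-scored map value at the fixations; AUC is the
# Judd-style rank AUC with every non-fixated pixel as a negative.

#' @keywords internal
.fixation_index <- function(map, fixations) {
  fx <- as.data.frame(fixations)
  if (!all(c("x", "y") %in% names(fx)))
    stop("fixations need columns x and y (0-based pixels)", call. = FALSE)
  if (nrow(fx) == 0L) stop("fixation set is empty", call. = FALSE)
  h <- nrow(map); w <- ncol(map)
  x <- round(fx$x); y <- round(fx$y)
  if (any(x < 0 | x > w - 1 | y < 0 | y > h - 1))
    stop("fixations must lie on the map", call. = FALSE)
  y + 1L + x * h
}

#' Normalized scanpath saliency
#'
#' The map is z-scored with its mean and population standard deviation;
#' NSS is the mean z-value at the fixation pixels. Zero means the map is no
#' better than chance at the fixated locations; repeated fixations count
#' with multiplicity.
#'
#' @param map numeric H x W matrix with nonzero variance.
#' @param fixations data.frame/matrix with columns `x`, `y` (0-based).
#' @return scalar NSS.
#' @export
nss <- function(map, fixations) {
  stopifnot(is.matrix(map))
  idx <- .fixation_index(map, fixations)
  mu <- mean(map)
  sd_pop <- sqrt(mean((map - mu)^2))
  if (sd_pop == 0)
    stop("map has zero variance: NSS is undefined", call. = FALSE)
  mean((map[idx] - mu) / sd_pop)
}

#' Area under the ROC curve for fixation prediction
#'
#' Probability that a fixated pixel receives a strictly higher map value
#' than a non-fixated one, counting ties as one half — the exact rank
#' (Mann-Whitney) computation, equivalent to the trapezoidal ROC area over
#' all thresholds. Fixated pixels are deduplicated; all remaining pixels
#' are negatives.
#'
#' @inheritParams nss
#' @return scalar in [0, 1]; 0.5 for a constant map.
#' @export
auc_judd <- function(map, fixations) {
  stopifnot(is.matrix(map))
  idx <- unique(.fixation_index(map, fixations))
  n_pos <- length(idx)
  n_neg <- length(map) - n_pos
  if (n_neg == 0L)
    stop("no negative pixels: every pixel is fixated", call. = FALSE)
  r <- rank(map) # midranks handle ties as 1/2
  (sum(r[idx]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
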