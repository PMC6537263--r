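# Deterministic synthetic stimuli: Ishihara-like dot plates (a symbol
# visible only through red-green contrast) and textured red-on-green
# scenes used as the standard end-to-end enhancement fixture. Everything
# is seeded and reproducible bit-for-bit; all colors are in-gamut sRGB.

# 5x7 dot-matrix glyphs for plate symbols.
.GLYPHS <- list(
  N = c("10001", "11001", "11001", "10101", "10011", "10011", "10001"),
  O = c("01110", "10001", "10001", "10001", "10001", "10001", "01110"),
  X = c("10001", "10001", "01010", "00100", "01010", "10001", "10001"),
  `8` = c("01110", "10001", "10001", "01110", "10001", "10001", "01110")
)

#' Binary symbol mask from dot-matrix glyphs
#'
#' Renders a short string (characters among N, O, X, 8) as a centered
#' binary raster, nearest-neighbor scaled to fill ~60% of the height.
#'
#' @param text string to render (default "NO", the classic plate the
#'   red-green deficient observer *can* read only when the contrast
#'   survives).
#' @param size (H, W) of the mask.
#' @return logical H x W matrix.
#' @export
symbol_mask <- function(text = "NO", size = c(96, 96)) {
  chars <- strsplit(text, "")[[1]]
  if (!all(chars %in% names(.GLYPHS)))
    stop("supported glyphs: ", paste(names(.GLYPHS), collapse = ", "),
         call. = FALSE)
  glyph_mats <- lapply(chars, function(ch) {
    rows <- .GLYPHS[[ch]]
    do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]]) == 1L))
  })
  # 1-column gap between glyphs
  gap <- matrix(FALSE, 7L, 1L)
  bitmap <- glyph_mats[[1]]
  for (g in glyph_mats[-1]) bitmap <- cbind(bitmap, gap, g)
  h <- size[1]; w <- size[2]
  scale <- floor(min(0.6 * h / nrow(bitmap), 0.8 * w / ncol(bitmap)))
  scale <- max(1L, scale)
  big <- bitmap[rep(seq_len(nrow(bitmap)), each = scale),
                rep(seq_len(ncol(bitmap)), each = scale), drop = FALSE]
  out <- matrix(FALSE, h, w)
  r0 <- floor((h - nrow(big)) / 2); c0 <- floor((w - ncol(big)) / 2)
  out[r0 + seq_len(nrow(big)), c0 + seq_len(ncol(big))] <- big
  out
}

# Bridson Poisson-disc sampling on [0, w) x [0, h) with minimum distance d.
#' @keywords internal
.poisson_disc <- function(h, w, d, k = 20L) {
  cell <- d / sqrt(2)
  gw <- ceiling(w / cell); gh <- ceiling(h / cell)
  grid <- matrix(0L, gh, gw)
  px <- numeric(0); py <- numeric(0)
  active <- integer(0)
  put <- function(x, y) {
    px <<- c(px, x); py <<- c(py, y)
    i <- length(px)
    grid[floor(y / cell) + 1L, floor(x / cell) + 1L] <<- i
    active <<- c(active, i)
    i
  }
  ok <- function(x, y) {
    if (x < 0 || y < 0 || x >= w || y >= h) return(FALSE)
    gc <- floor(x / cell) + 1L; gr <- floor(y / cell) + 1L
    for (rr in max(1L, gr - 2L):min(gh, gr + 2L))
      for (cc in max(1L, gc - 2L):min(gw, gc + 2L)) {
        j <- grid[rr, cc]
        if (j > 0L && (px[j] - x)^2 + (py[j] - y)^2 < d^2) return(FALSE)
      }
    TRUE
  }
  put(stats::runif(1, 0, w), stats::runif(1, 0, h))
  while (length(active)) {
    ai <- sample.int(length(active), 1L)
    i <- active[ai]
    placed <- FALSE
    for (trial in seq_len(k)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, d, 2 * d)
      x <- px[i] + rad * cos(ang); y <- py[i] + rad * sin(ang)
      if (ok(x, y)) { put(x, y); placed <- TRUE; break }
    }
    if (!placed) active <- active[-ai]
  }
  cbind(x = px, y = py)
}

#' Generate an Ishihara-like dot plate
#'
#' Seeded Poisson-disc dot layout on a neutral canvas; dots whose centers
#' fall inside the symbol mask draw from the foreground palette, others
#' from the background palette. With a red foreground on a green background
#' the symbol is legible to normal trichromats and collapses under
#' dichromat simulation.
#'
#' @param size (H, W) in pixels.
#' @param mask logical symbol mask (default [symbol_mask()] of "NO" at
#'   `size`).
#' @param fg_palette,bg_palette matrices of encoded RGB rows in [0,1];
#'   defaults: reds vs greens of matched lightness.
#' @param dot_radius_range (min, max) dot radius in pixels.
#' @param coverage target dotted fraction of the area, in (0, 1).
#' @param seed integer seed.
#' @return H x W x 3 encoded RGB array with attribute `symbol_mask`.
#' @export
make_plate <- function(size = c(96, 96), mask = NULL,
                       fg_palette = NULL, bg_palette = NULL,
                       dot_radius_range = c(2, 4), coverage = 0.45,
                       seed = 1L) {
  h <- as.integer(size[1]); w <- as.integer(size[2])
  if (is.null(mask)) mask <- symbol_mask("NO", c(h, w))
  if (!identical(dim(mask), c(h, w)))
    stop("mask dimensions must match size", call. = FALSE)
  if (coverage <= 0 || coverage >= 1)
    stop("coverage must be in (0, 1)", call. = FALSE)
  if (is.null(fg_palette))
    fg_palette <- rbind(c(0.80, 0.25, 0.20), c(0.87, 0.35, 0.25),
                        c(0.72, 0.20, 0.25))
  if (is.null(bg_palette))
    bg_palette <- rbind(c(0.35, 0.62, 0.25), c(0.45, 0.70, 0.30),
                        c(0.30, 0.55, 0.30))
  if (!NROW(fg_palette) || !NROW(bg_palette))
    stop("palettes must be nonempty", call. = FALSE)
  r_mean <- mean(dot_radius_range)
  # Bridson point density is ~0.65 points per d^2; solve d from coverage
  d <- sqrt(0.65 * pi * r_mean^2 / coverage)
  # when even the smallest dots are forced to overlap, the requested
  # coverage is unreachable with non-overlapping dots: reject
  if (d < 2 * dot_radius_range[1])
    stop("infeasible coverage/radius combination: requested coverage ",
         coverage, " needs dot spacing ", round(d, 2),
         " px, below twice the minimum radius", call. = FALSE)
  with_seed(seed, {
    centers <- .poisson_disc(h, w, d)
    canvas <- array(rep(c(0.93, 0.91, 0.86), each = h * w), c(h, w, 3L))
    for (i in seq_len(nrow(centers))) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      rad <- stats::runif(1, dot_radius_range[1], dot_radius_range[2])
      inside <- mask[floor(cy) + 1L, floor(cx) + 1L]
      pal <- if (inside) fg_palette else bg_palette
      col <- pal[sample.int(NROW(pal), 1L), ]
      rr <- max(1L, floor(cy - rad)):min(h, ceiling(cy + rad) + 1L)
      cc <- max(1L, floor(cx - rad)):min(w, ceiling(cx + rad) + 1L)
      for (ri in rr) for (ci in cc) {
        if ((ri - 1 - cy)^2 + (ci - 1 - cx)^2 <= rad^2)
          canvas[ri, ci, ] <- col
      }
    }
    attr(canvas, "symbol_mask") <- mask
    canvas
  })
}

#' Generate a textured red-on-green scene
#'
#' A saturated red disc on a saturated green ground: the standard
#' end-to-end enhancement fixture. The disc carries seeded *chromatic*
#' speckle along the chosen dichromat's confusion axis (the linear-RGB
#' direction annihilated by the cone projection), so a normal observer
#' sees rich texture there while the simulated dichromat sees an almost
#' uniform patch — exactly the saliency loss the enhancement pipeline
#' segments. The ground gets only a faint achromatic speckle. With
#' `chroma = 0` the same geometry renders achromatic (the
#' dichromat-invisible control).
#'
#' @param size (H, W) pixels.
#' @param seed integer seed.
#' @param deficiency confusion axis used for the disc texture.
#' @param disc_center (x, y) 0-based; default image center.
#' @param disc_radius pixels; default 15% of min(H, W).
#' @param chroma 0..1 scales saturation and chromatic texture
#'   (0 = grayscale control).
#' @param texture_amp chromatic dot amplitude in linear RGB
#'   (default 0.15).
#' @return H x W x 3 encoded RGB array with attribute `disc_mask` (logical
#'   matrix marking the disc).
#' @export
make_redgreen_scene <- function(size = c(96, 96), seed = 1L,
                                deficiency = "protan",
                                disc_center = NULL, disc_radius = NULL,
                                chroma = 1, texture_amp = 0.15) {
  h <- size[1]; w <- size[2]
  deficiency <- deficiency_type(deficiency)
  if (is.null(disc_center)) disc_center <- c((w - 1) / 2, (h - 1) / 2)
  if (is.null(disc_radius)) disc_radius <- 0.15 * min(h, w)
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  disc <- (xs - disc_center[1])^2 + (ys - disc_center[2])^2 <=
    disc_radius^2
  red <- c(0.75, 0.15, 0.12); green <- c(0.20, 0.60, 0.15)
  gray <- c(0.45, 0.45, 0.45)
  fg <- decode_gamma(chroma * red + (1 - chroma) * gray)
  bg <- decode_gamma(chroma * green + (1 - chroma) * gray)
  # linear-RGB direction the dichromat cannot see: the null space of the
  # cone-domain projection pulled back to RGB
  model <- build_dichromat_model(deficiency)
  missing_cone <- if (deficiency == "protan") c(1, 0, 0) else c(0, 1, 0)
  v <- drop(model$lms_to_rgb %*% missing_cone)
  v <- v / max(abs(v))
  with_seed(seed, {
    # chromatic dot field: Gaussian-profile blobs along the confusion
    # axis, jittered-grid centers inside the disc, alternating sign --
    # crisp DoG targets for a normal observer, invisible after projection.
    # blob sigma 2.8 px sits inside the detector's searched scale range
    # (the DoG pyramid starts at sigma 1.6; blobs below ~2.4 px peak on an
    # unsearched level and vanish)
    speck <- matrix(0, h, w)
    step <- 8
    blob_sigma <- 2.8
    sgn <- 1
    for (cy in seq(-disc_radius, disc_radius, by = step))
      for (cx in seq(-disc_radius, disc_radius, by = step)) {
        jx <- disc_center[1] + cx + stats::runif(1, -step / 4, step / 4)
        jy <- disc_center[2] + cy + stats::runif(1, -step / 4, step / 4)
        if ((jx - disc_center[1])^2 + (jy - disc_center[2])^2 >
            disc_radius^2) next
        sgn <- -sgn
        speck <- speck + sgn *
          exp(-((xs - jx)^2 + (ys - jy)^2) / (2 * blob_sigma^2))
      }
    # the ground stays flat: each saliency map is min-max normalized, so
    # structure shared by both observers on the ground would rescale the
    # simulated map against the original one and manufacture spurious
    # saliency "error" where nothing was lost -- a real limitation of
    # normalized-map differencing that this fixture deliberately avoids
    img <- array(0, c(h, w, 3L))
    for (c in 1:3) {
      lin <- ifelse(disc,
                    fg[c] + chroma * texture_amp * v[c] * speck,
                    bg[c])
      img[, , c] <- lin
    }
    img <- encode_gamma(clamp01(img))
    attr(img, "clipped") <- NULL
    attr(img, "disc_mask") <- disc
    img
  })
}
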