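# Raster I/O. PNG (8/16-bit) through the png package; NetPBM PGM/PPM
# (ASCII P2/P3 and binary P5/P6) in base R as the plain-text-friendly
# format for fixtures; JPEG through the jpeg package when installed.
# Integer samples are normalized by their max code value (255 or 65535) on
# read and quantized back on write.

#' Read a raster image
#'
#' Format chosen by extension: `.png`, `.pgm`/`.ppm`/`.pnm`, `.jpg`/`.jpeg`.
#' Grayscale inputs are replicated to three channels; an alpha channel is
#' dropped.
#'
#' @param path file path.
#' @return H x W x 3 numeric array in [0,1].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    pgm = , ppm = , pnm = read_pnm(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the jpeg package is required for JPEG input", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  if (is.matrix(px)) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 1L) px <- array(rep(px, 3L), c(dim(px)[1:2], 3L))
  px
}

#' Write a raster image
#'
#' @param pixels H x W x 3 array or H x W matrix in [0,1] (clipped).
#' @param path output path; extension selects the format (PNG, PGM/PPM
#'   ASCII, JPEG).
#' @param bits 8 or 16 (PNG/PNM only).
#' @return the path, invisibly.
#' @export
write_image <- function(pixels, path, bits = 8L) {
  px <- clamp01(pixels)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path, dpi = NULL),
    pgm = , ppm = , pnm = write_pnm(px, path, bits = bits),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the jpeg package is required for JPEG output", call. = FALSE)
      jpeg::writeJPEG(px, path, quality = 0.95)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Read a NetPBM image (P2/P3 ASCII, P5/P6 binary)
#'
#' @param path file path.
#' @return H x W matrix (PGM) or H x W x 3 array (PPM), values in [0,1].
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("not a supported PNM file (P2/P3/P5/P6): ", path, call. = FALSE)
  head_tokens <- character(0)
  # token scanner honoring '#' comments
  buf <- character(0)
  while (length(head_tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PNM header")
    if (ch == "#") {
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1L))
        if (c2 %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        head_tokens <- c(head_tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  dims <- as.integer(head_tokens[1:2])
  maxval <- as.integer(head_tokens[3])
  w <- dims[1]; h <- dims[2]
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = n, quiet = TRUE,
         comment.char = "#")
  } else if (maxval < 256L) {
    as.integer(readBin(con, "raw", n))
  } else {
    readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  }
  if (length(vals) != n) stop("truncated PNM pixel data", call. = FALSE)
  # PNM is row-major, channel-interleaved
  if (nch == 3L) {
    arr <- array(0, c(h, w, 3L))
    for (c in 1:3) arr[, , c] <- matrix(vals[seq(c, n, by = 3L)],
                                        h, w, byrow = TRUE)
    arr / maxval
  } else {
    matrix(vals, h, w, byrow = TRUE) / maxval
  }
}

#' Write a NetPBM image (ASCII P2/P3)
#'
#' ASCII output keeps fixtures text-only and diffable.
#'
#' @param pixels H x W matrix (writes PGM) or H x W x 3 array (PPM), in
#'   [0,1].
#' @param path output path.
#' @param bits 8 (maxval 255) or 16 (maxval 65535).
#' @return the path, invisibly.
#' @export
write_pnm <- function(pixels, path, bits = 8L) {
  maxval <- if (bits >= 16L) 65535L else 255L
  px <- round(clamp01(pixels) * maxval)
  is_color <- length(dim(px)) == 3L
  magic <- if (is_color) "P3" else "P2"
  if (is_color) {
    h <- dim(px)[1]; w <- dim(px)[2]
    inter <- matrix(aperm(px, c(3L, 2L, 1L)), nrow = 3L * w) # per-row interleave
    body <- apply(inter, 2L, paste, collapse = " ")
  } else {
    h <- nrow(px); w <- ncol(px)
    body <- apply(px, 1L, paste, collapse = " ")
  }
  writeLines(c(magic, paste(w, h), as.character(maxval), body), path)
  invisible(path)
}
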