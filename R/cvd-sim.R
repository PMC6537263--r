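# Dichromat (protan/deutan) simulation after Vienot, Brettel & Mollon
# (1999): linear RGB is taken to an LMS-like cone space, the missing cone's
# signal is replaced by a linear combination of the surviving two chosen so
# that the achromatic axis (and a blue-yellow hue axis) is preserved, and
# the result is mapped back to linear RGB. The replacement is a rank-2
# projection, hence idempotent: simulating an already-simulated image is a
# no-op up to 8-bit rounding.

# Vienot 1999 linear-RGB -> LMS transform (Smith-Pokorny style cone
# fundamentals folded with ITU-R BT.709 primaries).
.VIENOT_RGB_TO_LMS <- matrix(c(
  17.8824,   43.5161,  4.11935,
  3.45565,   27.1554,  3.86714,
  0.0299566, 0.184309, 1.46709), 3L, 3L, byrow = TRUE)

# Cone-space replacement rows: the missing channel as a combination of the
# surviving two (coefficients from the plane through white and 475/575 nm).
.VIENOT_PROJ <- list(
  protan = matrix(c(0, 2.02344, -2.52581,
                    0, 1,        0,
                    0, 0,        1), 3L, 3L, byrow = TRUE),
  deutan = matrix(c(1,        0, 0,
                    0.494207, 0, 1.24827,
                    0,        0, 1), 3L, 3L, byrow = TRUE))

#' Validate a dichromacy type
#'
#' The package models the two red-green dichromacies only. Tritanopia is
#' rejected: the method targets red-green chromatic contrast and the
#' blue-yellow axis is out of scope.
#'
#' @param deficiency `"protan"` or `"deutan"`.
#' @return the matched string.
#' @export
deficiency_type <- function(deficiency) {
  if (identical(deficiency, "tritan"))
    stop("tritan deficiency is not supported: the pipeline targets ",
         "red-green (protan/deutan) contrast only", call. = FALSE)
  match.arg(deficiency, c("protan", "deutan"))
}

#' Build the linear-RGB dichromat reduction model
#'
#' @param deficiency `"protan"` or `"deutan"`.
#' @return object of class `dichromat_model` with fields `rgb_to_lms`,
#'   `projection` (idempotent 3x3 cone-space matrix), `lms_to_rgb`, and the
#'   composed `full` linear-RGB matrix.
#' @export
#' @examples
#' m <- build_dichromat_model("protan")
#' max(abs(m$projection %*% m$projection - m$projection)) # idempotent
build_dichromat_model <- function(deficiency) {
  deficiency <- deficiency_type(deficiency)
  proj <- .VIENOT_PROJ[[deficiency]]
  lms_to_rgb <- solve(.VIENOT_RGB_TO_LMS)
  structure(list(
    deficiency = deficiency,
    rgb_to_lms = .VIENOT_RGB_TO_LMS,
    projection = proj,
    lms_to_rgb = lms_to_rgb,
    full = lms_to_rgb %*% proj %*% .VIENOT_RGB_TO_LMS
  ), class = "dichromat_model")
}

#' Simulate dichromatic perception of an encoded sRGB image
#'
#' Gamma-decodes, applies the dichromat reduction in linear RGB, clips to
#' gamut and re-encodes. Deterministic; output has the input's shape.
#'
#' @param pixels H x W x 3 encoded RGB array in [0,1].
#' @param deficiency `"protan"` or `"deutan"`.
#' @return encoded RGB array, the image as seen by the chosen dichromat.
#' @export
#' @examples
#' g <- array(0.5, c(2, 2, 3))
#' max(abs(simulate_dichromacy(g, "protan") - g)) < 1 / 255 # grays survive
simulate_dichromacy <- function(pixels, deficiency) {
  stopifnot_image(pixels)
  stopifnot_unit_range(pixels)
  model <- build_dichromat_model(deficiency)
  lin <- decode_gamma(pixels)
  out <- apply_matrix3(lin, model$full)
  enc <- encode_gamma(out)
  attr(enc, "clipped") <- NULL
  enc
}
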