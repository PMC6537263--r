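---
title: "Saliency-guided recoloring for red-green dichromats: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliency-guided recoloring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdenhance)
```

# The problem

A dichromat lacks one of the three cone classes. For protanopia (no
L-cones) and deuteranopia (no M-cones) the consequence is the same in kind:
color pairs that differ mainly along the red-green opponent axis become
metamers, and image regions whose structure is carried by that contrast
lose their visual salience. The package's premise is that *saliency*, not
raw color difference, is the right currency for deciding what to fix: a
region deserves recoloring when the deficiency destroys its ability to
attract gaze, which we estimate by comparing saliency maps of the image
and of its simulated dichromatic rendering.

# Color pipeline

All color math runs through CIE XYZ and CIE L\*a\*b\*.

* **Companding.** File pixels are IEC 61966-2-1 sRGB-encoded; the RGB-to-XYZ
  matrix is a linear-light operation, so values are gamma-decoded first
  (`v/12.92` below 0.04045, else `((v+0.055)/1.055)^2.4`) and re-encoded at
  the end. Without this step mid-tone Lab values are simply wrong.
* **Matrix construction.** The matrix is built from chromaticities: per
  primary, X = x/y, Y = 1, Z = (1-x-y)/y; the three columns are scaled by
  the solution of M0 S = white so that RGB (1,1,1) maps exactly onto the
  white point. The white point is D65 (0.95047, 1, 1.08883), sRGB's native
  white; the source material never names one.
* **CIE constants.** The Lab transfer function's junction constant and
  scale are kept as exact rationals, epsilon = 216/24389 and
  kappa = 24389/27, rather than the truncated 0.008856 / 903.3. With the
  rationals the two branches meet exactly at 6/29 and the branch-continuity
  test holds to 1e-9; with the truncated constants it does not.
* **Symbol overloading.** In colorimetry texts the symbol x_r denotes both
  the red primary's chromaticity and the white-relative ratio X/X_W inside
  the Lab transfer. These are distinct quantities here: chromaticities live
  in `colorspace_def()`, the ratios are unnamed intermediates of
  `xyz_to_lab()`.
* **Gamut handling.** The inverse path clips in *linear* RGB before
  encoding and reports the clip count as an attribute. Chroma negation can
  legitimately leave the sRGB gamut, so clipping is the contract, not an
  error. A 1e-9 tolerance keeps round-trip floating-point dust out of the
  count.

# Dichromat simulation

The Viénot-Brettel-Mollon (1999) linear-RGB reduction: an LMS transform
(Smith-Pokorny cone fundamentals folded with BT.709 primaries), a rank-2
replacement of the missing cone channel (protan:
L' = 2.02344 M - 2.52581 S; deutan: M' = 0.494207 L + 1.24827 S), and the
inverse transform. The replacement coefficients put the projection plane
through the achromatic axis, so grays are fixed points (verified on all 256
8-bit grays to under one code value) and the projection is exactly
idempotent. Anomalous trichromacy (severity-scaled) and tritanopia are out
of scope: the enhancement targets red-green contrast, and `"tritan"` is
rejected with an explicit message rather than extrapolated.

# Saliency

Saliency is the spatial density of multi-scale difference-of-Gaussians
keypoints, computed per Lab channel and averaged. The cited prior method is
SIFT-based; since its thresholds and octave layout are not published, this
package declares its own reproducible stand-in and exposes every knob:

* Channels are pre-scaled to a common order of magnitude (L\*/100, a\*/128,
  b\*/128) so one contrast threshold (default 0.01) means the same thing on
  all three. `detect_keypoints()` can instead min-max rescale a raw
  channel, its default for standalone use.
* The DoG pyramid starts at sigma 1.6 with factor sqrt(2), four DoG levels
  per octave, up to three octaves. Extrema must be strict over the 26
  neighbors in scale-space. **No edge-response rejection** is applied:
  region outlines are precisely the structure whose saliency matters here,
  the opposite of SIFT's matching use case. A practical consequence of the
  searched levels: blobs below roughly sigma 2.4 px peak on the unsearched
  first DoG level and are invisible to the detector.
* The density map is an exact Gaussian kernel sum over keypoint locations
  (verified against a brute-force loop to 1e-9), unweighted by detector
  response — "spatial distribution" is taken literally — with bandwidth
  defaulting to 5% of the image diagonal. Keypoint-free channels yield the
  all-zero map.

# Enhancement chain and its numerical choices

`enhance_image()` composes: simulate, dual saliency, error map
`|S_orig - S_sim|`, per-channel weighted Lab difference, inverse color
transform of that difference, correction-vector collapse, 3x3 smoothing,
Otsu segmentation, chroma negation.

Decisions a maintainer should know:

* **Signs.** The Lab difference keeps its sign until the collapse step,
  where channel *magnitudes* are averaged; only magnitudes are meaningful
  after averaging for segmentation.
* **The difference is not a color.** The weighted Lab difference is pushed
  through the algebraic inverse of the Lab-to-linear-RGB chain with no
  domain checks, no clipping and no companding (its L\* can be negative;
  magnitudes are taken immediately afterwards, so clipping would only
  destroy information).
* **Normalization conventions.** Min-max normalization maps constant
  rasters to zero everywhere *except* in the saliency error, where a
  constant absolute difference keeps its level (identical maps give all
  zeros; exactly complementary binary maps give all ones).
* **Correction vector** defaults to (1,1,1) — the neutral reading of an
  unspecified knob — and is configurable per run.
* **Smoothing kernel.** Only the 3x3 size is prescribed by the method;
  sigma is fixed at 0.85, making the kernel essentially the binomial
  [1 2 1] x [1 2 1] / 16. Padding is symmetric (edge-including), under
  which a unit-sum symmetric kernel conserves total mass exactly.
* **Otsu** is the global 256-bin between-class-variance maximizer on the
  smoothed map ("adaptive" is read as data-adaptive global thresholding,
  the simplest faithful reading of the citation); the threshold is the
  upper edge of the optimal low class, ties broken toward the first
  maximum, and a constant map yields an empty mask with a warning. A
  connected-component cleanup (`min_component_frac`) exists but defaults
  to off, keeping the faithful pipeline.
* **Recoloring acts on the original image's Lab**, not the simulated one:
  the enhanced image is displayed to the dichromat, so it is the true
  image whose chroma must move. Outside the mask, output pixels are copied
  from the input bit-for-bit (locality is exact, not approximate).

# Gaze and metrics

* Fixation points are the mean of the two eyes' coordinates; a one-eyed
  sample uses that eye, both-missing samples are dropped. Subpixel points
  round to the nearest pixel, ties to even.
* Excluding the first 200 ms (the center-biased onset of free viewing) is
  a first-class mode, as is keeping everything; both appear in analyses of
  eye-tracking data and the package takes no side.
* Count smoothing stamps a truncated, per-location renormalized Gaussian at
  each counted pixel, so total mass equals the retained sample count
  exactly even at map borders. The default sigma, 48 px, is one degree of
  visual angle for the reference geometry (70 cm viewing distance, 22-inch
  16:9 1920x1080 display); `visual_angle_px()` recomputes it for other
  setups.
* The gaze simulator emulates a 55 Hz tracker over 3 s (165 samples; the
  sample count is computed with an explicit fencepost formula because
  naive `seq()` arithmetic produces 166 at exactly this rate). Its center
  bias, hotspot mixture and jitter are all parameters; the nominal rate
  discrepancy in tracker folklore ("about 160 per 3 s" vs. 55 Hz = 165) is
  resolved by making rate a parameter, not a constant.
* NSS z-scores with the *population* standard deviation and averages over
  the fixation multiset; AUC is the exact rank (Mann-Whitney) computation
  with deduplicated fixation pixels as positives and every other pixel as
  a negative, ties counting one half. A zero-variance map is an error for
  NSS, not a silent zero.

# Synthetic fixtures: what they do and do not establish

`make_redgreen_scene()` renders a saturated red disc (radius 15% of the
short side) on a flat saturated green ground. The disc's texture is a
jittered grid of Gaussian blobs (sigma 2.8 px, just inside the detector's
searched scale range) displaced along the *confusion axis* of the chosen
deficiency — the linear-RGB direction annihilated by the cone projection,
computed as `lms_to_rgb %*% e_missing`. A normal observer's detector finds
rich structure there; the simulated dichromat sees an almost uniform
patch. This is the Ishihara plate principle turned into a pipeline
fixture, and it makes the expected outcome unambiguous: the saliency error
concentrates on the disc, the mask covers most of it, and recoloring flips
its a\* sign.

The ground is deliberately *flat*: each saliency map is min-max normalized
before differencing, so structure shared by both observers (visible
texture on the ground) rescales the simulated map against the original one
and manufactures spurious "error" where nothing was lost. That is a real
limitation of normalized-map differencing — scenes rich in
deficiency-independent texture will dilute and distort the segmentation —
and the fixture avoids it on purpose so that a green test certifies the
mechanism, not luck. Green tests on these fixtures therefore establish the
pipeline's internal correctness and its behavior under ideal red-green
contrast; they do not establish improvements for human observers on
natural images, which in the source study required eye-tracking sessions
and are explicitly outside this package's acceptance surface.

`make_plate()` builds Ishihara-like dot plates: Bridson Poisson-disc dot
centers (slight dot overlap is tolerated, as in printed plates; coverage
requiring spacing below twice the minimum radius is rejected as
infeasible), red foreground dots inside a dot-matrix symbol mask, green
background dots outside. Identical palettes make the symbol statistically
invisible — the generator's null case.

The end-to-end acceptance checks run at 96x96 px rather than
screen-resolution sizes to keep the suite inside its time budget; every
operation is resolution-independent and the saliency bandwidth scales with
the image diagonal.

# Known limitations

* The keypoint detector is a declared stand-in, not a reimplementation of
  the cited SIFT-density method; absolute saliency values are not
  comparable across detectors (the pluggable `detect_keypoints()` /
  `keypoint_density()` pair isolates the choice).
* Min-max-normalized map differencing is scale-blind (see above).
* The recolor map (chroma negation) is deficiency-independent; the source
  study itself notes it suits deuteranopia better than protanopia and
  leaves per-deficiency mappings as future work.
* Only dichromacy is modeled; anomalous trichromacy needs a severity
  parameter the projection model does not have.
* ICC profiles, chromatic adaptation and HDR transfer functions are out of
  scope; inputs are assumed sRGB.
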