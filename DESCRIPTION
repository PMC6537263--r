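Package: cvdenhance
Title: Saliency-Guided Image Enhancement for Dichromatic Observers
Version: 0.1.0
Authors@R:
    person("EToCVD", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates dichromatic (protan/deutan) color perception of sRGB
    images, detects where visual saliency is lost by the deficiency using
    keypoint-density saliency maps computed per CIE L*a*b* channel, segments
    the affected regions with Otsu thresholding of the saliency-weighted
    color difference, and recolors them by negating the a* and b* opponent
    channels so red-green content moves into the blue-yellow range that
    dichromats can discriminate. Also provides fixation-map construction
    from binocular eye-tracking logs, NSS and AUC saliency metrics,
    deterministic pseudoisochromatic plate and red-green scene generators,
    and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jpeg,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
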