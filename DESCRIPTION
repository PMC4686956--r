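Package: swiftag
Title: Semantic Wavelet-Induced Frequency-Tagging Stimuli and
    Frequency-Tagged BOLD Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for semantic wavelet-induced frequency-tagging (SWIFT)
    experiments. Generates cyclically wavelet-scrambled movie stimuli that
    reveal an image's semantic content periodically while conserving its
    principal low-level features (local luminance, local spatial frequency,
    global contrast) via isoenergetic circular paths in orientation space,
    composes alpha-blended multi-stream runs tagged at distinct temporal
    frequencies, and analyses frequency-tagged BOLD responses: spectral
    signal-to-noise ratios, per-voxel tagging statistics with false
    discovery rate control, phase maps, cycle-averaged time courses,
    block-design GLM contrasts, overlap percentages, hierarchy profiles and
    criterion-free ROC/AUC comparisons. Includes a synthetic-BOLD simulator
    with a canonical double-gamma hemodynamic response for end-to-end
    validation without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
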