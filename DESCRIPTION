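Package: bliq
Title: Trial-Averaged Analysis of Bioluminescence Imaging Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Stimulus-locked analysis of head-fixed mouse-brain bioluminescence
    imaging (BLI) video: dark subtraction, intensity-based head masking,
    substrate-decay correction by zero-phase Butterworth smoothing of the
    masked mean trace, trial epoching, per-trial baseline normalization to
    delta-L over L0, trial averaging and pseudocolor rendering; early
    (calcium) versus late (hemodynamic) response quantification by windowed
    area under the curve with Student's t comparisons; Michaelis-Menten and
    one-site binding fits for substrate titrations and calcium-indicator
    response curves; and a synthetic BLI video generator with EM-CCD noise
    and known ground truth so the whole chain is testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    signal,
    EBImage,
    tiff,
    jsonlite,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
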