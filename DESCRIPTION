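Package: cwtnet
Title: Channel-Wise Wavelet Correlation Networks for Multi-Channel EEG
    Classification with Grad-CAM Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transforms multi-channel resting-state EEG epochs into
    channel-wise continuous wavelet transform (CWT) correlation matrices
    (per-channel Gaussian-derivative scalograms, stacked channel-major and
    correlated row-wise with Pearson's r), classifies them with a compact
    convolutional neural network trained under class-weighted sparse
    categorical cross-entropy and stratified k-fold cross-validation with
    validation-fold checkpointing, and explains predictions by aggregating
    Grad-CAM saliency heatmaps into ranked EEG channel-pair attributions.
    Includes a synthetic multi-channel EEG generator that plants a shared
    band-limited oscillatory latent in a configurable channel pair per
    class, so the full classify-and-attribute pipeline can be exercised and
    validated end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
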