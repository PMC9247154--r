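Package: bonetomoqc
Title: Image Quality and Specimen Characterization for Bone Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image-quality and specimen-characterization pipeline for
    neutron and X-ray tomography of bone. Provides edge-sharpness estimation by
    fitting the Gaussian cumulative distribution to edge-spread profiles (FWHM and
    NRMSE), contrast-to-noise ratios between material phases, grey-value phase
    histograms with peak detection and peak-merging assessment, bone volume fraction
    (BV/TV) morphometry via median filtering and global thresholding, stress-strain
    analysis of trabecular bone compression tests (peak stress, elastic modulus,
    toughness, clear-peak inclusion rule), and drying/rehydration weight kinetics.
    Every stage is driven and validated by a synthetic phantom generator that
    emulates reconstructed tomographic volumes, compression curves, and weight
    time-series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    signal,
    stats,
    tibble,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
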