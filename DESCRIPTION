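Package: periomap
Title: Porosity-Weighted Diffusion Mapping for Tooth-in-Situ Organ Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts medium perfusion through the periodontium in ex vivo
    tooth-in-situ organ culture. Converts CT-like greyscale slices to per-pixel
    porosity by a two-endpoint linear calibration, computes porosity-weighted
    geodesic diffusion maps from multiple inlet points (junctional epithelium,
    inferior alveolar canal), quantizes them into 1 mm contour bands, flags
    slow-diffusion regions, and validates the map against a finite-difference
    tracer diffusion simulation (an in-silico ink test). Also provides tissue
    viability analytics (XTT per gram, glucose consumption per gram per day),
    histomorphometry summaries with ANOVA/Tukey group comparisons, a seeded
    synthetic phantom and assay-data generator, and the bioreactor
    chewing-cycle loading waveform.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    withr,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
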