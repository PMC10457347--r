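Package: scmsi
Title: Single-Cell MALDI Mass Spectrometry Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for single-cell lipidomics by MALDI mass spectrometry
    imaging (MSI). Reads and writes imzML imaging datasets with an optional
    trapped-ion-mobility (1/K0) sidecar, detects individual cells from pixel
    spectra by summed foreground/background channel thresholding and median
    filtering, extracts and averages per-cell spectra, builds ppm- and
    mobility-gated ion images, merges dual-polarity acquisition runs of the
    same cells via similarity-transform registration, annotates peaks against
    a lipid library by formula-derived monoisotopic mass, and provides a
    statistical layer (UMAP embedding, SVM/random-forest/MLP classification
    with confusion-matrix metrics, group comparison, ROI reproducibility).
    Includes a synthetic-scene generator with full ground truth so every
    stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    e1071,
    randomForest,
    nnet,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
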