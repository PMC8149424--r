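Package: enameloct
Title: Enamel Layer Analysis of Dental Optical Coherence Tomography Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tooth-enamel loss and abrasion from optical coherence
    tomography (OCT) B-scans and volumes. Implements depth-intensity profile
    analysis with per-A-scan surface flattening and dentinoenamel-junction
    thickness readout, a structural-connectivity pipeline (Laplacian-of-Gaussian
    filtering, Otsu binarization, connected components, morphological
    opening/closing, Sobel overlays) for total-enamel accounting and abrasion
    detection, intensity-based multilevel-Otsu layer segmentation with per-class
    connected structures, en-face slice extraction at a fixed depth below the
    detected surface, and group statistics (repeated-measures ANOVA with
    Bonferroni post-hoc tests and Kolmogorov-Smirnov normality checks) over
    treatment stages. Includes a synthetic layered-tooth phantom generator with
    ground truth so every pipeline stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    grid,
    ggplot2,
    igraph,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
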