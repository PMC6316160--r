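Package: sersuptake
Title: SERS Nanoprobe Characterization and Single-Cell Uptake Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for characterizing thiophenol-functionalized
    gold nanosphere SERS probes and quantifying their uptake in single cells from
    hyperspectral Raman maps. Includes statistical image analysis of particle
    micrographs (Otsu binarization, 8-connected labeling, roundness and Feret
    morphometrics, size-distribution FWHM), UV-Vis plasmonic quantification (LSPR
    peak detection, through-origin Beer-Lambert calibration, ageing stability,
    aggregation index), the geometric surface-packing model of the SERS
    enhancement factor, hyperspectral map processing (band intensity extraction,
    image reconstruction, cell-body sum-spectra, the I1078 uptake statistic and
    cell-line contrasts), and synthetic-data generators with known ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    EBImage,
    tiff,
    png,
    tools,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
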