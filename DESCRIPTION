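Package: ecdscan
Title: Eddy-Current Damping Stroke-Sensor Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward simulation and analysis tools for portable
    eddy-current-damping (ECD) transcranial sensing of hemorrhagic
    stroke.  Provides a lumped-element tank-circuit model of the sensor
    (equivalent parallel resistance under transformer coupling to a
    conductive target), a quasi-static Biot-Savart forward model that
    reduces voxelized conductivity scenes to reflected-impedance
    changes, generators for the benchtop cube-grid and phantom-head
    experiments, calibrated synthetic recordings, scan analysis
    (signal-to-noise ratios, conductivity heatmaps, lesion
    localization), a kernel-weighted k-nearest-neighbors classifier,
    and a nested cross-validation evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
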