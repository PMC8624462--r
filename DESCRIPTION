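Package: cephrr
Title: Repeatability and Reproducibility of 3D Cephalometric Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gauge repeatability and reproducibility (ISO 5725) analysis of
    three-dimensional craniofacial landmark annotations. Provides a
    33-landmark cephalometric catalog, readers and writers for landmark
    annotation files, construction of Frankfort Horizontal (FH) reference
    planes and subject coordinate frames, variance-component estimation of
    repeatability and reproducibility per landmark and axis with outlier
    screening and modified Bland-Altman statistics, reliability analysis of
    vertical measurements under the conventional and a foramen-based FH
    plane, plane-parallelism assessment, and a multi-operator landmarking
    simulator with known ground truth for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
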