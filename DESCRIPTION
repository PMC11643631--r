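Package: segclock
Title: Single-Cell Segmentation-Clock Dynamics: Simulation, Segmentation
    and Oscillation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of single-cell segmentation-clock dynamics in
    zebrafish presomitic mesoderm (PSM) cells. Provides an intrinsic-timer
    synthetic-data generator (slowing Her1 oscillations with rising
    amplitude that arrest after a drawn number of peaks, a coupled Mesp
    differentiation-marker onset, brightfield scenes with ground-truth
    masks, and embryo-like cell flows along a reference curve), a
    brightfield single-cell segmentation chain (CLAHE, guided filter,
    morphological gradient, Otsu threshold, central-blob selection and a
    morphological Chan-Vese active contour), oscillation peak and cycle
    analysis with sub-frame parabolic peak refinement, Mesp signal-onset
    calling, kymograph construction against a reference curve, and cohort
    statistics with condition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, TimeCourse, CellBiology, Visualization
RoxygenNote: 7.3.3
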