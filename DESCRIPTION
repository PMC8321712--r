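Package: petloop
Title: Dynamic FDG-PET Analysis of the Emotional-Control Loop
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semiquantitative analysis of dynamic 18F-FDG PET
    time-activity curves in the emotional-control loop (prefrontal cortex,
    striatum, hippocampus, thalamus): SUVmax extraction from 4D volumes,
    cerebellar standardization, peak/uptake-rate/washout-rate metrics, and
    pooled two-sample group comparison with qualitative dynamics labelling.
    Includes the image-analysis stages used for ROI delineation
    (intensity-hue-saturation plus shift-invariant multiscale fusion,
    context-aware saliency mapping, GrabCut graph-cut segmentation) and a
    synthetic phantom generator producing dynamic volumes, cohorts matching
    published group summaries, and colour scenes with ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    igraph,
    EBImage,
    RNifti,
    png,
    yaml,
    digest,
    stats,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
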