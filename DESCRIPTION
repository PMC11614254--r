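Package: ctseg
Title: Deep-Learning-Assisted Segmentation and Annotation of Abdominal CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless workflow for building pancreas (or other organ)
    segmentation datasets from abdominal computed tomography: reading DICOM
    series into calibrated Hounsfield-unit volumes, window/level conversion to
    16-bit PNG slice stores, a configurable residual-encoder U-Net/FPN
    segmentation network trained with Focal Tversky loss under patient-grouped
    cross-validation, segmentation (Dice) and slice-level detection evaluation,
    a deterministic CT phantom generator for fully offline testing, and a
    model-assisted annotation-session engine with timing and revision
    accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
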