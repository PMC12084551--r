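Package: mtkit
Title: Filament Polarity, Bundling, Binding and Dynamic-Instability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis toolkit for cytoskeletal filament experiments:
    reads RELION-style particle STAR files and traces per-filament
    microtubule polarity from Euler angles, detects bundled filament pairs
    and classifies them as parallel or antiparallel with wall-to-wall
    spacing statistics, quantifies co-sedimentation binding and bundling
    assays (single-site isotherm Kd fits, dose-response summaries),
    estimates oligomeric state from size-exclusion chromatography
    calibrations, and segments length-versus-time traces into growth,
    pause and shrinkage phases to compute dynamic-instability statistics
    (growth rate, catastrophe and rescue frequencies, pause times).
    Includes seeded synthetic-data generators with serialized ground
    truth for every pipeline stage and a small command-line front end.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
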