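Package: gaitmet
Title: Muscle-Tendon Mechanics and Metabolic Energetics of Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates muscle-tendon states over a gait cycle by solving the
    muscle redundancy problem with Hill-type muscle models and compliant
    tendons, under four levels of model individualization (generic, calibrated
    passive forces, personalized tendon stiffness, and EMG-informed controls).
    Computes per-muscle metabolic rate time series with six published metabolic
    energy models (with a non-negativity modification of the
    shortening/lengthening heat), aggregates energy use at the whole-body,
    muscle-group and gait-phase levels, and provides the statistical tools used
    to compare gait curves: repeated-measures correlation, one-dimensional
    permutation (sign-flip) paired tests, Wilcoxon signed-rank tests and
    curve agreement metrics. A built-in synthetic virtual subject generates
    gait trials, EMG envelopes and gas-exchange series with known ground truth
    so that every pipeline stage can be exercised and validated end to end.
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
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
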