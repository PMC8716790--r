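Package: cldbs
Title: Closed-Loop Deep Brain Stimulation Simulation and Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator and tuning toolkit for closed-loop
    (adaptive) deep brain stimulation as implemented on sense-enabled
    implants. Emulates the embedded detection pipeline: spectral band-power
    feature extraction from multichannel local field potentials, a linear
    discriminant classifier with feature normalization, a thresholded
    onset/termination/blanking state machine, and ramped stimulation whose
    artifacts feed back into sensing. Includes a synthetic data generator
    with symptom-state-dependent band power, diurnal symptom drift and the
    common artifact classes (stimulation transients, EKG, movement, open
    stimulation-circuit noise), plus programming heuristics: correlation
    based feature ranking, percentile threshold selection, control-parameter
    grid search, and wash-in/wash-out time-constant estimation.
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
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
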