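Package: lfpath
Title: Longitudinal LFP Spectral, Coupling, Fractal and Pathology Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for longitudinal mouse
    electrophysiology and volumetric pathology studies of combined
    amyloid and tau models. Provides motion-gated epoching of multi-channel
    local field potential recordings, Welch band-power estimation,
    phase-amplitude coupling by the Tort modulation index over a complex
    Morlet filter bank, Higuchi fractal dimension complexity scores,
    voxel-based regional pathology loads with plaque-colocalization
    splitting by binary dilation, and factorial linear mixed-model
    inference with likelihood-ratio interaction testing, predicted
    marginal means and Benjamini-Hochberg adjusted contrasts. A bundled
    synthetic-data generator produces every input the pipeline consumes
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    lme4,
    emmeans,
    jsonlite,
    yaml,
    readr,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    tiff,
    RNifti,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
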