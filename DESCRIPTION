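Package: encodetrf
Title: Temporal Receptive Field Encoding Models with Noise-Corrected
    Evaluation for Auditory Cortical Spiking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits time-lagged linear readouts (temporal receptive fields)
    from hierarchical audio features to binned multi-unit spiking activity,
    and evaluates them the way auditory encoding studies do: trial-to-trial
    reliability estimation with a circular-shift null, tuned and well-tuned
    unit selection, noise-ceiling correction of model-neuron correlations,
    an ERB-cochleagram STRF baseline, paired layer-wise model comparisons
    with false-discovery-rate control, and population analyses of layer
    preference (hierarchy) and prediction time scale (low-pass sweeps).
    Includes a synthetic-session generator with known ground truth for
    validating every step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
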