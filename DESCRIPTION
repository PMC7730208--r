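Package: fnirsselect
Title: Cortical Activity-Based Channel Selection for fNIRS Brain-Computer
    Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies cortically active channels in functional
    near-infrared spectroscopy (fNIRS) recordings for brain-computer
    interface (BCI) pipelines.  Implements a z-score channel-selection
    method based on the maximum raw cross-correlation between each
    channel's trial-averaged hemodynamic response and a desired response
    template (canonical two-gamma HRF convolved with the task boxcar),
    alongside two comparators: a robust-GLM t-statistic method and a
    task-versus-rest peak baseline-correction rule.  Includes modified
    Beer-Lambert law conversion between dual-wavelength absorbance and
    hemoglobin concentration changes, Butterworth band-pass and
    Savitzky-Golay preprocessing, trial epoching and averaging,
    spatio-temporal feature extraction with min-max normalization, Fisher
    linear discriminant analysis with leave-one-trial-out
    cross-validation, paired-test method comparison with Bonferroni
    correction, and a seeded synthetic-recording simulator with known
    ground-truth active channels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
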