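Package: swdclass
Title: EEG-Based Classification of Behavioral Impairment During Spike-Wave Discharges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies individual spike-wave discharges (SWDs) in absence
    epilepsy as behaviorally spared or impaired from scalp EEG alone.
    Implements preictal/ictal window extraction, time- and frequency-domain
    features (Hjorth parameters, band powers, multiscale permutation
    entropy), common spatial pattern (CSP) filtering, Wilcoxon rank-sum
    feature selection, linear discriminant and support vector machine
    scoring, weighted probabilistic Bayesian fusion of preictal and ictal
    scores, and conservative threshold calibration targeting perfect spared
    predictive value (zero false-spared). Includes a synthetic EEG cohort
    generator, EDF input/output, stratified cross-validation over the full
    model grid, patient-level aggregation, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    signal,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
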