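Package: ecgaudit
Title: Transparency and Robustness Auditing of 12-Lead ECG Deep Learning Classifiers
Version: 0.1.0
Authors@R:
    person("ECG Audit", "Maintainers", email = "maintainer@ecgaudit.org",
           role = c("aut", "cre"))
Description: A model-agnostic audit toolkit for 12-lead ECG classifiers that
    screen for left ventricular systolic dysfunction (LVSD). Provides a
    physically consistent synthetic 12-lead ECG cohort generator built on a
    dipole/electrode-potential model, a small trainable 1-D residual network
    surrogate exposing per-block activations, concept-based attribution
    (testing with concept activation vectors, TCAV) with repeated-run
    confidence intervals, phenotype discovery by K-means clustering of hidden
    features with elbow selection and t-SNE embedding, limb lead-reversal
    simulation via electrode-potential reconstruction (24 cable placements
    collapsing to 12 morphology classes), six ECG noise models, and diagnostic
    performance statistics (AUROC with DeLong or bootstrap confidence
    intervals, AUPRC, operating-point metrics with Wilson intervals,
    fixed-sensitivity thresholding, Pearson correlation, subgroup tables).
    A pipeline command runs the full audit end-to-end with seeded, bitwise
    reproducible outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
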