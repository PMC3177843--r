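Package: gazecue
Title: Gaze-Cueing Interference Analysis with Split-Plot ANOVA and Bootstrap Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for analysing gaze-following (gaze-cueing) experiments in
    which the task-irrelevant gaze of a model face interferes with observers'
    instructed saccades. Provides saccade detection on horizontal gaze traces
    with amplitude and latency trial filters, per-observer-by-model
    interference indices for accuracy and saccadic reaction time, Big-Five
    adjective-profile similarity and emotion-positivity scores, a split-plot
    (mixed between/within) ANOVA with partial eta-squared, a bootstrap F-null
    alternative to the parametric test, Duncan's multiple range post-hoc test,
    percentile-bootstrap confidence intervals for means and Pearson
    correlations, and a fully seeded synthetic-experiment generator that
    emulates the two-group, four-model design for power and calibration
    studies. An end-to-end pipeline assembles these stages into a structured,
    reproducible analysis report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
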