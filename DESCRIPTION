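Package: shapetrace
Title: Validation of Markerless Fingertip Tracking Against Touchscreen Shape-Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the agreement between fingertip trajectories
    predicted by a markerless video tracker and reference trajectories recorded
    by a touchscreen during a shape-tracing task. Provides a synthetic trial
    generator (closed five-segment stimulus shapes, frame-rate and speed
    conditions, a tracker degradation model), trajectory preprocessing
    (cubic-spline resampling to a fixed point count, per-axis min-max
    normalization, dynamic time warping), closed-form two-dimensional
    Procrustes superimposition with the root-mean-squared-error agreement
    statistic, and the accompanying statistical analyses: one-sample t tests,
    TOST equivalence testing, Hedges g with noncentral-t confidence intervals,
    and Welch pairwise frame-rate contrasts with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
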