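Package: cheeseCT
Title: Quantifying Eye Formation in Semi-Hard Cheese from X-Ray CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A non-destructive morphometry pipeline for volumetric X-ray
    computed tomography (CT) scans of semi-hard cheese wheels. Converts CT
    numbers to density, segments the wheel from background air by density
    thresholding, identifies gas-filled cavities (eyes, cracks and splits) as
    3D connected components, and computes per-cavity volume, surface area and
    sphericity together with per-wheel summary metrics (eye count, eye volume
    percentiles, eye-to-wheel volume ratio and eye percentage). Wheel
    summaries from ripening-stage cohorts are compared by one-way ANOVA with
    Tukey post-hoc letters. A synthetic cheese-wheel phantom generator with
    analytic ground truth validates every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
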