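Package: normreach
Title: Individually Scaled Evaluation of Upper-Limb Reaching After Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits individually scaled movement-time models to planar
    center-out reaching trajectories and scores affected-arm performance
    against the less-affected arm. Implements a normal-reaching power-law
    model in target distance and average speed, two comparator models
    (Fitts' law and a simplified submovement/curvature power law),
    log-space regression with AIC and R-squared model discrimination,
    kinematic feature extraction (movement time, average speed, curvature
    index, minimum-jerk submovement decomposition), curvature-based
    outlier rejection, a normalized-error deficit index with polar
    workspace maps, and a seeded synthetic session generator for testing
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
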