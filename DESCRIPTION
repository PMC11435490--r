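Package: trunkgait
Title: Trunk Acceleration-Derived Gait Indexes from a Single Lumbar
    Inertial Sensor
Version: 0.1.0
Authors@R:
    person("trunkgait", "developers", email = "trunkgait@example.org",
           role = c("aut", "cre"))
Description: Detects gait events from tri-axial trunk acceleration recorded
    by a single lumbar-mounted inertial measurement unit and computes the
    standard trunk acceleration-derived gait indexes: harmonic ratios
    (gait symmetry), the short-term largest Lyapunov exponent via delay
    embedding and Rosenstein's algorithm (local dynamic stability), the
    log-dimensionless jerk of accelerations (smoothness), and temporal
    symmetry indexes of the paretic versus non-paretic side. Includes a
    synthetic trace and cohort generator with analytic ground truth, a
    rank-based statistical layer (Kruskal-Wallis with Dunn/Holm post hocs,
    eta-squared effect sizes, and a nonparametric two-way repeated-measures
    ANOVA-type analysis), and a command-line pipeline for reproducible
    end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
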