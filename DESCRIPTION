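Package: rootkin
Title: Kinematic and Behavioural Analysis of 3D Root-Tip Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-stamped three-dimensional root-tip
    trajectories from plants grown alone or next to a neighbour. Extracts
    kinematic and oscillatory features (step kinematics, segmentation angles,
    growth rates, circumnutation amplitude and period, spectral entropy via
    Welch power spectral density, curvature, total variation of curvature,
    tortuosity), discriminates individual from social growth with
    cross-validated linear classifiers and coefficient-based feature
    importance, classifies primary-root behaviour as neutral, avoidant or
    aggregative from hourly displacement rules, and tests directional growth
    statistics (signed global growth angles, Shapiro-Wilk normality,
    chi-squared association with Yates' continuity correction). Includes a
    seeded synthetic trajectory generator emulating helical circumnutation
    about a growing axis so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
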