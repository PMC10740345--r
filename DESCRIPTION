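Package: siteFidelity
Title: Site Fidelity of Satellite-Tracked and Mark-Resighted Migratory Shorebirds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying site fidelity of migratory
    shorebirds from Argos satellite telemetry and colour-band resighting data.
    Provides quality control of Argos fixes (class retention plus a hybrid
    speed/redundant-distance filter), an optional random-walk state-space
    smoother that uses Argos error-ellipse information, stopover-site
    identification by complete-linkage clustering with silhouette model
    selection and containment/merge/duration rules, tracking- and
    resighting-based fidelity metrics for the non-breeding and migration
    periods, exact two-sided Fisher tests and fractional (quasi-binomial)
    logit regression for species comparisons, and a telemetry/resighting
    simulator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
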