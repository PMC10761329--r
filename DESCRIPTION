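Package: actidelta
Title: Event-Locked Actigraphy Analysis of Cluster-Headache Attacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for event-locked analysis of wrist-worn accelerometry
    around cluster-headache attacks. Computes the absolute activity index
    (a windowed-variance movement statistic) from raw tri-axial
    acceleration, detects off-body periods, applies daytime/data-ratio
    eligibility rules, constructs matched non-attack comparison intervals
    on same-type days, and tests per-attack percentile differences with
    paired Wilcoxon signed-rank tests under Bonferroni correction. Includes
    a synthetic-recording generator with latent activity states, embedded
    attack effects, streaming gaps and off-body segments, so the full
    pipeline can be exercised and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
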