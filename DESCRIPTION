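Package: kbplanr
Title: Knowledge-Based VMAT Plan Quality Scoring and DVH Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for knowledge-based volumetric modulated arc therapy
    (VMAT) planning research on pelvic (cervical cancer) cases:
    dose-volume histogram (DVH) representation and dose metrics,
    conformity and homogeneity indices, a 100-point plan quality metric,
    a trainable geometry-to-DVH prediction model based on principal
    component regression with estimate bands, a closed-loop model
    evolution procedure with self-checking admission of new plans, a
    rank-based model comparison score, and a synthetic pelvic plan
    cohort generator so the whole pipeline is exercisable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
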