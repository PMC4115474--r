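Package: rehabplan
Title: Adaptive Therapy Planning for Cognitive Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic planning of computerized cognitive
    rehabilitation for acquired-brain-injury patients. Normalizes
    neuropsychological assessments into 0-4 impairment profiles over an
    11-subfunction taxonomy, stratifies patients with a seeded
    expectation-maximization Gaussian mixture (automatic component
    selection by cross-validated held-out likelihood), rates a task
    catalog per patient by usage, improvement and clinical criteria
    combined into a global suitability score, assembles one-hour therapy
    sessions from suitability quartiles, adapts task difficulty from
    impairment and running performance, and simulates closed-loop
    treatment with a latent-ability logistic response model to compare
    planner variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
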