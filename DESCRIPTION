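Package: cytoimmune
Title: Multi-Modal Immune Profiling for Pediatric Lupus Cytometry and Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a multi-modal immune-profiling
    pipeline for childhood-onset systemic lupus erythematosus (cSLE) cohorts:
    hierarchical gating of mass-cytometry (CyTOF) event data with arcsinh
    transformation, anchor-referenced cytokine positivity scoring,
    housekeeping-normalized gene-module and type I interferon (IFN-1)
    signature scores, compositional analysis of cell-type abundances with a
    kernel distance-covariance association test and logistic mixed-model
    follow-up, repeated-measures differential correlation of cell features
    against disease-activity metrics, rule-based clinical state classifiers
    (LLDAS, renal response), and a convolutional multiple-instance learner
    with top-k pooling that discovers disease-associated cell signatures.
    A seed-deterministic synthetic-cohort generator emulates the study design
    so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
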