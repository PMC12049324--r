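Package: uacrcea
Title: Cost-Effectiveness of Urine Albumin Testing for Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus six-state Markov cohort model for evaluating
    urine albumin-to-creatinine ratio (UACR) testing against urine
    protein-creatinine ratio (UPCR) testing and against no urine testing in a
    non-diabetic population screened for chronic kidney disease. Health states
    follow the KDIGO prognosis heatmap (low, moderate, high and very high CKD
    risk, end-stage kidney disease, death). The package bundles a fully
    transcribed Japanese parameter set (re-test classification tables, KDIGO
    transition adjustment factors, mortality and cardiovascular hazard ratios,
    unit costs, resource use, utilities), computes discounted costs, life
    years, QALYs, dialysis initiations and cardiovascular events per 1000
    persons, and reports pairwise incremental cost-effectiveness ratios with
    subgroup, treatment-scenario and one-way deterministic sensitivity
    analyses. Includes seed-deterministic generators for a parametric
    (Gompertz-Makeham) life table and for synthetic re-test classification
    data used in validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
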