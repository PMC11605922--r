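Package: proteocost
Title: Micro-Costing of Mass Spectrometry Based Proteomics Diagnostic Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bottom-up (micro-costing) model of the per-patient cost of a
    mass-spectrometry-based quantitative proteomics diagnostic test, as used
    in the work-up of mitochondrial and other rare disorders. Resource items
    (consumables, equipment, labor) are allocated across the laboratory
    workflow stages via per-batch, per-sample, per-patient and annual-fixed
    bases; equipment acquisition costs are annuitized with an equivalent
    annual cost at a configurable discount rate; overheads are added as a
    percentage supplement. Parameter uncertainty is propagated with a gamma
    method-of-moments probabilistic sensitivity analysis, and deterministic
    one-way, two-way and throughput-scenario sensitivity analyses are
    provided, together with a synthetic workbook generator calibrated to
    published stage-by-category cost totals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
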