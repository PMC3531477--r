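Package: cenherit
Title: Quantification and Transgenerational Modeling of Centromeric
    CenH3 Inheritance
Version: 0.1.0
Authors@R:
    person("cenherit", "developers", email = "cenherit@example.org",
           role = c("aut", "cre"))
Description: Tools for studying quantitative inheritance of the
    centromere-specific histone CenH3 (Cid/CENP-A) through the Drosophila
    male germline. Provides a seeded synthetic microscopy scene generator
    (sperm, S5 spermatocytes, embryo metaphase fields) with ground truth,
    local-background-corrected centromeric spot quantification with
    within-cell, control-mean and ploidy normalizations, chromosome
    assignment from DNA-staining landmarks, a deterministic recursion for
    sex-specific germline loading of centromeric CenH3 across generations,
    closed-form dilution and ploidy arithmetic for early embryogenesis,
    and a pipeline that ties the stages together reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
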