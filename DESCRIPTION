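Package: chemomir
Title: Chemoresistance MicroRNA Discovery and Target Nomination from
    Matched Tumour Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying chemoresistance-associated
    microRNAs from matched pre- and post-chemotherapy qPCR arrays
    (global-mean normalized delta-delta Ct with detection-limit imputation,
    consistency and magnitude filtering), nominating their mRNA targets by
    combining biotin-mimic pulldown RNA-seq enrichment with multi-algorithm
    binding-site prediction consensus, quantifying chemoresponse from MTT
    and clonogenic assays (double normalization, paired one-tailed tests,
    interpolated IC estimates), and evaluating candidate targets as
    expression-dichotomized Kaplan-Meier survival markers with log-rank
    testing in treatment and receptor subgroups. Includes seeded synthetic
    data generators emulating each input so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
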