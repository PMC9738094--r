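Package: brcaness
Title: Pan-Cancer BRCAness Feature Scoring from Multi-Omics Cohort Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes BRCAness (homologous-recombination deficiency
    driven by non-BRCA1/2 genes) across cancer types from cohort-style
    multi-omics tables. Implements six per-cancer-type features --
    somatic and germline pathogenic-variant carrier frequency, homozygous
    deletion frequency, promoter methylation load, tumor-vs-normal
    differential expression, and prognostic gene counts -- and combines
    them into a composite score normalized against breast and ovarian
    reference cohorts to rank cancer types as PARP-inhibitor therapy
    candidates. Includes a seeded synthetic-cohort generator with planted
    signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
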