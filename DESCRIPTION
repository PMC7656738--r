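Package: mmlot
Title: Lines of Therapy, Attrition, and Comorbidity Profiling from
    Administrative Claims in Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs lines of therapy (LOT) from longitudinal drug-claim
    streams for newly diagnosed multiple myeloma using gap and new-agent
    rules, annotates transplant phases (induction, consolidation), applies
    study inclusion criteria, scores Charlson comorbidity and named
    cardiovascular/renal/hepatic comorbidity flags over configurable
    look-back windows, and summarises per-line attrition and disposition
    with treatment-duration statistics. Includes a seeded synthetic
    claims-data generator emulating the statistical structure of US
    administrative claims sources, group-comparison and logistic models of
    receipt of subsequent treatment, publication-style table rendering with
    CMS-style small-cell suppression, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
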