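Package: glycorank
Title: Glycomics-Guided Glycoproteomics Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for glycomics-guided glycoproteomics
    biomarker discovery in bladder cancer. Annotates and quantifies
    permethylated benzyl O-glycan mass spectra from elemental-formula mass
    calculus, matches glycopeptide spectra with b/y/c/z fragment ions and
    oxonium-ion diagnostics, localizes O-glycosites from site-determining
    EThcD ions, curates and ranks candidate glycoproteins with a 0-15
    target score combining tumour over-expression, healthy-tissue absence,
    membrane localization and immune/gamete penalties, and associates
    immunohistochemistry phenotypes with patient survival (Kaplan-Meier,
    log-rank, Cox proportional hazards with Efron ties). Seeded synthetic
    generators emulate every input with planted ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
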