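Package: mirgenet
Title: miRNA-mRNA Regulatory Network Inference and Liquid-Biopsy
    Biomarker Triage from Paired Tumor-Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates paired tumor/normal miRNA and mRNA expression
    profiles into candidate regulatory networks and liquid-biopsy
    biomarker signatures. Provides reads-per-million normalization,
    per-patient log2 fold changes, a paired differential-expression
    test with Benjamini-Hochberg adjustment, Pearson correlation of
    patient-level fold changes with a strict negative-correlation
    filter, confirmation of candidate miRNA-gene pairs against an
    interaction catalogue, bipartite miRNA-to-mRNA network assembly
    with GraphML export, and a biomarker triage cascade that bins
    body-fluid detection levels and flags circulating, exosomal and
    bronchoalveolar-lavage markers. A negative-binomial cohort
    simulator with planted repressive couplings supports end-to-end
    validation without external data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
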