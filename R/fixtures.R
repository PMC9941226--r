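# Accessors for the packaged lung-cancer tables (transcribed published
# results used as desk-scale fixtures and worked examples).

mirgenet_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mirgenet")
  if (path == "") abort(sprintf("packaged file not found: %s", file))
  path
}

#' Packaged lung-cancer reference tables
#'
#' Small TSV tables shipped with the package, transcribed from a published
#' two-cohort (LUAD and lSCC) miRNA-mRNA integration study of paired
#' tumor/normal samples:
#'
#' * `lung_network_pairs()` - the confirmed miRNA-target pairs that form the
#'   per-cancer regulatory networks (`cancer_type`, `mirna_id`, `gene_id`).
#' * `lung_cohort_evidence()` - large-cohort significance verdicts per miRNA
#'   and cancer type (`mirna_id`, `cancer_type`, `significant`).
#' * `lung_fluid_detection()` - detection symbols per miRNA in plasma,
#'   serum, exosomes and bronchoalveolar lavage (`mirna_id`, `fluid`,
#'   `symbol`). The published run-together symbol strings were segmented
#'   into per-fluid symbols consistently with the published biomarker flags.
#' * `lung_fluid_rpm_synthetic()` - a synthetic numeric-RPM variant of the
#'   fluid table (`mirna_id`, `fluid`, `rpm`); the RPM values are invented
#'   but bin to the published symbols via [detection_symbol()].
#' * `lung_signature_expected()` - the published 11-miRNA liquid-biopsy
#'   signature (`mirna_id`, `tumor`, `c_biomarker`, `e_biomarker`,
#'   `l_biomarker`), used to check the end-to-end cascade.
#'
#' @return A tibble.
#' @name lung_fixtures
NULL

#' @rdname lung_fixtures
#' @export
lung_network_pairs <- function() {
  readr::read_tsv(mirgenet_extdata("lung_network_pairs.tsv"), col_types = "ccc")
}

#' @rdname lung_fixtures
#' @export
lung_cohort_evidence <- function() {
  readr::read_tsv(mirgenet_extdata("lung_cohort_evidence.tsv"), col_types = "ccl")
}

#' @rdname lung_fixtures
#' @export
lung_fluid_detection <- function() {
  readr::read_tsv(mirgenet_extdata("lung_fluid_detection.tsv"), col_types = "ccc")
}

#' @rdname lung_fixtures
#' @export
lung_fluid_rpm_synthetic <- function() {
  readr::read_tsv(mirgenet_extdata("lung_fluid_rpm_synthetic.tsv"), col_types = "ccd")
}

#' @rdname lung_fixtures
#' @export
lung_signature_expected <- function() {
  readr::read_tsv(mirgenet_extdata("lung_signature_expected.tsv"), col_types = "cclll")
}
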