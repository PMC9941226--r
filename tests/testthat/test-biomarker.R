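candidates_from_fixture <- function() {
  lung_network_pairs() |>
    dplyr::distinct(mirna_id, cancer_type)
}

test_that("cohort filter reproduces the published candidate reductions", {
  cand <- candidates_from_fixture()
  retained <- cohort_filter(cand, lung_cohort_evidence())
  luad <- dplyr::filter(retained, cancer_type == "LUAD")
  lscc <- dplyr::filter(retained, cancer_type == "lSCC")
  # 4 LUAD candidates minus miR-149-5p; 15 lSCC minus miR-1246 and miR-448
  expect_equal(nrow(luad), 3)
  expect_false("hsa-miR-149-5p" %in% luad$mirna_id)
  expect_equal(nrow(lscc), 13)
  expect_false(any(c("hsa-miR-1246", "hsa-miR-448") %in% lscc$mirna_id))
})

test_that("cohort filter retains everything when all evidence is positive", {
  cand <- candidates_from_fixture()
  all_yes <- dplyr::mutate(lung_cohort_evidence(), significant = TRUE) |>
    dplyr::bind_rows(tibble::tibble(
      mirna_id = "hsa-miR-149-5p", cancer_type = "lSCC", significant = TRUE
    ))
  # ensure every candidate has a row to avoid the missing-evidence warning
  retained <- suppressWarnings(cohort_filter(cand, all_yes))
  expect_equal(nrow(retained), nrow(cand))
})

test_that("missing cohort evidence keeps the candidate with a warning", {
  cand <- tibble::tibble(mirna_id = c("hsa-miR-1", "hsa-miR-2"),
                         cancer_type = "LUAD")
  ev <- tibble::tibble(mirna_id = "hsa-miR-1", cancer_type = "LUAD",
                       significant = FALSE)
  expect_warning(out <- cohort_filter(cand, ev), "hsa-miR-2")
  expect_equal(out$mirna_id, "hsa-miR-2")
})

test_that("detection symbols partition the RPM axis with the published bins", {
  expect_equal(as.character(detection_symbol(c(0, 5, 9.99))), rep("-", 3))
  expect_equal(as.character(detection_symbol(c(10, 50, 100))), rep("+", 3))
  expect_equal(as.character(detection_symbol(c(100.5, 500, 1000))), rep("++", 3))
  expect_equal(as.character(detection_symbol(c(1000.1, 5000, 1e7))), rep("+++", 3))
  expect_error(detection_symbol(-1), ">= 0")
  expect_error(detection_symbol(NA_real_), "non-missing")

  # total, monotone, gap-free on a fine grid
  grid <- c(seq(0, 2000, by = 0.25), 10^seq(3.5, 8, by = 0.25))
  sym <- detection_symbol(grid)
  expect_false(anyNA(sym))
  expect_true(all(diff(as.integer(sym)) >= 0))
  expect_setequal(levels(sym), c("-", "+", "++", "+++"))
})

test_that("parse_detection_symbol accepts the printed symbol alphabet", {
  sym <- parse_detection_symbol(c("-", "+", "++", "+++", "−"))
  expect_equal(as.integer(sym), c(1, 2, 3, 4, 1))
  expect_true(sym[4] > sym[1])
  expect_error(parse_detection_symbol("++++"), "unknown detection symbol")
})

test_that("classification flags follow the per-fluid detection profile", {
  cand <- tibble::tibble(
    mirna_id = c("hsa-miR-182-5p", "hsa-miR-369-3p", "hsa-miR-137"),
    cancer_type = "lSCC"
  )
  calls <- classify_biomarkers(cand, lung_fluid_detection())
  r182 <- dplyr::filter(calls, mirna_id == "hsa-miR-182-5p")
  expect_true(r182$c_biomarker && r182$e_biomarker && r182$l_biomarker)
  r369 <- dplyr::filter(calls, mirna_id == "hsa-miR-369-3p")
  expect_false(r369$liquid_eligible)
  expect_true(r369$l_biomarker)
  r137 <- dplyr::filter(calls, mirna_id == "hsa-miR-137")
  expect_true(r137$c_biomarker)
  expect_false(r137$e_biomarker || r137$l_biomarker)
})

test_that("a miRNA absent from the fluid table counts as undetected everywhere", {
  cand <- tibble::tibble(mirna_id = "hsa-miR-none", cancer_type = "LUAD")
  calls <- classify_biomarkers(cand, lung_fluid_detection())
  expect_false(any(calls$c_biomarker, calls$e_biomarker, calls$l_biomarker))
  expect_false(calls$liquid_eligible)
})

test_that("liquid eligibility is exactly circulating-or-exosomal over random profiles", {
  set.seed(21)
  syms <- c("-", "+", "++", "+++")
  for (i in 1:30) {
    fl <- tidyr::expand_grid(
      mirna_id = paste0("m", 1:10),
      fluid = c("plasma", "serum", "exosomes", "bronchoalveolar")
    ) |>
      dplyr::mutate(symbol = sample(syms, 40, replace = TRUE))
    cand <- tibble::tibble(mirna_id = paste0("m", 1:10), cancer_type = "X")
    calls <- classify_biomarkers(cand, fl)
    expect_equal(calls$liquid_eligible, calls$c_biomarker | calls$e_biomarker)
  }
})

test_that("numeric RPM fluid tables bin to the same calls as the symbol table", {
  cand <- candidates_from_fixture() |> dplyr::distinct(mirna_id, cancer_type)
  from_symbols <- classify_biomarkers(cand, lung_fluid_detection())
  from_rpm <- classify_biomarkers(cand, lung_fluid_rpm_synthetic())
  common <- intersect(from_symbols$mirna_id, from_rpm$mirna_id)
  expect_equal(
    dplyr::arrange(dplyr::filter(from_symbols, mirna_id %in% common), mirna_id, cancer_type),
    dplyr::arrange(dplyr::filter(from_rpm, mirna_id %in% common), mirna_id, cancer_type)
  )
})

test_that("the end-to-end cascade reproduces the published 11-miRNA signature", {
  cand <- candidates_from_fixture()
  evidence <- lung_cohort_evidence()
  retained <- cohort_filter(cand, evidence)
  calls <- classify_biomarkers(retained, lung_fluid_detection())
  # 9 of the 13 lSCC candidates are detectable in plasma, serum or exosomes
  expect_equal(sum(calls$liquid_eligible[calls$cancer_type == "lSCC"]), 9)
  signature <- build_signature(calls, evidence)
  expect_equal(nrow(signature), 11)
  expect_equal(as.data.frame(signature), as.data.frame(lung_signature_expected()))
})

test_that("signature assembly merges tumor labels and ignores ineligible calls", {
  calls <- tibble::tibble(
    mirna_id = c("mB", "mB", "mA", "mC"),
    cancer_type = c("LUAD", "lSCC", "LUAD", "lSCC"),
    c_biomarker = c(TRUE, TRUE, TRUE, FALSE),
    e_biomarker = FALSE,
    l_biomarker = c(TRUE, FALSE, FALSE, TRUE),
    liquid_eligible = c(TRUE, TRUE, TRUE, FALSE)
  )
  sig <- build_signature(calls)
  expect_equal(sig$mirna_id, c("mA", "mB")) # lexicographic, mC ineligible
  expect_equal(sig$tumor[sig$mirna_id == "mB"], "LUAD/lSCC")
  expect_true(sig$l_biomarker[sig$mirna_id == "mB"]) # any() across cancers

  # adding an ineligible call never changes the signature
  more <- dplyr::bind_rows(calls, tibble::tibble(
    mirna_id = "mZ", cancer_type = "LUAD", c_biomarker = FALSE,
    e_biomarker = FALSE, l_biomarker = TRUE, liquid_eligible = FALSE
  ))
  expect_equal(build_signature(more), sig)

  expect_equal(nrow(build_signature(calls[calls$mirna_id == "mC", ])), 0)
})

test_that("tumor secretion flag is a strict comparison", {
  expect_true(tumor_secretion_flag(1000, 10))
  expect_false(tumor_secretion_flag(5, 5))
  expect_false(tumor_secretion_flag(0, 3))
  expect_equal(tumor_secretion_flag(c(2, 3), c(3, 2)), c(FALSE, TRUE))
  expect_error(tumor_secretion_flag(-1, 0), ">= 0")
})
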