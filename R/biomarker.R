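#' Filter candidate miRNAs by large-cohort evidence
#'
#' Keeps a candidate miRNA for a cancer type only when an independent
#' large-cohort evidence table marks its tumor-vs-healthy expression change
#' significant there. Candidates with no evidence row are retained with a
#' warning (absence of evidence is not treated as evidence of absence).
#'
#' @param candidates A tibble with columns `mirna_id`, `cancer_type`.
#' @param evidence A tibble with columns `mirna_id`, `cancer_type`,
#'   `significant` (logical).
#' @return The retained rows of `candidates`.
#' @export
cohort_filter <- function(candidates, evidence) {
  check_columns(candidates, c("mirna_id", "cancer_type"), "`candidates`")
  check_columns(evidence, c("mirna_id", "cancer_type", "significant"), "`evidence`")
  if (anyDuplicated(evidence[, c("mirna_id", "cancer_type")])) {
    abort("`evidence` has duplicated (mirna_id, cancer_type) rows")
  }
  joined <- candidates |>
    distinct(.data$mirna_id, .data$cancer_type) |>
    left_join(evidence, by = c("mirna_id", "cancer_type"))
  missing <- filter(joined, is.na(.data$significant))
  if (nrow(missing) > 0) {
    warn(sprintf(
      "no cohort evidence for %s; retained",
      paste(sprintf("%s (%s)", missing$mirna_id, missing$cancer_type), collapse = ", ")
    ))
  }
  joined |>
    filter(is.na(.data$significant) | .data$significant) |>
    select("mirna_id", "cancer_type")
}

detection_levels <- c("-", "+", "++", "+++")

#' Bin a body-fluid RPM level into a detection symbol
#'
#' The published binning: below 10 RPM undetected (`-`), 10-100 RPM `+`,
#' above 100 up to 1000 RPM `++`, above 1000 RPM `+++`. Boundaries fall to
#' the lower symbol so the bins partition `[0, Inf)` with no gaps.
#'
#' @param rpm Non-negative RPM level(s).
#' @return An ordered factor with levels `- < + < ++ < +++`.
#' @export
detection_symbol <- function(rpm) {
  if (!is.numeric(rpm) || anyNA(rpm)) abort("`rpm` must be numeric and non-missing")
  if (any(rpm < 0)) abort("`rpm` must be >= 0")
  cut(rpm,
      breaks = c(-Inf, 10, 100, 1000, Inf),
      labels = detection_levels,
      right = FALSE, include.lowest = TRUE,
      ordered_result = TRUE
  ) |>
    (\(x) {
      # cut() with right = FALSE puts exactly 10 into "+" (correct) but also
      # 100 into "++" and 1000 into "+++"; the published bins close 100 and
      # 1000 on the lower class.
      x[rpm == 100] <- "+"
      x[rpm == 1000] <- "++"
      x
    })()
}

#' Parse printed detection symbols
#'
#' @param x Character symbols among `-`, `+`, `++`, `+++` (unicode minus
#'   accepted).
#' @return An ordered factor with levels `- < + < ++ < +++`.
#' @export
parse_detection_symbol <- function(x) {
  x <- stringr::str_replace_all(stringr::str_trim(x), "[−–—]", "-")
  bad <- setdiff(unique(x), detection_levels)
  if (length(bad) > 0) {
    abort(sprintf("unknown detection symbol(s): %s", paste(bad, collapse = ", ")))
  }
  factor(x, levels = detection_levels, ordered = TRUE)
}

fluid_names <- c("plasma", "serum", "exosomes", "bronchoalveolar")

# Normalise a long fluid table (mirna_id, fluid, symbol|rpm) to symbols,
# filling absent fluids with "-".
fluid_profiles <- function(fluids) {
  check_columns(fluids, c("mirna_id", "fluid"), "`fluids`")
  bad <- setdiff(unique(fluids$fluid), fluid_names)
  if (length(bad) > 0) {
    abort(sprintf("unknown fluid(s): %s (expected %s)",
                  paste(bad, collapse = ", "), paste(fluid_names, collapse = ", ")))
  }
  if (anyDuplicated(fluids[, c("mirna_id", "fluid")])) {
    abort("`fluids` has duplicated (mirna_id, fluid) rows")
  }
  if ("symbol" %in% names(fluids)) {
    fluids <- mutate(fluids, symbol = parse_detection_symbol(.data$symbol))
  } else if ("rpm" %in% names(fluids)) {
    fluids <- mutate(fluids, symbol = detection_symbol(.data$rpm))
  } else {
    abort("`fluids` needs a `symbol` or `rpm` column")
  }
  fluids |>
    select("mirna_id", "fluid", "symbol") |>
    tidyr::complete(
      mirna_id = unique(fluids$mirna_id),
      fluid = fluid_names,
      fill = list(symbol = factor("-", levels = detection_levels, ordered = TRUE))
    )
}

#' Classify candidate miRNAs into liquid-biopsy biomarker categories
#'
#' Maps each candidate's per-fluid detection profile to the three biomarker
#' flags: `c_biomarker` (circulating: detected in plasma or serum),
#' `e_biomarker` (detected in exosomes), `l_biomarker` (detected in
#' bronchoalveolar lavage). A miRNA is `liquid_eligible` when it is a
#' circulating or exosomal biomarker; bronchoalveolar lavage alone does not
#' qualify because the sampling is invasive. Fluids absent from the table
#' count as undetected.
#'
#' @param candidates A tibble with columns `mirna_id`, `cancer_type`
#'   (typically the output of [cohort_filter()]).
#' @param fluids A long tibble `mirna_id`, `fluid`, and either `symbol`
#'   (`-`/`+`/`++`/`+++`) or numeric `rpm` binned via [detection_symbol()].
#'   Fluids are `plasma`, `serum`, `exosomes`, `bronchoalveolar`.
#' @return A tibble with one row per candidate row: `mirna_id`,
#'   `cancer_type`, the three logical flags and `liquid_eligible`.
#' @export
classify_biomarkers <- function(candidates, fluids) {
  check_columns(candidates, c("mirna_id", "cancer_type"), "`candidates`")
  prof <- fluid_profiles(fluids) |>
    tidyr::pivot_wider(names_from = "fluid", values_from = "symbol")
  missing_fluid <- setdiff(candidates$mirna_id, prof$mirna_id)
  if (length(missing_fluid) > 0) {
    prof <- bind_rows(prof, tibble(
      mirna_id = missing_fluid,
      plasma = factor("-", levels = detection_levels, ordered = TRUE),
      serum = factor("-", levels = detection_levels, ordered = TRUE),
      exosomes = factor("-", levels = detection_levels, ordered = TRUE),
      bronchoalveolar = factor("-", levels = detection_levels, ordered = TRUE)
    ))
  }
  candidates |>
    distinct(.data$mirna_id, .data$cancer_type) |>
    left_join(prof, by = "mirna_id") |>
    mutate(
      c_biomarker = .data$plasma > "-" | .data$serum > "-",
      e_biomarker = .data$exosomes > "-",
      l_biomarker = .data$bronchoalveolar > "-",
      liquid_eligible = .data$c_biomarker | .data$e_biomarker
    ) |>
    select("mirna_id", "cancer_type", "c_biomarker", "e_biomarker",
           "l_biomarker", "liquid_eligible")
}

#' Assemble the final biomarker signature
#'
#' One row per distinct liquid-eligible miRNA, with its tumor label merged
#' across cancers (e.g. `"LUAD/lSCC"`) and rows in lexicographic order. When
#' a cohort-evidence table is supplied the tumor label is the set of cancers
#' where the large cohort marks the miRNA significant; otherwise it is the
#' set of cancers where the miRNA was a candidate.
#'
#' @param calls Output of [classify_biomarkers()].
#' @param evidence Optional cohort-evidence tibble (`mirna_id`,
#'   `cancer_type`, `significant`) used to derive the tumor labels.
#' @return A tibble `mirna_id`, `tumor`, `c_biomarker`, `e_biomarker`,
#'   `l_biomarker`.
#' @export
build_signature <- function(calls, evidence = NULL) {
  check_columns(calls, c("mirna_id", "cancer_type", "c_biomarker",
                         "e_biomarker", "l_biomarker", "liquid_eligible"),
                "`calls`")
  eligible <- filter(calls, .data$liquid_eligible)
  if (nrow(eligible) == 0) {
    return(tibble(mirna_id = character(), tumor = character(),
                  c_biomarker = logical(), e_biomarker = logical(),
                  l_biomarker = logical()))
  }
  labels <- if (is.null(evidence)) {
    eligible |>
      group_by(.data$mirna_id) |>
      summarise(tumor = paste(sort_c(unique(.data$cancer_type)), collapse = "/"),
                .groups = "drop")
  } else {
    check_columns(evidence, c("mirna_id", "cancer_type", "significant"), "`evidence`")
    evidence |>
      filter(.data$significant, .data$mirna_id %in% eligible$mirna_id) |>
      group_by(.data$mirna_id) |>
      summarise(tumor = paste(sort_c(unique(.data$cancer_type)), collapse = "/"),
                .groups = "drop")
  }
  eligible |>
    group_by(.data$mirna_id) |>
    summarise(
      c_biomarker = any(.data$c_biomarker),
      e_biomarker = any(.data$e_biomarker),
      l_biomarker = any(.data$l_biomarker),
      .groups = "drop"
    ) |>
    left_join(labels, by = "mirna_id") |>
    mutate(tumor = dplyr::coalesce(.data$tumor, "")) |>
    select("mirna_id", "tumor", "c_biomarker", "e_biomarker", "l_biomarker") |>
    arrange_c("mirna_id")
}

#' Tumor-secretion comparison for exosomal miRNAs
#'
#' Flags a miRNA as tumor-secreted when its exosomal level from tumor tissue
#' strictly exceeds the level from healthy tissue. The two quantities are
#' user-supplied RPM values.
#'
#' @param exo_tumor_rpm,exo_healthy_rpm Non-negative RPM levels (vectorised).
#' @return Logical vector.
#' @export
tumor_secretion_flag <- function(exo_tumor_rpm, exo_healthy_rpm) {
  if (any(exo_tumor_rpm < 0, na.rm = TRUE) || any(exo_healthy_rpm < 0, na.rm = TRUE)) {
    abort("RPM levels must be >= 0")
  }
  exo_tumor_rpm > exo_healthy_rpm
}

#' Plot a per-fluid detection profile
#'
#' Tile map of detection symbols per miRNA and fluid.
#'
#' @param fluids A long fluid tibble (`mirna_id`, `fluid`, `symbol` or `rpm`).
#' @return A ggplot object.
#' @export
plot_fluid_profile <- function(fluids) {
  prof <- fluid_profiles(fluids)
  ggplot2::ggplot(prof, ggplot2::aes(
    x = factor(.data$fluid, levels = fluid_names),
    y = .data$mirna_id, fill = .data$symbol
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = as.character(.data$symbol)), size = 3) +
    ggplot2::scale_fill_brewer(palette = "Blues", drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "detection") +
    ggplot2::theme_minimal()
}
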