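#' Reads-per-million normalization
#'
#' Scales each sample (column) of a count-unit expression set so its values
#' sum to one million, the standard small-RNA RPM normalization.
#'
#' @param expr A `paired_expr` tibble in `counts` unit.
#' @return The same expression set with `unit = "rpm"`.
#' @export
rpm_normalize <- function(expr) {
  if (!inherits(expr, "paired_expr")) abort("`expr` must be a paired_expr object")
  if (expr_unit(expr) != "counts") {
    abort(sprintf("rpm_normalize() expects unit 'counts', got '%s'", expr_unit(expr)))
  }
  totals <- expr |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$value), .groups = "drop")
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero) > 0) {
    abort(sprintf("sample(s) with zero library size: %s", paste(zero, collapse = ", ")))
  }
  out <- expr |>
    left_join(totals, by = "sample_id") |>
    mutate(value = .data$value / .data$total * 1e6) |>
    select(-"total")
  new_paired_expr(out, assay = expr_assay(expr), unit = "rpm")
}

# Patients having both a tumor and a normal sample.
complete_patients <- function(expr) {
  expr_samples(expr) |>
    group_by(.data$patient_id) |>
    summarise(ok = all(c("tumor", "normal") %in% .data$condition), .groups = "drop") |>
    filter(.data$ok) |>
    pull("patient_id")
}

#' Per-patient log2 fold changes
#'
#' For every feature and every patient with both a tumor and a normal sample,
#' computes `log2((rpm_tumor + pseudocount) / (rpm_normal + pseudocount))`.
#' Patients lacking either sample are dropped with a message.
#'
#' @param expr A `paired_expr` tibble in `rpm` unit.
#' @param pseudocount Non-negative RPM offset applied to both numerator and
#'   denominator; the default 1 RPM keeps zero observations finite.
#' @return A tibble with columns `feature_id`, `patient_id`, `log2fc`,
#'   ordered by feature then patient (identical patient order for every
#'   feature).
#' @export
patient_log2fc <- function(expr, pseudocount = 1) {
  if (!inherits(expr, "paired_expr")) abort("`expr` must be a paired_expr object")
  if (expr_unit(expr) != "rpm") {
    abort("patient_log2fc() expects RPM values; run rpm_normalize() first")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    abort("`pseudocount` must be a single number >= 0")
  }
  patients <- complete_patients(expr)
  all_patients <- unique(expr$patient_id)
  dropped <- setdiff(all_patients, patients)
  if (length(dropped) > 0) {
    inform(sprintf("dropping %d patient(s) without a complete tumor/normal pair: %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  if (length(patients) == 0) {
    abort("no patient has a complete tumor/normal sample pair")
  }
  wide <- expr |>
    filter(.data$patient_id %in% patients) |>
    select("feature_id", "patient_id", "condition", "value") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  if (pseudocount == 0 && any(wide$tumor == 0 | wide$normal == 0)) {
    abort("zero RPM encountered with pseudocount = 0; supply a positive pseudocount")
  }
  wide |>
    mutate(log2fc = log2((.data$tumor + pseudocount) / (.data$normal + pseudocount))) |>
    select("feature_id", "patient_id", "log2fc") |>
    arrange(.data$feature_id, .data$patient_id)
}

# Long fold-change tibble -> features x patients matrix.
fc_matrix <- function(fc) {
  check_columns(fc, c("feature_id", "patient_id", "log2fc"), "fold-change table")
  wide <- fc |>
    tidyr::pivot_wider(names_from = "patient_id", values_from = "log2fc")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$feature_id
  m
}

#' Paired differential expression on per-patient fold changes
#'
#' A defined stand-in for an external negative-binomial DE caller: the
#' cohort-level log2 fold change is the mean of the per-patient log2 fold
#' changes, the p-value comes from a two-sided paired (one-sample) t-test of
#' those values against zero, and multiplicity is adjusted by
#' Benjamini-Hochberg across all features of the assay. Externally produced
#' DE tables can be supplied instead through [import_de_table()].
#'
#' Features whose per-patient fold changes are all identical and non-zero
#' have no within-feature variance; their p-value is set to 0 (with a note)
#' rather than propagating NaN. Identical and zero gives p = 1.
#'
#' @inheritParams patient_log2fc
#' @return A tibble with columns `feature_id`, `log2fc`, `p`, `p_adj`,
#'   `direction` (`"up"` iff `log2fc > 0`).
#' @export
differential_expression <- function(expr, pseudocount = 1) {
  fc <- patient_log2fc(expr, pseudocount = pseudocount)
  m <- fc_matrix(fc)
  n <- ncol(m)
  if (n < 3) {
    abort(sprintf("differential expression needs >= 3 complete patient pairs, got %d", n))
  }
  means <- rowMeans(m)
  sds <- apply(m, 1, stats::sd)
  tstat <- means / (sds / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  degen <- sds == 0
  if (any(degen)) {
    p[degen] <- ifelse(means[degen] == 0, 1, 0)
    if (any(degen & means != 0)) {
      inform(sprintf(
        "%d feature(s) with zero variance and non-zero shift; p set to 0",
        sum(degen & means != 0)
      ))
    }
  }
  tibble(
    feature_id = rownames(m),
    log2fc = unname(means),
    p = unname(p),
    p_adj = p.adjust(p, method = "BH"),
    direction = if_else(means > 0, "up", "down")
  )
}

#' Apply the differential-expression thresholds
#'
#' Retains features with `p_adj < alpha` and linear fold change
#' `|FC| > min_abs_fc` (equivalently `|log2fc| > log2(min_abs_fc)`); both
#' inequalities are strict.
#'
#' @param records A DE tibble as returned by [differential_expression()] or
#'   [import_de_table()].
#' @param alpha Adjusted-probability cutoff (default 0.05).
#' @param min_abs_fc Linear fold-change cutoff, must be > 1 (default 2).
#' @return The retained rows, a tibble partitioned by the `direction` column;
#'   see [de_feature_sets()] for the up/down id sets.
#' @export
filter_de <- function(records, alpha = 0.05, min_abs_fc = 2) {
  check_columns(records, c("feature_id", "log2fc", "p_adj"), "DE table")
  if (!is.numeric(min_abs_fc) || min_abs_fc <= 1) {
    abort("`min_abs_fc` must be > 1 (a linear fold-change ratio)")
  }
  filter(records, .data$p_adj < alpha, abs(.data$log2fc) > log2(min_abs_fc))
}

#' @rdname filter_de
#' @return `de_feature_sets()` returns `list(up = , down = )` of feature ids.
#' @export
de_feature_sets <- function(records, alpha = 0.05, min_abs_fc = 2) {
  kept <- filter_de(records, alpha = alpha, min_abs_fc = min_abs_fc)
  list(
    up = kept$feature_id[kept$log2fc > 0],
    down = kept$feature_id[kept$log2fc < 0]
  )
}

#' Import an externally produced differential-expression table
#'
#' Reads a TSV with columns `feature_id`, `log2fc`, `p`, `p_adj` (for
#' example, exported from a negative-binomial DE caller) and validates it
#' row by row; malformed rows are reported with their line numbers.
#'
#' @param path Path to the TSV file.
#' @return A validated DE tibble with a computed `direction` column.
#' @export
import_de_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, c("feature_id", "log2fc", "p", "p_adj"), basename(path))
  if (nrow(raw) == 0) {
    warn(sprintf("%s contains no data rows", basename(path)))
    return(tibble(
      feature_id = character(), log2fc = double(), p = double(),
      p_adj = double(), direction = character()
    ))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  parsed <- raw |>
    mutate(
      line = row_number() + 1L, # header is line 1
      log2fc = num(.data$log2fc), p = num(.data$p), p_adj = num(.data$p_adj)
    )
  bad <- parsed |>
    filter(
      is.na(.data$log2fc) | is.na(.data$p) | is.na(.data$p_adj) |
        .data$p < 0 | .data$p > 1 | .data$p_adj < 0 | .data$p_adj > 1 |
        .data$p_adj < .data$p |
        is.na(.data$feature_id) | .data$feature_id == ""
    )
  if (nrow(bad) > 0) {
    abort(sprintf(
      "invalid DE row(s) at line(s) %s of %s (non-numeric value, probability outside [0,1], or p_adj < p)",
      paste(bad$line, collapse = ", "), basename(path)
    ))
  }
  parsed |>
    mutate(direction = if_else(.data$log2fc > 0, "up", "down")) |>
    select("feature_id", "log2fc", "p", "p_adj", "direction")
}

#' Write a differential-expression table
#'
#' @param records A DE tibble.
#' @param path Output TSV path.
#' @return `records`, invisibly.
#' @export
write_de_table <- function(records, path) {
  check_columns(records, c("feature_id", "log2fc", "p", "p_adj", "direction"), "DE table")
  readr::write_tsv(select(records, "feature_id", "log2fc", "p", "p_adj", "direction"), path)
  invisible(records)
}
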