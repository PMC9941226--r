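#' Build a paired tumor/normal expression set
#'
#' Combines a features-by-samples value table with a sample sheet into the
#' long, tidy container used throughout the package. Each patient contributes
#' at most one tumor and one normal sample; values are non-negative counts or
#' reads-per-million (RPM).
#'
#' @param values A data frame whose first column is `feature_id` and whose
#'   remaining columns are numeric, one per sample (column name = sample id).
#' @param samples A data frame with columns `sample_id`, `patient_id` and
#'   `condition` (`"tumor"` or `"normal"`). Every value column must appear
#'   here exactly once.
#' @param assay `"mirna"` or `"mrna"`.
#' @param unit `"counts"` or `"rpm"`.
#'
#' @return A tibble of class `paired_expr` with columns `feature_id`,
#'   `sample_id`, `patient_id`, `condition`, `value`, carrying `assay` and
#'   `unit` as attributes (see [expr_assay()], [expr_unit()]).
#' @seealso [rpm_normalize()], [patient_log2fc()], [differential_expression()]
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   feature_id = c("hsa-miR-21-5p", "hsa-miR-1-3p"),
#'   s1 = c(90, 10), s2 = c(50, 50)
#' )
#' samples <- tibble::tibble(
#'   sample_id = c("s1", "s2"),
#'   patient_id = c("p1", "p1"),
#'   condition = c("tumor", "normal")
#' )
#' paired_expression_set(counts, samples, assay = "mirna")
paired_expression_set <- function(values, samples,
                                  assay = c("mirna", "mrna"),
                                  unit = c("counts", "rpm")) {
  assay <- match.arg(assay)
  unit <- match.arg(unit)
  values <- as_tibble(values)
  samples <- as_tibble(samples)
  check_columns(values, "feature_id", "`values`")
  check_columns(samples, c("sample_id", "patient_id", "condition"), "`samples`")

  if (anyDuplicated(values$feature_id)) {
    abort(sprintf(
      "duplicated feature_id in `values`: %s",
      paste(unique(values$feature_id[duplicated(values$feature_id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicated sample_id in `samples`")
  }
  bad_cond <- setdiff(unique(samples$condition), c("tumor", "normal"))
  if (length(bad_cond) > 0) {
    abort(sprintf("condition must be 'tumor' or 'normal'; found: %s",
                  paste(bad_cond, collapse = ", ")))
  }
  dup_pc <- samples |>
    dplyr::count(.data$patient_id, .data$condition) |>
    filter(n > 1)
  if (nrow(dup_pc) > 0) {
    abort(sprintf(
      "patient(s) with more than one sample per condition: %s",
      paste(unique(dup_pc$patient_id), collapse = ", ")
    ))
  }

  sample_cols <- setdiff(names(values), "feature_id")
  if (!setequal(sample_cols, samples$sample_id)) {
    abort("value columns and sample sheet sample_ids do not match")
  }
  long <- values |>
    tidyr::pivot_longer(all_of(sample_cols),
                        names_to = "sample_id", values_to = "value") |>
    left_join(samples, by = "sample_id") |>
    select("feature_id", "sample_id", "patient_id", "condition", "value")
  if (!is.numeric(long$value) || anyNA(long$value) || any(long$value < 0)) {
    abort("expression values must be non-negative, non-missing numbers")
  }
  new_paired_expr(long, assay = assay, unit = unit)
}

new_paired_expr <- function(long, assay, unit) {
  out <- as_tibble(long)
  attr(out, "assay") <- assay
  attr(out, "unit") <- unit
  class(out) <- c("paired_expr", class(tibble()))
  out
}

#' Assay and unit of an expression set
#' @param expr A `paired_expr` object.
#' @return A string: the assay (`"mirna"`/`"mrna"`) or unit (`"counts"`/`"rpm"`).
#' @export
expr_assay <- function(expr) attr(expr, "assay")

#' @rdname expr_assay
#' @export
expr_unit <- function(expr) attr(expr, "unit")

# Features x samples numeric matrix view.
expr_matrix <- function(expr) {
  wide <- expr |>
    select("feature_id", "sample_id", "value") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$feature_id
  m
}

expr_samples <- function(expr) {
  expr |>
    select("sample_id", "patient_id", "condition") |>
    distinct()
}

#' Read an expression set from TSV files
#'
#' Expects the interchange format also written by [write_expression()]: a
#' counts table whose first column is `feature_id` with one numeric column per
#' sample, and a sample sheet with columns `sample_id`, `patient_id`,
#' `condition` (and optionally `assay`).
#'
#' @param counts_path,samples_path Paths to the two TSV files.
#' @inheritParams paired_expression_set
#' @return A `paired_expr` tibble.
#' @export
read_expression <- function(counts_path, samples_path,
                            assay = c("mirna", "mrna"),
                            unit = c("counts", "rpm")) {
  values <- readr::read_tsv(counts_path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  if ("assay" %in% names(samples)) {
    assay <- match.arg(assay)
    samples <- filter(samples, .data$assay == !!assay) |> select(-"assay")
    values <- select(values, all_of(c("feature_id", samples$sample_id)))
  }
  paired_expression_set(values, samples, assay = assay, unit = unit)
}

#' Write an expression set to TSV files
#'
#' @param expr A `paired_expr` object.
#' @param counts_path,samples_path Output paths.
#' @return `expr`, invisibly.
#' @export
write_expression <- function(expr, counts_path, samples_path) {
  wide <- expr |>
    select("feature_id", "sample_id", "value") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  readr::write_tsv(wide, counts_path)
  sheet <- expr_samples(expr) |>
    mutate(assay = expr_assay(expr))
  readr::write_tsv(sheet, samples_path)
  invisible(expr)
}

#' @export
print.paired_expr <- function(x, ...) {
  cat(sprintf(
    "# paired_expr: %s [%s], %d features x %d samples (%d patients)\n",
    expr_assay(x), expr_unit(x),
    dplyr::n_distinct(x$feature_id), dplyr::n_distinct(x$sample_id),
    dplyr::n_distinct(x$patient_id)
  ))
  NextMethod()
}
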