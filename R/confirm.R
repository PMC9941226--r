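#' Load a miRNA-target interaction catalogue
#'
#' Reads a TSV with columns `mirna_id`, `gene_id`, `evidence`
#' (`"experimental"` or `"predicted"`), the local stand-in for curated
#' interaction databases. Exact duplicates are dropped with a warning; the
#' same pair may appear under both evidence classes.
#'
#' @param path Path to the TSV file.
#' @return A tibble of interaction records.
#' @export
load_interactions <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, c("mirna_id", "gene_id", "evidence"), basename(path))
  bad <- setdiff(unique(raw$evidence), c("experimental", "predicted"))
  if (length(bad) > 0) {
    abort(sprintf("unknown evidence label(s) in %s: %s",
                  basename(path), paste(bad, collapse = ", ")))
  }
  if (any(raw$mirna_id == "" | raw$gene_id == "", na.rm = TRUE) ||
      anyNA(raw$mirna_id) || anyNA(raw$gene_id)) {
    abort(sprintf("empty identifiers in %s", basename(path)))
  }
  dedup <- distinct(raw, .data$mirna_id, .data$gene_id, .data$evidence)
  if (nrow(dedup) < nrow(raw)) {
    warn(sprintf("%d duplicated interaction row(s) removed", nrow(raw) - nrow(dedup)))
  }
  dedup
}

#' Confirm selected pairs against an interaction catalogue
#'
#' A selected miRNA-gene pair is confirmed when the same `(mirna_id,
#' gene_id)` combination appears in the catalogue under either evidence
#' class. Identifiers are canonicalised before matching (whitespace trimmed,
#' unicode dashes unified); matching is otherwise exact and case-sensitive.
#'
#' @param selected A tibble of selected correlation pairs (needs `mirna_id`,
#'   `gene_id`; other columns are carried through).
#' @param catalogue An interaction tibble as from [load_interactions()].
#' @return An object of class `pair_confirmation`: use [tidy()] for the
#'   confirmed pairs (with a collapsed `evidence` column) and [glance()] for
#'   the one-row report (`n_selected`, `n_confirmed`, `pct_confirmed`,
#'   `n_unique_mirna`, `n_unique_gene`). `pct_confirmed` is the percentage
#'   rounded half away from zero to one decimal, `NA` when nothing was
#'   selected.
#' @export
confirm_pairs <- function(selected, catalogue) {
  check_columns(selected, c("mirna_id", "gene_id"), "`selected`")
  check_columns(catalogue, c("mirna_id", "gene_id", "evidence"), "`catalogue`")
  selected <- selected |>
    select(-dplyr::any_of("evidence")) |> # re-confirmation stays idempotent
    mutate(mirna_id = normalize_id(.data$mirna_id),
           gene_id = normalize_id(.data$gene_id))
  cat_norm <- catalogue |>
    mutate(mirna_id = normalize_id(.data$mirna_id),
           gene_id = normalize_id(.data$gene_id)) |>
    group_by(.data$mirna_id, .data$gene_id) |>
    summarise(evidence = paste(sort_c(unique(.data$evidence)), collapse = ";"),
              .groups = "drop")
  confirmed <- inner_join(selected, cat_norm, by = c("mirna_id", "gene_id"))
  report <- list(
    n_selected = nrow(selected),
    n_confirmed = nrow(confirmed),
    pct_confirmed = if (nrow(selected) > 0) {
      round_half_up(100 * nrow(confirmed) / nrow(selected), 1)
    } else {
      NA_real_
    },
    n_unique_mirna = dplyr::n_distinct(confirmed$mirna_id),
    n_unique_gene = dplyr::n_distinct(confirmed$gene_id)
  )
  structure(list(confirmed = confirmed, report = report),
            class = "pair_confirmation")
}

#' @export
print.pair_confirmation <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "# pair_confirmation: %d of %d selected pair(s) confirmed (%s%%), %d miRNA(s) / %d gene(s)\n",
    r$n_confirmed, r$n_selected,
    ifelse(is.na(r$pct_confirmed), "-", format(r$pct_confirmed)),
    r$n_unique_mirna, r$n_unique_gene
  ))
  invisible(x)
}

#' @rdname confirm_pairs
#' @param x A `pair_confirmation` object.
#' @param ... Unused.
#' @method tidy pair_confirmation
#' @export
tidy.pair_confirmation <- function(x, ...) as_tibble(x$confirmed)

#' @rdname confirm_pairs
#' @method glance pair_confirmation
#' @export
glance.pair_confirmation <- function(x, ...) as_tibble(x$report)

#' Write a confirmation result to disk
#'
#' @param x A `pair_confirmation` object.
#' @param pairs_path TSV path for the confirmed pairs.
#' @param report_path Optional JSON path for the report.
#' @return `x`, invisibly.
#' @export
write_confirmation <- function(x, pairs_path, report_path = NULL) {
  readr::write_tsv(tidy(x), pairs_path)
  if (!is.null(report_path)) {
    jsonlite::write_json(x$report, report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
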