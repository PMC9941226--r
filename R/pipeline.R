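#' Pipeline configuration
#'
#' Collects the file paths, thresholds and flags for an end-to-end run. Each
#' cancer entry names either the four expression inputs (counts + sample
#' sheet per assay, with optional externally produced DE tables), or a
#' `confirmed_pairs` TSV that short-circuits straight to network assembly
#' (fixture mode).
#'
#' @param cancers Named list (name = cancer label). Each element is a list
#'   with paths: `mirna_counts`, `mirna_samples`, `mrna_counts`,
#'   `mrna_samples`, optional `mirna_de`, `mrna_de`, or a single
#'   `confirmed_pairs`.
#' @param interactions Path to the interaction-catalogue TSV (required for
#'   any cancer run from expression data).
#' @param cohort_evidence Optional path to the large-cohort evidence TSV.
#' @param fluids Optional path to the fluid-detection TSV (`symbol` or `rpm`).
#' @param out_dir Output directory for all artifacts.
#' @param alpha_de,min_fc DE thresholds (adjusted p < `alpha_de`, linear
#'   |FC| > `min_fc`).
#' @param r_max,alpha_corr Negative-correlation selection thresholds.
#' @param pseudocount RPM pseudocount for log-ratios.
#' @param adjust_correlation `"none"` or `"bh"`.
#' @param dedupe_combined Union rather than sum in the combined summary.
#' @return A validated list of class `mirgenet_config`.
#' @export
pipeline_config <- function(cancers, interactions = NULL,
                            cohort_evidence = NULL, fluids = NULL,
                            out_dir = tempfile("mirgenet_run_"),
                            alpha_de = 0.05, min_fc = 2,
                            r_max = -0.5, alpha_corr = 0.05,
                            pseudocount = 1,
                            adjust_correlation = c("none", "bh"),
                            dedupe_combined = FALSE) {
  adjust_correlation <- match.arg(adjust_correlation)
  if (!is.list(cancers) || length(cancers) == 0 || is.null(names(cancers)) ||
      any(names(cancers) == "")) {
    abort("`cancers` must be a non-empty named list")
  }
  for (label in names(cancers)) {
    entry <- cancers[[label]]
    fixture <- !is.null(entry$confirmed_pairs)
    expr_keys <- c("mirna_counts", "mirna_samples", "mrna_counts", "mrna_samples")
    if (!fixture && !all(expr_keys %in% names(entry))) {
      abort(sprintf(
        "cancer '%s' needs either `confirmed_pairs` or all of: %s",
        label, paste(expr_keys, collapse = ", ")
      ))
    }
    if (!fixture && is.null(interactions)) {
      abort(sprintf("cancer '%s' runs from expression data; `interactions` is required", label))
    }
  }
  if (!(alpha_de > 0 && alpha_de < 1)) abort("`alpha_de` must lie in (0, 1)")
  if (!(min_fc > 1)) abort("`min_fc` must be > 1")
  if (!(r_max >= -1 && r_max < 0)) abort("`r_max` must lie in [-1, 0)")
  if (!(alpha_corr > 0 && alpha_corr < 1)) abort("`alpha_corr` must lie in (0, 1)")
  if (!(pseudocount >= 0)) abort("`pseudocount` must be >= 0")
  structure(list(
    cancers = cancers, interactions = interactions,
    cohort_evidence = cohort_evidence, fluids = fluids, out_dir = out_dir,
    alpha_de = alpha_de, min_fc = min_fc, r_max = r_max,
    alpha_corr = alpha_corr, pseudocount = pseudocount,
    adjust_correlation = adjust_correlation, dedupe_combined = dedupe_combined
  ), class = "mirgenet_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `mirgenet_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `mirgenet_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate pipeline inputs without running the pipeline
#'
#' Checks that every referenced file exists and has the expected schema,
#' that each patient has a complete tumor/normal pair, and that the
#' interaction catalogue overlaps the measured miRNAs. Problems are
#' classified as `"fatal"` (the pipeline would abort) or `"warning"`.
#'
#' @param config A [pipeline_config()] object.
#' @return A tibble with columns `severity`, `stage`, `message` (zero rows
#'   when everything checks out).
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "mirgenet_config"))
  issues <- list()
  note <- function(severity, stage, message) {
    issues[[length(issues) + 1]] <<- tibble(
      severity = severity, stage = stage, message = message
    )
  }
  need_file <- function(path, stage) {
    if (!is.null(path) && !file.exists(path)) {
      note("fatal", stage, sprintf("file not found: %s", path))
      FALSE
    } else {
      !is.null(path)
    }
  }
  check_expr <- function(counts_path, samples_path, label, assay) {
    stage <- sprintf("%s/%s", label, assay)
    if (!need_file(counts_path, stage) || !need_file(samples_path, stage)) {
      return(invisible(NULL))
    }
    counts <- readr::read_tsv(counts_path, show_col_types = FALSE, n_max = Inf)
    samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
    if (!"feature_id" %in% names(counts)) {
      note("fatal", stage, sprintf("%s lacks a feature_id column", basename(counts_path)))
      return(invisible(NULL))
    }
    if (anyDuplicated(counts$feature_id)) {
      note("fatal", stage, sprintf("duplicated feature_id in %s", basename(counts_path)))
    }
    miss <- setdiff(c("sample_id", "patient_id", "condition"), names(samples))
    if (length(miss) > 0) {
      note("fatal", stage, sprintf("%s lacks column(s): %s",
                                   basename(samples_path), paste(miss, collapse = ", ")))
      return(invisible(NULL))
    }
    if ("assay" %in% names(samples)) samples <- filter(samples, .data$assay == !!assay)
    incomplete <- samples |>
      group_by(.data$patient_id) |>
      summarise(ok = all(c("tumor", "normal") %in% .data$condition), .groups = "drop") |>
      filter(!.data$ok)
    if (nrow(incomplete) > 0) {
      note("warning", stage, sprintf(
        "patient(s) without a complete tumor/normal pair: %s",
        paste(incomplete$patient_id, collapse = ", ")
      ))
    }
    invisible(counts$feature_id)
  }

  measured_mirnas <- character()
  for (label in names(config$cancers)) {
    entry <- config$cancers[[label]]
    if (!is.null(entry$confirmed_pairs)) {
      need_file(entry$confirmed_pairs, sprintf("%s/network", label))
      next
    }
    ids <- check_expr(entry$mirna_counts, entry$mirna_samples, label, "mirna")
    if (!is.null(ids)) measured_mirnas <- union(measured_mirnas, ids)
    check_expr(entry$mrna_counts, entry$mrna_samples, label, "mrna")
    for (key in c("mirna_de", "mrna_de")) need_file(entry[[key]], sprintf("%s/de", label))
  }
  if (need_file(config$interactions, "confirm")) {
    cat_tbl <- tryCatch(load_interactions(config$interactions), error = function(e) {
      note("fatal", "confirm", conditionMessage(e))
      NULL
    })
    if (!is.null(cat_tbl) && length(measured_mirnas) > 0 &&
        !any(cat_tbl$mirna_id %in% measured_mirnas)) {
      note("warning", "confirm", "interaction catalogue references no measured miRNA")
    }
  }
  need_file(config$cohort_evidence, "classify")
  need_file(config$fluids, "classify")
  if (length(issues) == 0) {
    tibble(severity = character(), stage = character(), message = character())
  } else {
    bind_rows(issues)
  }
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full integration pipeline
#'
#' Executes, per cancer: RPM normalization, differential expression (or
#' import of external DE tables), DE filtering, per-patient fold-change
#' vectors, Pearson correlation of up-regulated miRNAs against DE genes,
#' negative-correlation selection, catalogue confirmation and network
#' assembly; then, across cancers, the biomarker cascade (cohort filter,
#' fluid classification, signature). Every intermediate artifact is written
#' under `config$out_dir`, and a manifest with per-stage row counts is both
#' written as JSON and returned. The pipeline is deterministic: identical
#' config and inputs give identical outputs.
#'
#' @param config A [pipeline_config()] object.
#' @return The manifest, a list with `config_hash`, `stages` (per-cancer row
#'   counts), `summaries` and `signature` file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mirgenet_config"))
  fatal <- filter(validate_inputs(config), .data$severity == "fatal")
  if (nrow(fatal) > 0) {
    abort(paste0("invalid pipeline inputs:\n",
                 paste(sprintf("- [%s] %s", fatal$stage, fatal$message), collapse = "\n")))
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  catalogue <- if (!is.null(config$interactions)) {
    pipeline_stage("load_interactions", load_interactions(config$interactions))
  }
  networks <- list()
  stages <- list()
  candidates <- list()
  for (label in names(config$cancers)) {
    entry <- config$cancers[[label]]
    cdir <- file.path(out_dir, label)
    if (!dir.exists(cdir)) dir.create(cdir)
    if (!is.null(entry$confirmed_pairs)) {
      confirmed <- pipeline_stage(
        paste0(label, "/confirmed_pairs"),
        readr::read_tsv(entry$confirmed_pairs, show_col_types = FALSE)
      )
      net <- pipeline_stage(paste0(label, "/network"), build_network(confirmed, label))
      stage_counts <- list(confirmed = nrow(net$edges))
    } else {
      de <- list()
      fcs <- list()
      for (assay in c("mirna", "mrna")) {
        expr <- pipeline_stage(
          paste0(label, "/read_", assay),
          read_expression(entry[[paste0(assay, "_counts")]],
                          entry[[paste0(assay, "_samples")]],
                          assay = if (assay == "mirna") "mirna" else "mrna")
        )
        rpm <- pipeline_stage(paste0(label, "/rpm_", assay), rpm_normalize(expr))
        fcs[[assay]] <- pipeline_stage(
          paste0(label, "/log2fc_", assay),
          patient_log2fc(rpm, pseudocount = config$pseudocount)
        )
        de_path <- entry[[paste0(assay, "_de")]]
        de[[assay]] <- pipeline_stage(
          paste0(label, "/de_", assay),
          if (!is.null(de_path)) {
            import_de_table(de_path)
          } else {
            differential_expression(rpm, pseudocount = config$pseudocount)
          }
        )
        write_de_table(de[[assay]], file.path(cdir, paste0("de_", assay, ".tsv")))
        readr::write_tsv(fcs[[assay]], file.path(cdir, paste0("log2fc_", assay, ".tsv")))
      }
      mirna_sets <- de_feature_sets(de$mirna, alpha = config$alpha_de,
                                    min_abs_fc = config$min_fc)
      gene_kept <- filter_de(de$mrna, alpha = config$alpha_de,
                             min_abs_fc = config$min_fc)
      mirna_fc <- filter(fcs$mirna, .data$feature_id %in% mirna_sets$up)
      gene_fc <- filter(fcs$mrna, .data$feature_id %in% gene_kept$feature_id)
      pairs <- pipeline_stage(paste0(label, "/correlate"),
                              correlate_pairs(mirna_fc, gene_fc))
      selected <- select_negative(pairs, r_max = config$r_max,
                                  alpha = config$alpha_corr,
                                  adjust = config$adjust_correlation)
      readr::write_tsv(pairs, file.path(cdir, "pairs.tsv"))
      readr::write_tsv(selected, file.path(cdir, "selected.tsv"))
      conf <- pipeline_stage(paste0(label, "/confirm"),
                             confirm_pairs(selected, catalogue))
      write_confirmation(conf, file.path(cdir, "confirmed.tsv"),
                         file.path(cdir, "confirmation_report.json"))
      net <- pipeline_stage(paste0(label, "/network"),
                            build_network(tidy(conf), label))
      stage_counts <- list(
        mirna_de_up = length(mirna_sets$up),
        mirna_de_down = length(mirna_sets$down),
        gene_de = nrow(gene_kept),
        pairs = nrow(pairs),
        selected = nrow(selected),
        confirmed = conf$report$n_confirmed
      )
    }
    export_network(net, file.path(cdir, "network.graphml"), "graphml")
    export_network(net, file.path(cdir, "edges.tsv"), "edge_tsv")
    jsonlite::write_json(as.list(network_summary(net)),
                         file.path(cdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    networks[[label]] <- net
    stages[[label]] <- stage_counts
    candidates[[label]] <- tibble(
      mirna_id = net$nodes$id[net$nodes$kind == "mirna"],
      cancer_type = label
    )
  }
  combined <- combined_summary(networks, dedupe = config$dedupe_combined)
  readr::write_tsv(bind_rows(lapply(networks, network_summary)),
                   file.path(out_dir, "network_summaries.tsv"))

  signature <- NULL
  cand_tbl <- bind_rows(candidates)
  classify_counts <- list(candidates = nrow(cand_tbl))
  if (!is.null(config$fluids)) {
    evidence <- if (!is.null(config$cohort_evidence)) {
      readr::read_tsv(config$cohort_evidence, show_col_types = FALSE)
    }
    retained <- if (!is.null(evidence)) {
      pipeline_stage("cohort_filter", cohort_filter(cand_tbl, evidence))
    } else {
      cand_tbl
    }
    fluid_tbl <- readr::read_tsv(config$fluids, show_col_types = FALSE)
    calls <- pipeline_stage("classify", classify_biomarkers(retained, fluid_tbl))
    signature <- pipeline_stage("signature", build_signature(calls, evidence))
    readr::write_tsv(calls, file.path(out_dir, "biomarker_calls.tsv"))
    readr::write_tsv(signature, file.path(out_dir, "signature.tsv"))
    classify_counts$cohort_retained <- nrow(retained)
    classify_counts$liquid_eligible <- sum(calls$liquid_eligible)
    classify_counts$signature <- nrow(signature)
  }

  manifest <- list(
    package = "mirgenet",
    version = as.character(utils::packageVersion("mirgenet")),
    config_hash = rlang::hash(unclass(config)),
    out_dir = out_dir,
    stages = stages,
    classification = classify_counts,
    combined_summary = as.list(combined)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
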