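#' Simulation parameters for a paired tumor/normal cohort
#'
#' Bundles and validates the parameters of the negative-binomial cohort
#' simulator. The defaults describe a small paired cohort (8 patients, two
#' samples each) with strong, patient-variable tumor shifts: a handful of
#' up-regulated miRNAs, a subset of differentially expressed genes, and
#' `n_planted` true repressive miRNA-to-gene couplings in which the gene's
#' patient-level log2 fold change is `-coupling_slope` times the miRNA's,
#' plus residual noise.
#'
#' @param n_patients Patients, each with one tumor and one normal sample.
#' @param n_mirna,n_gene Feature counts per assay.
#' @param frac_mirna_up Fraction of miRNAs given a positive tumor shift.
#' @param frac_gene_de Fraction of genes that are differentially expressed
#'   (independent shifts, random sign); planted target genes count toward
#'   this fraction.
#' @param n_planted True repressive miRNA-gene couplings to plant.
#' @param coupling_slope Negative-regulation slope (beta >= 0): the target's
#'   patient shift is `-beta` times the miRNA's, plus noise.
#' @param patient_fc_sd Standard deviation (log2 units) of patient-level
#'   shifts around the feature mean — the biological patient-to-patient
#'   variability that makes fold-change correlation detectable.
#' @param noise_sd Residual log2 noise on planted targets.
#' @param mean_log2fc_up Mean tumor shift (log2 units, >= 1) of up-regulated
#'   miRNAs; independent DE genes use the same magnitude with random sign.
#' @param library_size Expected reads per sample; feature means are scaled
#'   per sample so every library has this expected total.
#' @param dispersion Negative-binomial dispersion alpha in
#'   `Var = mu + alpha * mu^2` (technical count noise; biological
#'   variability is carried by the patient-level shifts).
#' @param baseline_range_mirna,baseline_range_gene Log-uniform range
#'   (relative abundance, RPM scale) of baseline levels for flat
#'   (non-differential) features.
#' @param de_baseline_range_mirna,de_baseline_range_gene Log-uniform
#'   baseline range for the shifted features (up-regulated miRNAs, DE and
#'   planted target genes). Kept low so that differential features are a
#'   small fraction of library mass: strongly tumor-induced miRNAs are
#'   typically rare in normal tissue, and a stable library composition
#'   keeps RPM fold changes attributable to regulation rather than to
#'   normalization.
#' @param seed Integer seed driving all hierarchical random streams.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_patients = 8,
                       n_mirna = 300,
                       n_gene = 600,
                       frac_mirna_up = 0.1,
                       frac_gene_de = 0.08,
                       n_planted = 10,
                       coupling_slope = 1,
                       patient_fc_sd = 2,
                       noise_sd = 0.05,
                       mean_log2fc_up = 4,
                       library_size = 1e7,
                       dispersion = 0.002,
                       baseline_range_mirna = c(100, 5e4),
                       baseline_range_gene = c(200, 2e4),
                       de_baseline_range_mirna = c(20, 200),
                       de_baseline_range_gene = c(50, 500),
                       seed = 1L) {
  p <- list(
    n_patients = n_patients, n_mirna = n_mirna, n_gene = n_gene,
    frac_mirna_up = frac_mirna_up, frac_gene_de = frac_gene_de,
    n_planted = n_planted, coupling_slope = coupling_slope,
    patient_fc_sd = patient_fc_sd, noise_sd = noise_sd,
    mean_log2fc_up = mean_log2fc_up, library_size = library_size,
    dispersion = dispersion,
    baseline_range_mirna = baseline_range_mirna,
    baseline_range_gene = baseline_range_gene,
    de_baseline_range_mirna = de_baseline_range_mirna,
    de_baseline_range_gene = de_baseline_range_gene,
    seed = as.integer(seed)
  )
  for (field in c("n_patients", "n_mirna", "n_gene", "library_size")) {
    if (!is_count(p[[field]])) abort(sprintf("`%s` must be an integer >= 1", field))
  }
  for (field in c("frac_mirna_up", "frac_gene_de")) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort(sprintf("`%s` must lie in [0, 1]", field))
    }
  }
  if (!is.numeric(p$n_planted) || p$n_planted < 0 || p$n_planted != floor(p$n_planted)) {
    abort("`n_planted` must be a non-negative integer")
  }
  n_up <- round(p$frac_mirna_up * p$n_mirna)
  if (p$n_planted > 0 && n_up == 0) {
    abort("`n_planted` > 0 requires at least one up-shifted miRNA (`frac_mirna_up`)")
  }
  if (p$n_planted > n_up * p$n_gene) {
    abort("`n_planted` exceeds the number of available up-miRNA x gene pairs")
  }
  if (p$n_planted > p$n_gene) {
    abort("`n_planted` exceeds `n_gene` (each planted pair uses a distinct target gene)")
  }
  for (field in c("coupling_slope", "patient_fc_sd", "noise_sd")) {
    if (!is.numeric(p[[field]]) || p[[field]] < 0) {
      abort(sprintf("`%s` must be >= 0", field))
    }
  }
  if (!is.numeric(p$mean_log2fc_up) || p$mean_log2fc_up < 1) {
    abort("`mean_log2fc_up` must be >= 1 (log2 units)")
  }
  if (!is.numeric(p$dispersion) || p$dispersion <= 0) {
    abort("`dispersion` must be > 0")
  }
  for (field in c("baseline_range_mirna", "baseline_range_gene",
                  "de_baseline_range_mirna", "de_baseline_range_gene")) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 2 || any(v <= 0) || v[1] >= v[2]) {
      abort(sprintf("`%s` must be an increasing positive pair", field))
    }
  }
  structure(p, class = "sim_params")
}

sim_mirna_ids <- function(params) sprintf("sim-miR-%03d", seq_len(params$n_mirna))
sim_gene_ids <- function(params) sprintf("GENE%04d", seq_len(params$n_gene))
sim_patient_ids <- function(params) sprintf("P%02d", seq_len(params$n_patients))

r_log_uniform <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

# The cohort design (which features carry shifts, which pairs are planted)
# lives on its own stream so feature-level value draws are reproducible per
# feature.
sim_design <- function(params) {
  set.seed(derive_seed(params$seed, "design"))
  mirnas <- sim_mirna_ids(params)
  genes <- sim_gene_ids(params)
  n_up <- round(params$frac_mirna_up * params$n_mirna)
  up <- sort_c(sample(mirnas, n_up))
  n_de_gene <- max(round(params$frac_gene_de * params$n_gene), params$n_planted)
  planted_genes <- if (params$n_planted > 0) sample(genes, params$n_planted) else character()
  planted_mirnas <- if (params$n_planted > 0) {
    if (params$n_planted <= n_up) {
      sample(up, params$n_planted)
    } else {
      sample(up, params$n_planted, replace = TRUE)
    }
  } else {
    character()
  }
  free_de_genes <- sample(setdiff(genes, planted_genes),
                          n_de_gene - params$n_planted)
  gene_sign <- sample(c(-1, 1), length(free_de_genes), replace = TRUE)
  list(
    up_mirnas = up,
    planted = tibble(mirna_id = planted_mirnas, gene_id = planted_genes,
                     slope = rep(params$coupling_slope, params$n_planted)),
    free_de_genes = free_de_genes,
    free_de_sign = setNames(gene_sign, free_de_genes)
  )
}

# Draw per-feature baselines and patient-level shifts on per-feature streams.
sim_mirna_shifts <- function(params, design) {
  ids <- sim_mirna_ids(params)
  baseline <- numeric(length(ids))
  shifts <- matrix(0, nrow = length(ids), ncol = params$n_patients,
                   dimnames = list(ids, sim_patient_ids(params)))
  for (i in seq_along(ids)) {
    set.seed(derive_seed(params$seed, "mirna_values", i))
    up <- ids[i] %in% design$up_mirnas
    baseline[i] <- r_log_uniform(1, if (up) params$de_baseline_range_mirna
                                    else params$baseline_range_mirna)
    if (up) {
      shifts[i, ] <- params$mean_log2fc_up +
        rnorm(params$n_patients, 0, params$patient_fc_sd)
    }
  }
  list(baseline = setNames(baseline, ids), shifts = shifts)
}

sim_gene_shifts <- function(params, design, mirna_shifts) {
  ids <- sim_gene_ids(params)
  baseline <- numeric(length(ids))
  shifts <- matrix(0, nrow = length(ids), ncol = params$n_patients,
                   dimnames = list(ids, sim_patient_ids(params)))
  planted_lookup <- setNames(design$planted$mirna_id, design$planted$gene_id)
  for (j in seq_along(ids)) {
    set.seed(derive_seed(params$seed, "gene_values", j))
    id <- ids[j]
    is_de <- id %in% names(planted_lookup) || id %in% design$free_de_genes
    baseline[j] <- r_log_uniform(1, if (is_de) params$de_baseline_range_gene
                                    else params$baseline_range_gene)
    if (id %in% names(planted_lookup)) {
      l <- mirna_shifts$shifts[planted_lookup[[id]], ]
      shifts[j, ] <- -params$coupling_slope * l +
        rnorm(params$n_patients, 0, params$noise_sd)
    } else if (id %in% design$free_de_genes) {
      shifts[j, ] <- design$free_de_sign[[id]] * params$mean_log2fc_up +
        rnorm(params$n_patients, 0, params$patient_fc_sd)
    }
  }
  list(baseline = setNames(baseline, ids), shifts = shifts)
}

# Expected count matrix: normal-sample mean from the baseline, tumor-sample
# mean baseline * 2^shift, each column rescaled so its expected sum equals
# the library size; then one NB draw per cell on per-feature streams.
sim_counts <- function(params, baseline, shifts, stream) {
  patients <- sim_patient_ids(params)
  mu_tumor <- baseline * 2^shifts
  mu_normal <- matrix(baseline, nrow = length(baseline), ncol = params$n_patients,
                      dimnames = dimnames(shifts))
  mu <- cbind(mu_tumor, mu_normal)
  colnames(mu) <- c(paste0(patients, "_tumor"), paste0(patients, "_normal"))
  mu <- sweep(mu, 2, colSums(mu), "/") * params$library_size
  counts <- matrix(0, nrow = nrow(mu), ncol = ncol(mu), dimnames = dimnames(mu))
  for (i in seq_len(nrow(mu))) {
    set.seed(derive_seed(params$seed, stream, i))
    counts[i, ] <- rnbinom(ncol(mu), mu = mu[i, ], size = 1 / params$dispersion)
  }
  counts
}

counts_to_expr <- function(counts, params, assay) {
  patients <- sim_patient_ids(params)
  samples <- tibble(
    sample_id = colnames(counts),
    patient_id = rep(patients, 2),
    condition = rep(c("tumor", "normal"), each = length(patients))
  )
  values <- as_tibble(counts) |>
    mutate(feature_id = rownames(counts), .before = 1)
  paired_expression_set(values, samples, assay = assay, unit = "counts")
}

#' Simulate a paired tumor/normal miRNA + mRNA cohort
#'
#' Generates matched miRNA and mRNA count sets over the same patients (one
#' tumor and one normal sample each) together with the ground-truth list of
#' planted repressive couplings. Up-shifted miRNAs draw a patient-level
#' log2 shift `L ~ N(mean_log2fc_up, patient_fc_sd)`; each planted target
#' gene's shift is `-coupling_slope * L` plus `N(0, noise_sd)` noise;
#' independent DE genes draw their own shifts; all remaining features are
#' flat. Counts are negative-binomial around library-scaled means. A single
#' seed drives hierarchical per-feature streams, so runs are bit-identical.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `mirna` and `mrna` (two `paired_expr` count
#'   sets), `truth` (tibble `mirna_id`, `gene_id`, `slope`) and `params`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_params(n_mirna = 20, n_gene = 40, n_planted = 2))
#' sim$truth
simulate_cohort <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) abort("`params` must come from sim_params()")
  design <- sim_design(params)
  mir <- sim_mirna_shifts(params, design)
  gen <- sim_gene_shifts(params, design, mir)
  mirna_counts <- sim_counts(params, mir$baseline, mir$shifts, "mirna_counts")
  gene_counts <- sim_counts(params, gen$baseline, gen$shifts, "gene_counts")
  truth <- arrange_c(design$planted, "mirna_id", "gene_id")
  list(
    mirna = counts_to_expr(mirna_counts, params, "mirna"),
    mrna = counts_to_expr(gene_counts, params, "mrna"),
    truth = as_tibble(truth),
    params = params
  )
}

#' True patient-level shifts of a simulated cohort
#'
#' Returns the noiseless patient-level log2 shifts the simulator planted
#' (before count noise), useful for verifying the coupling structure.
#'
#' @param params A [sim_params()] object.
#' @return A list with matrices `mirna` and `gene` (features x patients).
#' @export
simulated_true_shifts <- function(params) {
  design <- sim_design(params)
  mir <- sim_mirna_shifts(params, design)
  gen <- sim_gene_shifts(params, design, mir)
  list(mirna = mir$shifts, gene = gen$shifts)
}

#' Generate auxiliary tables for a simulated cohort
#'
#' Builds local stand-ins for the three external resources the pipeline
#' consumes: an interaction catalogue containing every planted pair (evidence
#' `"experimental"`) plus decoy pairs (evidence `"predicted"`), a cohort
#' evidence table, and a fluid-detection table with log-uniform RPM levels
#' spanning all detection bins.
#'
#' @param truth Planted-pair tibble from [simulate_cohort()] (may be empty).
#' @param params The matching [sim_params()] object.
#' @param n_decoys Decoy interactions to add (non-planted combinations).
#' @param significant_mirnas miRNAs to mark significant in the cohort
#'   evidence table; `NULL` (default) marks all simulated miRNAs.
#' @param cancer_type Cancer label used in the evidence table.
#' @param fluid_rpm_range Log-uniform range of fluid RPM levels.
#' @return A list of tibbles: `interactions`, `cohort_evidence`,
#'   `fluid_detection`.
#' @export
generate_auxiliary_tables <- function(truth, params,
                                      n_decoys = 100,
                                      significant_mirnas = NULL,
                                      cancer_type = "SIM",
                                      fluid_rpm_range = c(1, 5000)) {
  if (!inherits(params, "sim_params")) abort("`params` must come from sim_params()")
  set.seed(derive_seed(params$seed, "aux"))
  mirnas <- sim_mirna_ids(params)
  genes <- sim_gene_ids(params)
  planted_keys <- character()
  interactions <- tibble(mirna_id = character(), gene_id = character(),
                         evidence = character())
  if (!is.null(truth) && nrow(truth) > 0) {
    check_columns(truth, c("mirna_id", "gene_id"), "`truth`")
    planted_keys <- paste(truth$mirna_id, truth$gene_id)
    interactions <- tibble(mirna_id = truth$mirna_id, gene_id = truth$gene_id,
                           evidence = "experimental")
  }
  if (n_decoys > 0) {
    decoys <- tibble(
      mirna_id = sample(mirnas, 4 * n_decoys, replace = TRUE),
      gene_id = sample(genes, 4 * n_decoys, replace = TRUE)
    ) |>
      filter(!paste(.data$mirna_id, .data$gene_id) %in% planted_keys) |>
      distinct() |>
      head(n_decoys) |>
      mutate(evidence = "predicted")
    interactions <- bind_rows(interactions, decoys)
  }
  cohort_evidence <- tibble(
    mirna_id = mirnas,
    cancer_type = cancer_type,
    significant = if (is.null(significant_mirnas)) TRUE else mirnas %in% significant_mirnas
  )
  fluid_detection <- tidyr::expand_grid(mirna_id = mirnas, fluid = fluid_names) |>
    mutate(rpm = r_log_uniform(dplyr::n(), fluid_rpm_range))
  list(
    interactions = interactions,
    cohort_evidence = cohort_evidence,
    fluid_detection = fluid_detection
  )
}

#' Write a simulated cohort to a directory
#'
#' Writes the counts and sample-sheet TSVs for both assays, the planted-pair
#' truth table, and the auxiliary tables, in the package's interchange
#' formats.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param aux Optional output of [generate_auxiliary_tables()].
#' @return `dir`, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir, aux = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(sim$mirna, file.path(dir, "mirna_counts.tsv"),
                   file.path(dir, "mirna_samples.tsv"))
  write_expression(sim$mrna, file.path(dir, "mrna_counts.tsv"),
                   file.path(dir, "mrna_samples.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "planted_pairs.tsv"))
  if (!is.null(aux)) {
    readr::write_tsv(aux$interactions, file.path(dir, "interactions.tsv"))
    readr::write_tsv(aux$cohort_evidence, file.path(dir, "cohort_evidence.tsv"))
    readr::write_tsv(aux$fluid_detection, file.path(dir, "fluid_detection.tsv"))
  }
  invisible(dir)
}
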