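# Shared test helpers: tiny cohort builders and independent oracles.

# A minimal paired expression set from a features x samples value matrix.
# Sample names follow "P<k>_tumor" / "P<k>_normal".
tiny_expr <- function(values, assay = "mirna", unit = "counts") {
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)))
  samples <- tibble::tibble(
    sample_id = colnames(values),
    patient_id = sub("_(tumor|normal)$", "", colnames(values)),
    condition = sub("^.*_", "", colnames(values))
  )
  counts <- tibble::as_tibble(values) |>
    dplyr::mutate(feature_id = rownames(values), .before = 1)
  paired_expression_set(counts, samples, assay = assay, unit = unit)
}

# Expression set in which every feature has the given per-patient linear
# tumor/normal RPM ratio (normal fixed at `base` RPM).
ratio_expr <- function(ratios, base = 100, assay = "mirna") {
  # ratios: features x patients matrix of linear FCs
  patients <- colnames(ratios)
  vals <- cbind(base * ratios, matrix(base, nrow(ratios), ncol(ratios)))
  colnames(vals) <- c(paste0(patients, "_tumor"), paste0(patients, "_normal"))
  rownames(vals) <- rownames(ratios)
  tiny_expr(vals, assay = assay, unit = "rpm")
}

# Brute-force Benjamini-Hochberg reference: sort, (m / rank) * p, cumulative
# minimum from the largest rank down, cap at 1, unsort.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- (m / seq_len(m)) * p[o]
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# All permutations of seq_len(n) (n <= 7).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Exhaustive two-sided permutation p-value for Pearson's r.
perm_pvalue <- function(x, y) {
  perms <- all_perms(length(y))
  r_obs <- abs(cor(x, y))
  r_perm <- apply(perms, 1, function(idx) abs(cor(x, y[idx])))
  mean(r_perm >= r_obs - 1e-12)
}

# Run the standard synthetic recovery chain: DE filter both assays,
# correlate up-miRNAs against DE genes, select, confirm against the
# truth-plus-decoys catalogue. Returns the planted pairs whose members
# passed DE filtering and the confirmed hits among them.
run_recovery <- function(params, n_decoys = 100) {
  sim <- simulate_cohort(params)
  rpm_m <- rpm_normalize(sim$mirna)
  rpm_g <- rpm_normalize(sim$mrna)
  de_m <- suppressMessages(differential_expression(rpm_m))
  de_g <- suppressMessages(differential_expression(rpm_g))
  up <- de_feature_sets(de_m)$up
  genes <- filter_de(de_g)$feature_id
  pairs <- suppressMessages(correlate_pairs(
    dplyr::filter(patient_log2fc(rpm_m), feature_id %in% up),
    dplyr::filter(patient_log2fc(rpm_g), feature_id %in% genes)
  ))
  selected <- select_negative(pairs)
  aux <- generate_auxiliary_tables(sim$truth, params, n_decoys = n_decoys)
  conf <- confirm_pairs(selected, aux$interactions)
  eligible <- dplyr::filter(sim$truth, mirna_id %in% up, gene_id %in% genes)
  hits <- dplyr::inner_join(tidy(conf), eligible, by = c("mirna_id", "gene_id"))
  list(sim = sim, pairs = pairs, selected = selected, confirmation = conf,
       eligible_truth = eligible, recovered = hits)
}

# Fraction of all miRNA x gene fold-change pairs passing the negative
# selection in a null cohort (no planted couplings).
null_selected_fraction <- function(seed) {
  params <- sim_params(
    seed = seed, n_mirna = 40, n_gene = 80,
    frac_mirna_up = 0.2, frac_gene_de = 0.25, n_planted = 0
  )
  sim <- simulate_cohort(params)
  pairs <- suppressMessages(correlate_pairs(
    patient_log2fc(rpm_normalize(sim$mirna)),
    patient_log2fc(rpm_normalize(sim$mrna))
  ))
  nrow(select_negative(pairs)) / nrow(pairs)
}
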