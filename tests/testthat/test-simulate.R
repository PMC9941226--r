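small_params <- function(...) {
  args <- utils::modifyList(
    list(n_mirna = 30, n_gene = 60, frac_mirna_up = 0.2,
         frac_gene_de = 0.2, n_planted = 4),
    list(...)
  )
  do.call(sim_params, args)
}

test_that("sim_params validates every field and names the offender", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(n_patients = 0), "n_patients")
  expect_error(sim_params(frac_mirna_up = 1.4), "frac_mirna_up")
  expect_error(sim_params(dispersion = 0), "dispersion")
  expect_error(sim_params(mean_log2fc_up = 0.5), "mean_log2fc_up")
  expect_error(sim_params(n_planted = -1), "n_planted")
  expect_error(sim_params(n_mirna = 10, frac_mirna_up = 0, n_planted = 1),
               "frac_mirna_up")
  expect_error(sim_params(baseline_range_mirna = c(10, 5)), "baseline_range_mirna")
  # planted pairs cannot exceed the up-miRNA x gene grid
  expect_error(sim_params(n_mirna = 10, n_gene = 2, frac_mirna_up = 0.1,
                          n_planted = 3), "n_planted")
})

test_that("a null cohort has no planted structure", {
  sim <- simulate_cohort(small_params(n_planted = 0, coupling_slope = 0, seed = 3))
  expect_equal(nrow(sim$truth), 0)
  # miRNA and gene patient shifts are drawn independently: across seeds,
  # the fraction of (shifted miRNA, DE gene) true-shift pairs passing the
  # downstream selection stays within the two-sided alpha = 0.05 budget
  cors <- unlist(lapply(1:10, function(s) {
    shifts <- simulated_true_shifts(small_params(n_planted = 0,
                                                 coupling_slope = 0, seed = s))
    up <- rownames(shifts$mirna)[rowMeans(shifts$mirna) != 0]
    de_genes <- rownames(shifts$gene)[rowMeans(abs(shifts$gene)) != 0]
    as.vector(cor(t(shifts$mirna[up, ]), t(shifts$gene[de_genes, ])))
  }))
  expect_gt(length(cors), 500)
  expect_lt(mean(cors < -0.5 & pearson_pvalue(cors, 8) < 0.05), 0.05)
})

test_that("noiseless planted couplings are perfectly anticorrelated", {
  p <- small_params(noise_sd = 0, coupling_slope = 1, seed = 5)
  shifts <- simulated_true_shifts(p)
  sim <- simulate_cohort(p)
  for (k in seq_len(nrow(sim$truth))) {
    r <- cor(shifts$mirna[sim$truth$mirna_id[k], ],
             shifts$gene[sim$truth$gene_id[k], ])
    expect_equal(r, -1)
  }
})

test_that("simulation output is byte-identical under a fixed seed", {
  p <- sim_params(n_patients = 8, coupling_slope = 1, noise_sd = 0.1, seed = 7,
                  n_mirna = 40, n_gene = 80, frac_mirna_up = 0.2,
                  frac_gene_de = 0.1, n_planted = 3)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  expect_identical(s1, s2)
  a1 <- generate_auxiliary_tables(s1$truth, p)
  a2 <- generate_auxiliary_tables(s2$truth, p)
  expect_identical(a1, a2)
  # a different seed changes the draws
  s3 <- simulate_cohort(sim_params(n_patients = 8, coupling_slope = 1,
                                   noise_sd = 0.1, seed = 8, n_mirna = 40,
                                   n_gene = 80, frac_mirna_up = 0.2,
                                   frac_gene_de = 0.1, n_planted = 3))
  expect_false(identical(s1$mirna, s3$mirna))
})

test_that("library sizes concentrate around the configured total", {
  p <- small_params(seed = 9)
  sim <- simulate_cohort(p)
  for (assay in c("mirna", "mrna")) {
    wide <- sim[[assay]] |>
      tidyr::pivot_wider(id_cols = feature_id, names_from = sample_id,
                         values_from = value)
    sums <- colSums(wide[, -1])
    # NB column-sum standard deviation is bounded by sqrt(sum(mu + a*mu^2))
    # with column means summing to the library size
    sd_bound <- sqrt(p$library_size + p$dispersion * p$library_size^2)
    expect_true(all(abs(sums - p$library_size) <= 3 * sd_bound))
    # and the empirical spread is far tighter than the worst case
    expect_lt(max(abs(sums - p$library_size)) / p$library_size, 0.2)
  }
})

test_that("auxiliary tables contain the truth plus configurable extras", {
  p <- small_params(seed = 11)
  sim <- simulate_cohort(p)
  aux0 <- generate_auxiliary_tables(sim$truth, p, n_decoys = 0)
  expect_equal(nrow(aux0$interactions), nrow(sim$truth))
  expect_true(all(aux0$interactions$evidence == "experimental"))

  aux <- generate_auxiliary_tables(sim$truth, p, n_decoys = 25)
  expect_equal(nrow(aux$interactions), nrow(sim$truth) + 25)
  expect_false(anyDuplicated(aux$interactions[, c("mirna_id", "gene_id")]) > 0)

  # all-significant evidence makes the cohort filter the identity
  cand <- tibble::tibble(mirna_id = unique(sim$mirna$feature_id)[1:5],
                         cancer_type = "SIM")
  retained <- cohort_filter(cand, aux$cohort_evidence)
  expect_equal(nrow(retained), nrow(cand))

  # fluid RPM levels span all four detection bins
  expect_setequal(as.character(unique(detection_symbol(aux$fluid_detection$rpm))),
                  c("-", "+", "++", "+++"))

  # empty truth is allowed
  aux_empty <- generate_auxiliary_tables(sim$truth[0, ], p, n_decoys = 5)
  expect_equal(nrow(aux_empty$interactions), 5)
})

test_that("simulated cohorts round-trip through the on-disk formats", {
  p <- small_params(seed = 13)
  sim <- simulate_cohort(p)
  aux <- generate_auxiliary_tables(sim$truth, p, n_decoys = 10)
  dir <- withr::local_tempdir()
  write_simulated_cohort(sim, dir, aux)
  back <- read_expression(file.path(dir, "mirna_counts.tsv"),
                          file.path(dir, "mirna_samples.tsv"), assay = "mirna")
  expect_equal(as.data.frame(back), as.data.frame(sim$mirna))
  truth <- readr::read_tsv(file.path(dir, "planted_pairs.tsv"), col_types = "ccd")
  expect_equal(as.data.frame(truth), as.data.frame(sim$truth))
  expect_equal(nrow(load_interactions(file.path(dir, "interactions.tsv"))),
               nrow(aux$interactions))
})
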