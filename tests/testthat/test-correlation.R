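test_that("pearson_r reproduces hand-computed coefficients", {
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3), 2 * c(1, 2, 3) + 5), 1)
  # cov = 1.25, sd_x = sd_y = 1.29099...; r = 0.8
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
})

test_that("pearson_r rejects degenerate input", {
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3), x_id = "miR-x"), "miR-x")
  expect_error(pearson_r(c(1, 2, 3), c(2, 2, 2), y_id = "GENE1"), "GENE1")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_r(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("pearson_pvalue implements the two-sided t-transform", {
  expect_equal(pearson_pvalue(0, 5), 1)
  expect_equal(pearson_pvalue(-1, 5), 0)
  expect_equal(pearson_pvalue(1, 10), 0)
  # r = -0.75, n = 8: t = -2.7775, df = 6 -> p ~= 0.032, checked against
  # direct numeric integration of the t density (written out, not stats::dt)
  t_density <- function(t, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  }
  t_obs <- -0.75 * sqrt(6 / (1 - 0.75^2))
  p_oracle <- 2 * integrate(t_density, -Inf, t_obs, df = 6)$value
  expect_lte(abs(p_oracle - 0.032), 1e-3)
  expect_lte(abs(pearson_pvalue(-0.75, 8) - p_oracle), 1e-3)
  expect_error(pearson_pvalue(0.5, 2), "at least 3")
  expect_error(pearson_pvalue(1.5, 5), "\\[-1, 1\\]")
})

test_that("pearson_pvalue agrees with cor.test", {
  set.seed(3)
  for (n in c(4, 8, 15)) {
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    ct <- cor.test(x, y)
    expect_equal(pearson_pvalue(unname(ct$estimate), n), ct$p.value,
                 tolerance = 1e-12)
  }
})

test_that("pearson_pvalue agrees with the exhaustive permutation oracle", {
  set.seed(17)
  for (n in c(5, 6)) {
    n_perm <- factorial(n)
    for (i in 1:4) {
      x <- rnorm(n)
      y <- -0.8 * x + rnorm(n, 0, 0.8)
      r <- pearson_r(x, y)
      expect_lte(abs(pearson_pvalue(r, n) - perm_pvalue(x, y)), 2 / sqrt(n_perm))
    }
  }
})

fc_tbl <- function(m) {
  tibble::tibble(
    feature_id = rep(rownames(m), each = ncol(m)),
    patient_id = rep(colnames(m), nrow(m)),
    log2fc = as.vector(t(m))
  )
}

test_that("correlate_pairs forms the full cross product over common patients", {
  patients <- paste0("P", 1:5)
  set.seed(5)
  mir <- matrix(rnorm(10), 2, 5, dimnames = list(c("mA", "mB"), patients))
  gen <- matrix(rnorm(15), 3, 5, dimnames = list(c("g1", "g2", "g3"), patients))
  pairs <- correlate_pairs(fc_tbl(mir), fc_tbl(gen))
  expect_equal(nrow(pairs), 6)
  expect_equal(unique(pairs$n), 5)
  expect_false(anyDuplicated(pairs[, c("mirna_id", "gene_id")]) > 0)

  # exact mirror pair: r = -1, p = 0
  gen2 <- rbind(gen, mirror = -mir["mA", , drop = FALSE])
  rownames(gen2)[4] <- "g_mirror"
  pairs2 <- correlate_pairs(fc_tbl(mir), fc_tbl(gen2))
  mirror_row <- pairs2[pairs2$mirna_id == "mA" & pairs2$gene_id == "g_mirror", ]
  expect_equal(mirror_row$r, -1)
  expect_equal(mirror_row$p, 0)
})

test_that("correlate_pairs is invariant to consistent patient permutation", {
  patients <- paste0("P", 1:6)
  set.seed(6)
  mir <- matrix(rnorm(12), 2, 6, dimnames = list(c("mA", "mB"), patients))
  gen <- matrix(rnorm(18), 3, 6, dimnames = list(c("g1", "g2", "g3"), patients))
  base <- correlate_pairs(fc_tbl(mir), fc_tbl(gen))
  perm <- sample(6)
  shuffled <- correlate_pairs(fc_tbl(mir[, perm]), fc_tbl(gen[, perm]))
  expect_equal(
    dplyr::arrange(base, mirna_id, gene_id)$r,
    dplyr::arrange(shuffled, mirna_id, gene_id)$r
  )
})

test_that("correlate_pairs skips zero-variance vectors and needs 3 patients", {
  patients <- paste0("P", 1:4)
  mir <- matrix(c(1, 2, 3, 4, 5, 5, 5, 5), 2, 4, byrow = TRUE,
                dimnames = list(c("mA", "m_flat"), patients))
  gen <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), patients))
  expect_message(pairs <- correlate_pairs(fc_tbl(mir), fc_tbl(gen)), "zero-variance")
  expect_equal(sort(unique(pairs$mirna_id)), "mA")
  expect_equal(attr(pairs, "n_skipped"), 2)

  mir2 <- mir[, 1:2]
  expect_error(correlate_pairs(fc_tbl(mir2), fc_tbl(gen[, 1:2])), ">= 3")
})

test_that("select_negative applies strict bounds", {
  pairs <- tibble::tibble(
    mirna_id = paste0("m", 1:4), gene_id = paste0("g", 1:4),
    r = c(-0.5, -0.9, -0.51, -1),
    p = c(0.001, 0.06, 0.04, 0.001),
    n = 8
  )
  kept <- select_negative(pairs)
  # r = -0.5 exactly excluded; p = 0.06 excluded; r = -1 retained
  expect_setequal(kept$mirna_id, c("m3", "m4"))
  expect_error(select_negative(pairs, r_max = 0.2), "\\[-1, 0\\)")
  expect_error(select_negative(pairs, alpha = 1.2), "\\(0, 1\\)")
})

test_that("select_negative is a monotone subset operation", {
  set.seed(9)
  pairs <- tibble::tibble(
    mirna_id = paste0("m", 1:300), gene_id = paste0("g", 1:300),
    r = runif(300, -1, 1), n = 8
  ) |>
    dplyr::mutate(p = pearson_pvalue(r, 8))
  for (i in 1:10) {
    r1 <- runif(1, -0.9, -0.1); r2 <- max(-1, r1 - runif(1, 0, 0.5))
    a1 <- runif(1, 0.01, 0.2); a2 <- a1 / 2
    loose <- select_negative(pairs, r_max = r1, alpha = a1)
    strict <- select_negative(pairs, r_max = r2, alpha = a2)
    expect_true(all(strict$mirna_id %in% loose$mirna_id))
    expect_true(nrow(loose) <= nrow(pairs))
  }
})

test_that("positive rescaling of fold changes leaves r and the selection unchanged", {
  patients <- paste0("P", 1:6)
  set.seed(10)
  mir <- matrix(rnorm(12), 2, 6, dimnames = list(c("mA", "mB"), patients))
  gen <- matrix(rnorm(18), 3, 6, dimnames = list(c("g1", "g2", "g3"), patients))
  base <- correlate_pairs(fc_tbl(mir), fc_tbl(gen))
  scaled <- correlate_pairs(fc_tbl(3.7 * mir), fc_tbl(0.2 * gen))
  expect_equal(base$r, scaled$r)
  expect_equal(
    nrow(select_negative(base)), nrow(select_negative(scaled))
  )
})
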