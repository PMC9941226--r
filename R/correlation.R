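#' Pearson correlation of two fold-change vectors
#'
#' Standard product-moment coefficient, with an explicit error (naming the
#' offending feature where known) when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @param x_id,y_id Optional identifiers used in error messages.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y, x_id = "x", y_id = "y") {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("correlation needs at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) abort("fold-change vectors must not contain NA")
  if (stats::sd(x) == 0) abort(sprintf("correlation undefined: '%s' has zero variance", x_id))
  if (stats::sd(y) == 0) abort(sprintf("correlation undefined: '%s' has zero variance", y_id))
  unname(cor(x, y))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t-transform `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t
#' distribution with `n - 2` degrees of freedom; `r = +/-1` gives `p = 0`.
#' Vectorised over `r` (and `n`).
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param n Number of paired observations, at least 3.
#' @return Two-sided probabilities in `[0, 1]`.
#' @export
pearson_pvalue <- function(r, n) {
  if (any(n < 3)) abort("`n` must be at least 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) abort("`r` must lie in [-1, 1]")
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tstat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-abs(tstat), df = n - 2)
  p
}

#' Correlate miRNA and gene fold-change profiles across patients
#'
#' Forms the full cross product of miRNA and gene fold-change vectors
#' (typically the up-regulated differentially expressed miRNAs against all
#' differentially expressed genes), aligned on the patients common to both
#' assays, and computes Pearson's r with its two-sided p-value for each pair.
#' Pairs involving a zero-variance vector are skipped; their count is
#' reported in a message and in the `n_skipped` attribute.
#'
#' @param mirna_fc,gene_fc Fold-change tibbles (`feature_id`, `patient_id`,
#'   `log2fc`) as returned by [patient_log2fc()].
#' @return A tibble with columns `mirna_id`, `gene_id`, `r`, `p`, `n`.
#' @export
correlate_pairs <- function(mirna_fc, gene_fc) {
  mx <- fc_matrix(mirna_fc)
  gx <- fc_matrix(gene_fc)
  common <- intersect(colnames(mx), colnames(gx))
  if (length(common) < 3) {
    abort(sprintf("only %d patient(s) common to both assays; need >= 3", length(common)))
  }
  mx <- mx[, common, drop = FALSE]
  gx <- gx[, common, drop = FALSE]
  n <- length(common)

  m_const <- apply(mx, 1, stats::sd) == 0
  g_const <- apply(gx, 1, stats::sd) == 0
  n_skipped <- sum(m_const) * nrow(gx) + sum(!m_const) * sum(g_const)
  if (n_skipped > 0) {
    inform(sprintf(
      "skipping %d pair(s) with a zero-variance fold-change vector (%d miRNA(s), %d gene(s))",
      n_skipped, sum(m_const), sum(g_const)
    ))
  }
  mx <- mx[!m_const, , drop = FALSE]
  gx <- gx[!g_const, , drop = FALSE]

  rmat <- cor(t(mx), t(gx))
  pairs <- tidyr::expand_grid(mirna_id = rownames(mx), gene_id = rownames(gx)) |>
    mutate(
      r = as.vector(t(rmat)),
      p = pearson_pvalue(.data$r, n),
      n = n
    )
  attr(pairs, "n_skipped") <- n_skipped
  pairs
}

#' Select significantly negatively correlated pairs
#'
#' Retains pairs with `r < r_max` and `p < alpha`, both strict — the
#' negative-correlation filter used to nominate candidate repressive
#' miRNA-gene couplings. Optionally adjusts the correlation p-values by
#' Benjamini-Hochberg before applying `alpha`.
#'
#' @param pairs A correlation tibble from [correlate_pairs()].
#' @param r_max Upper bound on r; must lie in `[-1, 0)`. Default -0.5.
#' @param alpha Probability bound in `(0, 1)`. Default 0.05.
#' @param adjust `"none"` (default) to threshold raw p-values, `"bh"` to
#'   threshold BH-adjusted ones.
#' @return The retained subset of `pairs`.
#' @export
select_negative <- function(pairs, r_max = -0.5, alpha = 0.05,
                            adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  check_columns(pairs, c("mirna_id", "gene_id", "r", "p"), "pair table")
  if (!is.numeric(r_max) || r_max >= 0 || r_max < -1) {
    abort("`r_max` must lie in [-1, 0)")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)")
  }
  p_use <- if (adjust == "bh") p.adjust(pairs$p, method = "BH") else pairs$p
  pairs[pairs$r < r_max & p_use < alpha, , drop = FALSE]
}
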