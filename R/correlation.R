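#' Filter genes by expression level
#'
#' Keeps genes whose mean expression across the retained tumors is at least
#' `min_level` (log2 RPKM-like units; the boundary is inclusive). Pass
#' `min_level = -Inf` to disable the filter.
#'
#' @param expression Long tibble `gene_id, sample, expr`.
#' @param min_level Threshold, default 0.5.
#' @param samples Optional subset of tumors over which the mean is taken.
#' @return The filtered expression tibble.
#' @export
filter_expressed <- function(expression, min_level = 0.5, samples = NULL) {
  assert_columns(expression, c("gene_id", "sample", "expr"), "expression table")
  e <- expression
  if (!is.null(samples)) e <- e[e$sample %in% samples, , drop = FALSE]
  keep <- e |>
    group_by(.data$gene_id) |>
    summarise(m = mean(.data$expr, na.rm = TRUE), .groups = "drop") |>
    filter(!is.na(.data$m), .data$m >= min_level) |>
    pull("gene_id")
  expression[expression$gene_id %in% keep &
               (if (is.null(samples)) TRUE else expression$sample %in% samples), ,
             drop = FALSE]
}

#' Correlate gene expression with per-tumor outlier burden
#'
#' For each gene, the expression values across tumors are correlated with
#' that tumor's eSNV outlier burden. The default is the Pearson correlation
#' with its two-sided t-distribution p-value — for a single continuous
#' covariate this is the same test as a one-regressor ANOVA/regression F —
#' with a Spearman alternative. Genes with constant expression (or fewer
#' than 4 complete pairs) cannot be tested and are returned with
#' `skipped = TRUE`. Benjamini-Hochberg q-values are computed over all
#' tested genes.
#'
#' @param expression Long tibble `gene_id, sample, expr` (typically after
#'   [filter_expressed()]).
#' @param burden Tibble `sample, n_outliers` from [outlier_burden()],
#'   restricted to the tumors free of private concerted LOH.
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble of class `vloh_cor`:
#'   `gene_id, r, p, q, sign, n, skipped`, signs `"negative"`/`"positive"`.
#' @export
correlate_burden <- function(expression, burden,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_columns(expression, c("gene_id", "sample", "expr"), "expression table")
  assert_columns(burden, c("sample", "n_outliers"), "burden table")
  common <- intersect(unique(expression$sample), burden$sample)
  if (length(common) < 4) {
    abort(sprintf(
      "correlation needs >= 4 tumors common to expression and burden (found %d)",
      length(common)))
  }
  b <- burden$n_outliers[match(common, burden$sample)]
  e <- expression[expression$sample %in% common, , drop = FALSE]

  res <- e |>
    group_by(.data$gene_id) |>
    summarise(
      res = list(cor_one(.data$expr[match(common, .data$sample)], b, method)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("res")
  n_skipped <- sum(res$skipped)
  if (n_skipped > 0) {
    inform(sprintf("%d gene(s) skipped (constant expression or < 4 complete pairs)",
                   n_skipped))
  }
  res$q <- NA_real_
  tested <- !res$skipped
  res$q[tested] <- bh_adjust(res$p[tested])
  res$sign <- dplyr::if_else(res$r < 0, "negative", "positive")
  res <- res[, c("gene_id", "r", "p", "q", "sign", "n", "skipped")]
  attr(res, "method") <- method
  attr(res, "n_tumors") <- length(common)
  class(res) <- c("vloh_cor", class(res))
  res
}

cor_one <- function(x, y, method) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 4 || length(unique(x[ok])) == 1 || length(unique(y[ok])) == 1) {
    return(list(r = NA_real_, p = NA_real_, n = n, skipped = TRUE))
  }
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = n, skipped = FALSE)
}

#' Sign bias of strong correlations
#'
#' Among tested genes with `p < p_cut`, reports the fraction whose
#' correlation with outlier burden is negative — the signature of a
#' repression-dominated mechanism. An empty filtered set is undefined and
#' reported as such (`NA`).
#'
#' @param results A `vloh_cor` tibble.
#' @param p_cut P-value cutoff (default `1e-6`).
#' @return A one-row tibble `n, n_negative, fraction_negative` (fraction is
#'   `NA` when no gene passes the cutoff).
#' @export
sign_summary <- function(results, p_cut = 1e-6) {
  assert_columns(results, c("p", "sign", "skipped"), "correlation results")
  hit <- results[!results$skipped & !is.na(results$p) & results$p < p_cut, ]
  if (nrow(hit) == 0) {
    inform(sprintf("no genes with p < %g: sign bias undefined", p_cut))
    return(tibble(n = 0L, n_negative = 0L, fraction_negative = NA_real_))
  }
  tibble(
    n = nrow(hit),
    n_negative = sum(hit$sign == "negative"),
    fraction_negative = mean(hit$sign == "negative")
  )
}

#' Binomial enrichment of correlated genes
#'
#' One-sided upper-tail binomial probability of observing at least `n_hits`
#' correlated genes among `n_tested` when each gene has probability
#' `null_rate` of showing a correlation of that magnitude by chance.
#'
#' @param n_hits Number of genes passing the correlation threshold.
#' @param n_tested Number of genes tested.
#' @param null_rate Assumed chance rate (default 0.01).
#' @return A one-row tibble `n_hits, n_tested, observed_rate, null_rate,
#'   expected_hits, p_value, log10_p`.
#' @examples
#' correlated_fraction_test(748, 15975, 0.01)
#' @export
correlated_fraction_test <- function(n_hits, n_tested, null_rate = 0.01) {
  assert_scalar_number(n_hits, "n_hits", lower = 0)
  assert_scalar_number(n_tested, "n_tested", lower = 1)
  assert_scalar_number(null_rate, "null_rate", lower = 0, upper = 1)
  if (n_hits > n_tested) abort("n_hits cannot exceed n_tested")
  logp <- pbinom(n_hits - 1, n_tested, null_rate, lower.tail = FALSE,
                 log.p = TRUE)
  if (n_hits == 0) logp <- 0
  tibble(
    n_hits = as.integer(n_hits),
    n_tested = as.integer(n_tested),
    observed_rate = n_hits / n_tested,
    null_rate = null_rate,
    expected_hits = n_tested * null_rate,
    p_value = exp(logp),
    log10_p = logp / log(10)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (the standard BH procedure, via [stats::p.adjust()]) plus input
#' validation; ties are handled deterministically in stable order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed, propagated).
#' @return The vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("p-values must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Threshold hits of the correlation screen
#'
#' Applies the dual headline filter `|r| > r_cut` and `p < p_cut` to a
#' correlation result table.
#'
#' @param results A `vloh_cor` tibble.
#' @param r_cut Absolute correlation threshold (default 0.7).
#' @param p_cut P-value threshold (default 0.01).
#' @return The subset of `results` passing both thresholds.
#' @export
correlation_hits <- function(results, r_cut = 0.7, p_cut = 0.01) {
  assert_columns(results, c("r", "p", "skipped"), "correlation results")
  results[!results$skipped & !is.na(results$r) &
            abs(results$r) > r_cut & results$p < p_cut, , drop = FALSE]
}
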