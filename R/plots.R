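#' Plot per-tumor mean CAF along one chromosome
#'
#' One point per tumor (mean CAF over the chromosome's sites), with the
#' balanced 0.5 line and the 0.25/0.75 skew guides — the display used to
#' read X-inactivation clonality at a glance.
#'
#' @param caf CAF tibble from [compute_caf()].
#' @param chrom Chromosome to show.
#' @param low,high Skew guide positions.
#' @return A ggplot object.
#' @export
plot_chromosome_caf <- function(caf, chrom, low = 0.25, high = 0.75) {
  assert_columns(caf, c("chrom", "sample", "caf"), "CAF table")
  d <- caf[caf$chrom == chrom, , drop = FALSE] |>
    group_by(.data$sample) |>
    summarise(mean_caf = mean(.data$caf, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$mean_caf)) +
    ggplot2::geom_hline(yintercept = 0.5, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(low, high), linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "mean CAF",
                  title = sprintf("Mean BALB/c-allele frequency, %s", chrom)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Variegation tile plot of outlier flags
#'
#' Site-by-tumor tiles for one chromosome: white for a high outlier
#' (Z above threshold), black for a low outlier, grey for unflagged or
#' masked cells — the variegated-LOH display.
#'
#' @param calls A `vloh_outliers` object.
#' @param chrom Chromosome to show.
#' @return A ggplot object.
#' @export
plot_variegation <- function(calls, chrom) {
  stopifnot(inherits(calls, "vloh_outliers"))
  d <- calls$flags[calls$flags$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0) abort(sprintf("no sites on %s", chrom))
  d$state <- factor(
    dplyr::case_when(
      is.na(d$flag) ~ "masked",
      d$flag == 1 ~ "high outlier",
      d$flag == -1 ~ "low outlier",
      TRUE ~ "normal"
    ),
    levels = c("high outlier", "normal", "low outlier", "masked")
  )
  d$site <- factor(d$site_id, levels = unique(d$site_id[order(d$pos)]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site, y = .data$sample,
                                  fill = .data$state)) +
    ggplot2::geom_tile(color = "grey80", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(
      "high outlier" = "white", "normal" = "grey55",
      "low outlier" = "black", "masked" = "grey85"
    ), drop = FALSE) +
    ggplot2::labs(x = sprintf("eSNV along %s", chrom), y = NULL,
                  fill = NULL,
                  title = sprintf("Variegated allelic-ratio outliers, %s",
                                  chrom)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Burden-expression correlation panels
#'
#' Scatter of expression against per-tumor outlier burden for the top
#' correlated genes, with least-squares lines.
#'
#' @param results A `vloh_cor` tibble.
#' @param expression Long expression tibble used for the screen.
#' @param burden Burden tibble `sample, n_outliers`.
#' @param n_genes Number of top-|r| genes to display.
#' @return A ggplot object.
#' @export
plot_burden_correlation <- function(results, expression, burden,
                                    n_genes = 9) {
  assert_columns(results, c("gene_id", "r", "p", "skipped"),
                 "correlation results")
  top <- results[!results$skipped, ]
  top <- head(top[order(-abs(top$r)), ], n_genes)
  d <- expression[expression$gene_id %in% top$gene_id, , drop = FALSE]
  d <- inner_join(d, burden, by = "sample")
  d$gene_id <- factor(d$gene_id, levels = top$gene_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_outliers, y = .data$expr)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, color = "steelblue") +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "eSNV outlier burden", y = "expression (log2 RPKM)",
                  title = "Top burden-correlated genes") +
    ggplot2::theme_minimal()
}

#' @rdname plot_variegation
#' @param object A `vloh_outliers` object.
#' @param ... Passed on (must include `chrom`).
#' @method autoplot vloh_outliers
#' @export
autoplot.vloh_outliers <- function(object, ...) {
  args <- list(...)
  chrom <- args$chrom %||% object$flags$chrom[1]
  plot_variegation(object, chrom)
}
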