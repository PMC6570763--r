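#' Tidy outlier calls
#'
#' Returns the long (site, tumor) flag table of a `vloh_outliers` object.
#'
#' @param x A `vloh_outliers` object.
#' @param ... Unused.
#' @return A tibble `site_id, chrom, pos, gene_id, sample, caf, z, flag`.
#' @method tidy vloh_outliers
#' @export
tidy.vloh_outliers <- function(x, ...) {
  select(x$flags, -"masked")
}

#' One-row summary of outlier calls
#'
#' @param x A `vloh_outliers` object.
#' @param ... Unused.
#' @return A one-row tibble: entries, flags, gene counts and the fraction of
#'   genes with at least one outlier tumor.
#' @method glance vloh_outliers
#' @export
glance.vloh_outliers <- function(x, ...) {
  tibble(
    n_entries = sum(!is.na(x$flags$flag)),
    n_flagged = sum(abs(x$flags$flag) == 1, na.rm = TRUE),
    n_genes = nrow(x$gene_tumors),
    n_genes_with_outlier = sum(x$gene_tumors$n_tumor_outliers >= 1),
    fraction_genes_with_outlier =
      sum(x$gene_tumors$n_tumor_outliers >= 1) / max(nrow(x$gene_tumors), 1),
    z_thresh = x$params$z_thresh,
    boundary = x$params$boundary
  )
}

#' Tidy a correlation screen
#'
#' @param x A `vloh_cor` tibble.
#' @param ... Unused.
#' @return The underlying tibble, stripped of its class.
#' @method tidy vloh_cor
#' @export
tidy.vloh_cor <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "vloh_cor")
  as_tibble(out)
}

#' One-row summary of a correlation screen
#'
#' @param x A `vloh_cor` tibble.
#' @param r_cut,p_cut Hit thresholds (defaults 0.7, 0.01).
#' @param ... Unused.
#' @return A one-row tibble with tested/hit counts and sign balance.
#' @method glance vloh_cor
#' @export
glance.vloh_cor <- function(x, r_cut = 0.7, p_cut = 0.01, ...) {
  hits <- correlation_hits(x, r_cut = r_cut, p_cut = p_cut)
  tibble(
    n_genes = nrow(x),
    n_tested = sum(!x$skipped),
    n_hits = nrow(hits),
    hit_rate = nrow(hits) / max(sum(!x$skipped), 1),
    n_hits_negative = sum(hits$sign == "negative"),
    method = attr(x, "method") %||% "pearson",
    n_tumors = attr(x, "n_tumors") %||% NA_integer_
  )
}

#' @method glance vloh_enrichment
#' @export
glance.vloh_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "vloh_enrichment")
  as_tibble(out)
}
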