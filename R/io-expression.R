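#' Read a gene expression matrix
#'
#' Parses a TSV with a `gene_id` column followed by one numeric column per
#' sample; values are log2 RPKM-like expression levels. Duplicate gene ids
#' are an error; missing values are permitted but flagged with a warning.
#'
#' @param path File path.
#' @return A long tibble `gene_id, sample, expr`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  wide <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  assert_columns(wide, "gene_id", sprintf("expression table %s", basename(path)))
  if (ncol(wide) < 2) abort("expression table has no sample columns")
  dup <- wide$gene_id[duplicated(wide$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene id in expression table: %s", dup[1]))
  }
  samples <- setdiff(names(wide), "gene_id")
  n_miss <- sum(is.na(wide[, samples]))
  if (n_miss > 0) {
    warn(sprintf("expression table contains %d missing value(s); they are retained as NA",
                 n_miss))
  }
  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(samples),
                              names_to = "sample", values_to = "expr")
  long$sample <- factor(long$sample, levels = samples)
  long <- long[order(match(long$gene_id, wide$gene_id), as.integer(long$sample)), ]
  long$sample <- as.character(long$sample)
  as_tibble(long)
}

#' Write a gene expression matrix as TSV
#'
#' Inverse of [read_expression()]; genes sorted by id, samples in
#' first-appearance order.
#'
#' @param expression Long tibble `gene_id, sample, expr`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expression, path) {
  assert_columns(expression, c("gene_id", "sample", "expr"), "expression table")
  samples <- sample_levels(expression$sample)
  wide <- tidyr::pivot_wider(expression, id_cols = "gene_id",
                             names_from = "sample", values_from = "expr")
  wide <- wide[order(wide$gene_id), c("gene_id", samples)]
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
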