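#' Read a per-sample allele-count table
#'
#' Parses the package's count TSV dialect: header columns
#' `site_id, chrom, pos, gene_id` followed by one `<sample>_A` and one
#' `<sample>_B` column per sample (strain-A and strain-B read counts).
#' Counts must be non-negative integers; empty cells are an error, never a
#' silent drop. When a variant table is supplied every `site_id` must be
#' cross-referenced against it.
#'
#' @param path File path.
#' @param variants Optional variant tibble used for cross-referencing.
#' @return A long tibble with columns
#'   `site_id, chrom, pos, gene_id, sample, count_a, count_b`, sites in
#'   genome order and samples in file column order.
#' @export
read_counts <- function(path, variants = NULL) {
  if (!file.exists(path)) abort(sprintf("count file not found: %s", path))
  wide <- readr::read_tsv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  assert_columns(wide, c("site_id", "chrom", "pos", "gene_id"),
                 sprintf("count table %s", basename(path)))
  count_cols <- setdiff(names(wide), c("site_id", "chrom", "pos", "gene_id"))
  a_cols <- grep("_A$", count_cols, value = TRUE)
  b_cols <- grep("_B$", count_cols, value = TRUE)
  stray <- setdiff(count_cols, c(a_cols, b_cols))
  if (length(stray) > 0) {
    abort(sprintf("unrecognized count column(s): %s (expected <sample>_A/<sample>_B)",
                  paste(stray, collapse = ", ")))
  }
  samples <- sub("_A$", "", a_cols)
  if (!setequal(samples, sub("_B$", "", b_cols))) {
    abort("every sample needs both an _A and a _B column")
  }
  mats <- wide[, count_cols, drop = FALSE]
  if (anyNA(mats)) {
    miss <- which(colSums(is.na(mats)) > 0)
    abort(sprintf("missing count values in column(s): %s",
                  paste(names(mats)[miss], collapse = ", ")))
  }
  if (any(mats < 0)) abort("negative allele counts are not allowed")
  if (any(mats != floor(mats))) abort("allele counts must be integers")
  if (!is.null(variants)) {
    unknown <- setdiff(wide$site_id, variants$site_id)
    if (length(unknown) > 0) {
      abort(sprintf(
        "cross-reference error: %d site id(s) absent from the variant table (first: %s)",
        length(unknown), unknown[1]
      ))
    }
  }
  long <- tidyr::pivot_longer(
    wide,
    cols = dplyr::all_of(count_cols),
    names_to = c("sample", "strain"),
    names_pattern = "^(.*)_([AB])$",
    values_to = "count"
  )
  long <- tidyr::pivot_wider(long, names_from = "strain", values_from = "count",
                             names_prefix = "count_")
  long <- rename(long, count_a = "count_A", count_b = "count_B")
  long$sample <- factor(long$sample, levels = samples)
  long <- long[order(chrom_rank(long$chrom), long$pos, as.integer(long$sample)), ]
  long$sample <- as.character(long$sample)
  long$count_a <- as.integer(long$count_a)
  long$count_b <- as.integer(long$count_b)
  as_tibble(long[, c("site_id", "chrom", "pos", "gene_id", "sample",
                     "count_a", "count_b")])
}

#' Write a per-sample allele-count table as TSV
#'
#' Inverse of [read_counts()]: pivots the long count tibble to the wide
#' `<sample>_A`/`<sample>_B` dialect. Sites are written in genome order and
#' samples in first-appearance order, so output is byte-deterministic.
#'
#' @param counts Long count tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  assert_columns(counts, c("site_id", "chrom", "pos", "gene_id", "sample",
                           "count_a", "count_b"), "count table")
  if (any(counts$count_a < 0 | counts$count_b < 0)) {
    abort("negative allele counts are not allowed")
  }
  samples <- sample_levels(counts$sample)
  wide <- tidyr::pivot_wider(
    counts,
    id_cols = c("site_id", "chrom", "pos", "gene_id"),
    names_from = "sample",
    values_from = c("count_a", "count_b"),
    names_glue = "{sample}_{ifelse(.value == 'count_a', 'A', 'B')}"
  )
  ordered_cols <- c("site_id", "chrom", "pos", "gene_id",
                    as.vector(rbind(paste0(samples, "_A"), paste0(samples, "_B"))))
  wide <- wide[, ordered_cols]
  wide <- wide[order(chrom_rank(wide$chrom), wide$pos), ]
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
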