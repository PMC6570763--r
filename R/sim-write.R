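#' Write a simulated dataset and its truth manifest to disk
#'
#' Emits `variants.tsv`, `counts.tsv` and `expression.tsv` in the package's
#' standard TSV dialects (see [read_variants()], [read_counts()],
#' [read_expression()]) plus `truth.yaml`, a versioned YAML ground-truth
#' manifest (`schema_version: 1`) recording the silenced X parent per tumor,
#' lost-chromosome events, the deleted segment, every planted
#' (gene, tumor, direction) outlier, the repressed genes with their true
#' slope, and the full generating configuration. Output is deterministic:
#' the same dataset always produces byte-identical files.
#'
#' @param sim A `vloh_sim` object from [simulate_ase()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_sim <- function(sim, out_dir) {
  if (!inherits(sim, "vloh_sim")) abort("`sim` must come from simulate_ase()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    variants = file.path(out_dir, "variants.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    truth = file.path(out_dir, "truth.yaml")
  )
  write_variants(sim$variants, paths[["variants"]])
  write_counts(sim$counts, paths[["counts"]])
  write_expression(sim$expression, paths[["expression"]])
  write_truth(sim$truth, paths[["truth"]])
  invisible(paths)
}

write_truth <- function(truth, path) {
  cfg <- unclass(truth$config)
  cfg$n_sites_per_chrom <- as.list(cfg$n_sites_per_chrom)
  doc <- list(
    schema_version = truth$schema_version,
    x_inactivated_parent = purrr::transpose(as.list(truth$x_inactivated_parent)),
    lost_chromosome_events = purrr::transpose(as.list(truth$lost_chromosome_events)),
    deleted_segment = truth$deleted_segment,
    planted_outliers = purrr::transpose(as.list(truth$planted_outliers)),
    repressed_genes = purrr::transpose(as.list(truth$repressed_genes)),
    planted_burden = purrr::transpose(as.list(truth$planted_burden)),
    config = cfg
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a simulation truth manifest
#'
#' Parses a `truth.yaml` manifest written by [write_sim()] back into the
#' in-memory `vloh_sim_truth` layout (tibbles of events).
#'
#' @param path Path to `truth.yaml`.
#' @return A `vloh_sim_truth` list.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) abort(sprintf("truth manifest not found: %s", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    abort(sprintf("unsupported truth manifest schema_version in %s", path))
  }
  rebind <- function(records, cols) {
    if (length(records) == 0) {
      return(as_tibble(setNames(rep(list(character(0)), length(cols)), cols)))
    }
    as_tibble(purrr::map_dfr(records, ~ as_tibble(.x)))
  }
  structure(
    list(
      schema_version = 1L,
      x_inactivated_parent = rebind(doc$x_inactivated_parent, c("sample", "silenced")),
      lost_chromosome_events = rebind(doc$lost_chromosome_events, c("sample", "chrom")),
      deleted_segment = doc$deleted_segment,
      planted_outliers = rebind(doc$planted_outliers, c("gene_id", "sample", "direction")),
      repressed_genes = rebind(doc$repressed_genes, c("gene_id", "slope")),
      planted_burden = rebind(doc$planted_burden, c("sample", "n_planted")),
      config = doc$config
    ),
    class = "vloh_sim_truth"
  )
}
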