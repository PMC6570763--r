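# Small in-code fixtures shared across tests.

# A minimal long count table: `caf_rows` is a list of numeric vectors, one
# per site (length = n samples); counts are scaled to the requested depth.
make_counts <- function(caf_rows, depth = 100, chrom = NULL, pos = NULL,
                        gene = NULL, samples = NULL) {
  n_sites <- length(caf_rows)
  n_samp <- length(caf_rows[[1]])
  if (is.null(samples)) samples <- sprintf("T%02d", seq_len(n_samp))
  if (is.null(chrom)) chrom <- rep("chr1", n_sites)
  if (is.null(pos)) pos <- seq_len(n_sites) * 1000L
  if (is.null(gene)) gene <- paste0("g", seq_len(n_sites))
  purrr::map_dfr(seq_len(n_sites), function(i) {
    b <- round(caf_rows[[i]] * depth)
    tibble::tibble(
      site_id = paste0(chrom[i], ":", pos[i]),
      chrom = chrom[i], pos = as.integer(pos[i]), gene_id = gene[i],
      sample = samples,
      count_a = as.integer(depth - b), count_b = as.integer(b)
    )
  })
}

# Small simulated dataset for pipeline-level tests: 2 autosomes + X.
small_sim <- function(seed = 101, ...) {
  simulate_ase(sim_config(
    n_tumors = 10,
    n_sites_per_chrom = c(chr1 = 60, chr2 = 60, chrX = 30),
    lost_chromosome = "chr2",
    deleted_segment = NULL,
    depth_mean = 120,
    seed = seed,
    ...
  ))
}
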