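test_that("invalid configurations are rejected", {
  expect_error(sim_config(depth_mean = 0), "depth_mean")
  expect_error(sim_config(depth_mean = -5), "depth_mean")
  expect_error(sim_config(outlier_delta = 0), "outlier_delta")
  expect_error(sim_config(outlier_delta = 0.6), "outlier_delta")
  expect_error(sim_config(overdispersion_rho = 1), "overdispersion_rho")
  expect_error(sim_config(deleted_segment = list("chr1", 100, 100)), "start")
  expect_error(sim_config(deleted_segment_caf = 0.5), "deleted_segment_caf")
})

test_that("the same config and seed reproduce the dataset exactly", {
  cfg <- sim_config(n_tumors = 6, n_sites_per_chrom = c(chr1 = 40, chrX = 20),
                    seed = 33)
  s1 <- simulate_ase(cfg)
  s2 <- simulate_ase(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$truth$planted_outliers, s2$truth$planted_outliers)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_ase(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("counts conserve depth and respect planted clonal events", {
  sim <- simulate_ase(sim_config(
    n_tumors = 8, n_sites_per_chrom = c(chr1 = 40, chr7 = 60, chrX = 20),
    lost_chromosome = NULL,
    deleted_segment = list("chr7", 0, 5e7), deleted_segment_caf = 0,
    seed = 12
  ))
  expect_true(all(sim$counts$count_a >= 0 & sim$counts$count_b >= 0))
  # X-inactivation forces every tumor's chrX mean CAF outside (0.25, 0.75)
  caf <- compute_caf(sim$counts)
  xmean <- call_clonality(caf)$chrx_mean_caf
  expect_true(all(xmean < 0.25 | xmean > 0.75))
  # silenced parent in the manifest matches the direction of the skew
  truth <- sim$truth$x_inactivated_parent
  expect_identical(
    unname(ifelse(xmean < 0.25, "B-silenced", "A-silenced")),
    truth$silenced[match(call_clonality(caf)$sample, truth$sample)]
  )
  # deleted segment: BALB allele gone entirely, CAF exactly 0
  seg <- dplyr::filter(sim$counts, chrom == "chr7", pos - 1 < 5e7)
  expect_gt(nrow(seg), 0)
  expect_true(all(seg$count_b == 0))
})

test_that("lost chromosome pulls every tumor toward the residual CAF", {
  sim <- small_sim(seed = 7)
  caf <- compute_caf(sim$counts)
  chr2 <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(caf, chrom == "chr2"), sample),
    m = mean(caf, na.rm = TRUE)
  )
  expect_true(all(chr2$m < 0.25))
})

test_that("baseline CAF marginals match the configured center and spread", {
  sim <- simulate_ase(sim_config(
    n_tumors = 20, n_sites_per_chrom = c(chr1 = 2500, chr2 = 2500),
    x_inactivation = FALSE, lost_chromosome = NULL, deleted_segment = NULL,
    outlier_rate = 0, depth_mean = 500, overdispersion_rho = 0, seed = 21
  ))
  s <- summarize_caf(compute_caf(sim$counts))
  expect_equal(s$mean_caf, 0.511, tolerance = 0.01)
  expect_equal(s$sd_caf, 0.096, tolerance = 0.011)
})

test_that("recovery sensitivity does not decrease with outlier_delta", {
  sens <- vapply(c(0.2, 0.4), function(delta) {
    sim <- simulate_ase(sim_config(
      n_tumors = 12, n_sites_per_chrom = c(chr1 = 120, chrX = 20),
      lost_chromosome = NULL, deleted_segment = NULL,
      outlier_rate = 0.05, outlier_delta = delta, depth_mean = 150,
      seed = 404
    ))
    caf <- compute_caf(sim$counts)
    calls <- call_outliers(caf_zscores(caf, mask = build_mask(NULL)))
    hits <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(calls$flags, !is.na(flag)),
                      gene_id, sample),
      hit = any(abs(flag) == 1), .groups = "drop")
    m <- dplyr::inner_join(sim$truth$planted_outliers, hits,
                           by = c("gene_id", "sample"))
    mean(m$hit)
  }, 0)
  expect_gte(sens[2], sens[1])
})

test_that("written fixtures round-trip and are byte-deterministic", {
  sim <- small_sim(seed = 55)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_sim(sim, d1)
  write_sim(simulate_ase(sim$truth$config), d2)
  for (f in basename(p1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), info = f)
  }
  v <- read_variants(p1[["variants"]])
  cts <- read_counts(p1[["counts"]], variants = v)
  expr <- read_expression(p1[["expression"]])
  expect_equal(v, sim$variants)
  expect_equal(cts, sim$counts)
  expect_equal(expr, sim$expression)
  truth <- read_truth(p1[["truth"]])
  expect_equal(truth$planted_outliers, sim$truth$planted_outliers)
  # referential integrity of the manifest
  expect_true(all(truth$planted_outliers$gene_id %in% v$gene_id))
  expect_true(all(truth$repressed_genes$gene_id %in% v$gene_id))
})
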