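test_that("Z-scores use include-self cohort mean/SD and center to zero", {
  # 19 tumors at 0.5 and one at 0.9: mean 0.52, sd sqrt(0.152/19)
  vals <- c(rep(0.5, 19), 0.9)
  caf <- caf_tibble_from_matrix(matrix(vals, nrow = 1), gene = "g1")
  z <- caf_zscores(caf)
  m <- mean(vals)
  s <- sd(vals)
  expect_equal(z$z, (vals - m) / s)
  expect_gt(z$z[20], 2)
  expect_equal(sum(z$z), 0, tolerance = 1e-12)
  # leave-one-out is even more extreme for an aberrant sample
  vals2 <- c(0.48, 0.52, 0.49, 0.51, 0.5, 0.47, 0.53, 0.5, 0.46, 0.9)
  caf2 <- caf_tibble_from_matrix(matrix(vals2, nrow = 1), gene = "g1")
  expect_gt(caf_zscores(caf2, method = "loo")$z[10],
            caf_zscores(caf2)$z[10])

  # constant rows have no SD and are excluded with a report
  const <- caf_tibble_from_matrix(matrix(rep(0.5, 20), nrow = 1), gene = "g1")
  expect_message(zc <- caf_zscores(const), "excluded")
  expect_true(all(is.na(zc$z)))
  expect_equal(attr(zc, "excluded_sites"), "chr1:100")

  # strain relabeling flips the sign of every Z
  flipped <- caf
  flipped$caf <- 1 - flipped$caf
  expect_equal(caf_zscores(flipped)$z, -z$z)
})

test_that("outlier flags honor the threshold boundary convention", {
  z <- tibble::tibble(
    site_id = "chr1:100", chrom = "chr1", pos = 100L, gene_id = "g1",
    sample = sprintf("T%02d", 1:4),
    caf = NA_real_, z = c(-2.5, 0, 2, 1.9), masked = FALSE
  )
  incl <- call_outliers(z, z_thresh = 2, boundary = "inclusive")
  expect_equal(incl$flags$flag, c(-1L, 0L, 1L, 0L))
  excl <- call_outliers(z, z_thresh = 2, boundary = "exclusive")
  expect_equal(excl$flags$flag, c(-1L, 0L, 0L, 0L))
  # all-zero Z means zero counts everywhere
  z0 <- dplyr::mutate(z, z = 0)
  expect_equal(sum(call_outliers(z0)$tumor_burden$n_outliers), 0L)
})

test_that("adding a masked site changes no flags or counts", {
  sim <- small_sim(seed = 71)
  caf <- compute_caf(filter_sites(sim$counts))
  mask <- build_mask(scan_concerted_loh(caf))
  base <- call_outliers(caf_zscores(caf, mask = mask))
  # duplicate one chr1 site into the masked chr2 territory
  sid <- caf$site_id[1]
  extra_src <- dplyr::filter(caf, site_id == sid)
  extra <- dplyr::mutate(extra_src, chrom = "chr2", pos = 1L,
                         site_id = "chr2:1", gene_id = "g_extra")
  aug <- call_outliers(caf_zscores(dplyr::bind_rows(caf, extra), mask = mask))
  expect_equal(aug$tumor_burden, base$tumor_burden)
  expect_equal(
    dplyr::filter(aug$flags, site_id != "chr2:1"),
    base$flags
  )
})

test_that("pipeline matches the brute-force oracle on random instances", {
  withr::local_seed(2024)
  for (rep in 1:25) {
    n_sites <- sample(3:10, 1)
    n_samp <- 20
    caf_m <- matrix(pmin(pmax(rnorm(n_sites * n_samp, 0.5, 0.12), 0), 1),
                    nrow = n_sites)
    caf_m[sample(length(caf_m), 3)] <- NA
    gene <- paste0("g", sample(1:3, n_sites, replace = TRUE))
    masked <- sample(c(TRUE, FALSE), n_sites, replace = TRUE, prob = c(.2, .8))
    chrom <- ifelse(masked, "chrM", "chr1")
    mask <- region_mask("chrM", 0, 1e9, "test")
    oracle <- oracle_outliers(caf_m, gene, masked)
    caf_tbl <- caf_tibble_from_matrix(caf_m, gene, chrom = chrom)
    calls <- suppressMessages(
      call_outliers(caf_zscores(caf_tbl, mask = mask)))
    z_mat <- matrix(calls$flags$z, nrow = n_sites, byrow = TRUE)
    expect_equal(z_mat, oracle$z)
    expect_equal(calls$tumor_burden$n_outliers, oracle$tumor_counts)
    got_genes <- calls$gene_tumors
    expect_equal(
      setNames(got_genes$n_tumor_outliers, got_genes$gene_id)[names(sort(oracle$gene_counts))],
      sort(oracle$gene_counts)
    )
  }
})

test_that("Poisson zero-outlier expectation matches the analytic value", {
  expect_equal(round(poisson_zero_expectation(20, 1 / 20), 4), 0.3679)
  expect_equal(round(1 - poisson_zero_expectation(20, 1 / 20), 4), 0.6321)
  expect_equal(poisson_zero_expectation(20, 0), 1)
  expect_error(poisson_zero_expectation(20, 1.5), "per_sample_rate")
})

test_that("enrichment test agrees with exact enumeration and has a calibrated center", {
  # small case: full enumeration of the binomial lower tail
  p0 <- poisson_zero_expectation(4, 0.25)
  enum <- sum(vapply(0:2, function(k) {
    choose(5, k) * p0^k * (1 - p0)^(5 - k)
  }, 0))
  res <- enrichment_test(n_samples = 4, per_sample_rate = 0.25,
                         n_genes = 5, n_with_outlier = 3)
  expect_equal(res$p_value, enum, tolerance = 1e-12)
  # observing exactly the expectation is not significant
  n_genes <- 1000
  k_expected <- round(n_genes * poisson_zero_expectation(20, 1 / 20))
  center <- enrichment_test(n_samples = 20, n_genes = n_genes,
                            n_with_outlier = n_genes - k_expected)
  expect_gte(center$p_value, 0.5)
  # large n switches to the continuity-corrected normal approximation
  big <- enrichment_test(n_samples = 20, n_genes = 2e4,
                         n_with_outlier = 14000)
  expect_equal(big$method, "normal-approximation")
  expect_error(enrichment_test(n_samples = 20, n_genes = 0,
                               n_with_outlier = 0), "at least one gene")
})

test_that("variegation report localizes events and its histogram is complete", {
  sim <- simulate_ase(sim_config(
    n_tumors = 10, n_sites_per_chrom = c(chr1 = 90, chrX = 15),
    lost_chromosome = NULL, deleted_segment = NULL,
    outlier_rate = 0, seed = 83
  ))
  counts <- sim$counts
  # plant one gene-level event by hand: gene of site 1, tumor T05, CAF -> ~0
  g <- counts$gene_id[1]
  pick <- counts$gene_id == g & counts$sample == "T05"
  counts$count_a[pick] <- counts$count_a[pick] + counts$count_b[pick]
  counts$count_b[pick] <- 0L
  calls <- call_outliers(caf_zscores(compute_caf(counts),
                                     mask = build_mask(NULL)))
  rep <- variegation_report(calls)
  in_gene <- dplyr::filter(rep$cells, gene_id == g)
  expect_true(all(in_gene$flag[in_gene$sample == "T05"] == -1))
  expect_true(all(in_gene$flag[in_gene$sample != "T05"] == 0))
  expect_equal(sum(rep$multiplicity$n_genes), nrow(calls$gene_tumors))
})

test_that("null gene-level zero-outlier fraction reflects site independence", {
  # within a gene the sites are sampled independently, so the fraction of
  # zero-outlier genes should equal the per-site zero-outlier probability
  # raised to the sites-per-gene power (within-site flags across tumors are
  # strongly dependent, so no Poisson/binomial form is assumed here)
  sim <- simulate_ase(sim_config(
    n_tumors = 20, n_sites_per_chrom = c(chr1 = 1500), sites_per_gene = 3,
    x_inactivation = FALSE, lost_chromosome = NULL, deleted_segment = NULL,
    outlier_rate = 0, depth_mean = 5000, overdispersion_rho = 0, seed = 91
  ))
  calls <- call_outliers(caf_zscores(compute_caf(sim$counts),
                                     mask = build_mask(NULL)))
  site_zero <- calls$flags |>
    dplyr::filter(!is.na(flag)) |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(zero = all(flag == 0), .groups = "drop")
  q_site <- mean(site_zero$zero)
  mult <- variegation_report(calls)$multiplicity
  n_genes <- sum(mult$n_genes)
  obs_zero <- sum(mult$n_genes[mult$n_tumor_outliers == 0]) / n_genes
  se <- sqrt(obs_zero * (1 - obs_zero) / n_genes)
  expect_lt(abs(obs_zero - q_site^3), 3 * se + 0.01)
  expect_equal(sum(mult$n_genes), nrow(calls$gene_tumors))
})
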