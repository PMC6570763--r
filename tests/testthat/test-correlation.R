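expr_fixture <- function(mat, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("T%02d", seq_len(ncol(mat)))
  purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    tibble::tibble(gene_id = rownames(mat)[i], sample = samples,
                   expr = mat[i, ])
  })
}

test_that("expression filter keeps genes at or above the floor", {
  mat <- rbind(gA = rep(0.5, 6), gB = rep(0.49, 6), gC = rep(5, 6))
  expr <- expr_fixture(mat)
  kept <- filter_expressed(expr, min_level = 0.5)
  expect_setequal(unique(kept$gene_id), c("gA", "gC"))
  # disabled mode keeps everything
  expect_setequal(unique(filter_expressed(expr, min_level = -Inf)$gene_id),
                  c("gA", "gB", "gC"))
  # the mean is taken over the retained tumors only
  mat2 <- rbind(gD = c(10, 10, 10, -5, -5, -5))
  kept2 <- filter_expressed(expr_fixture(mat2), min_level = 0.5,
                            samples = sprintf("T%02d", 1:3))
  expect_equal(unique(kept2$gene_id), "gD")
})

test_that("burden correlation recovers exact linear coupling and skips degenerates", {
  burden <- tibble::tibble(sample = sprintf("T%02d", 1:8),
                           n_outliers = c(3, 9, 1, 14, 6, 2, 11, 7))
  mat <- rbind(
    neg = 10 - 0.5 * burden$n_outliers,
    flat = rep(2, 8),
    noisy = 5 + c(.3, -.2, .1, -.4, .2, 0, -.1, .25)
  )
  expr <- expr_fixture(mat)
  res <- suppressMessages(correlate_burden(expr, burden))
  neg <- dplyr::filter(res, gene_id == "neg")
  expect_equal(neg$r, -1)
  expect_lt(neg$p, 1e-12)
  expect_equal(neg$sign, "negative")
  expect_true(dplyr::filter(res, gene_id == "flat")$skipped)
  # q-values are BH over tested genes only
  tested <- dplyr::filter(res, !skipped)
  expect_equal(tested$q, oracle_bh(tested$p))
  # affine rescaling of burden leaves Pearson results unchanged
  res2 <- suppressMessages(correlate_burden(
    expr, dplyr::mutate(burden, n_outliers = 10 * n_outliers + 3)))
  expect_equal(res2$r, res$r)
  expect_equal(res2$p, res$p)
  # too few common tumors is an error
  expect_error(correlate_burden(expr, burden[1:3, ]), ">= 4 tumors")
})

test_that("sign summary reports the negative fraction or declares it undefined", {
  res <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    r = c(-.9, -.95, .92, -.99, .1, NA),
    p = c(1e-9, 1e-8, 1e-10, 1e-12, 0.5, NA),
    q = NA_real_,
    sign = c("negative", "negative", "positive", "negative", "positive",
             "positive"),
    n = 12L, skipped = c(rep(FALSE, 5), TRUE)
  )
  s <- sign_summary(res, p_cut = 1e-6)
  expect_equal(s$n, 4L)
  expect_equal(s$fraction_negative, 0.75)
  empty <- suppressMessages(sign_summary(res, p_cut = 1e-20))
  expect_true(is.na(empty$fraction_negative))
  # symmetric planted slopes give a balanced split
  burden <- tibble::tibble(sample = sprintf("T%02d", 1:10),
                           n_outliers = 1:10)
  mat <- rbind(up = burden$n_outliers, dn = -burden$n_outliers)
  sym <- suppressMessages(correlate_burden(expr_fixture(mat), burden))
  expect_equal(sign_summary(sym, p_cut = 0.05)$fraction_negative, 0.5)
})

test_that("correlated-fraction binomial tail matches enumeration", {
  tiny <- correlated_fraction_test(2, 10, 0.1)
  enum <- sum(vapply(2:10, function(k) choose(10, k) * 0.1^k * 0.9^(10 - k), 0))
  expect_equal(tiny$p_value, enum, tolerance = 1e-12)
  expect_equal(correlated_fraction_test(0, 100, 0.01)$p_value, 1)
  expect_error(correlated_fraction_test(11, 10), "exceed")
})

test_that("BH adjustment matches the hand-computed step-up", {
  p <- c(0.01, 0.04, 0.03, 0.005, 0.9)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # ties are deterministic and order-stable
  pt <- c(0.02, 0.02, 0.5)
  expect_equal(bh_adjust(pt), oracle_bh(pt))
})

test_that("null correlation screen is calibrated at the nominal level", {
  withr::local_seed(515)
  n_genes <- 1500
  burden <- tibble::tibble(sample = sprintf("T%02d", 1:12),
                           n_outliers = rpois(12, 50))
  mat <- matrix(rnorm(n_genes * 12, 5, 1), nrow = n_genes,
                dimnames = list(paste0("g", seq_len(n_genes)), NULL))
  res <- correlate_burden(expr_fixture(mat), burden)
  frac <- mean(res$p < 0.01, na.rm = TRUE)
  se <- sqrt(0.01 * 0.99 / n_genes)
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("repressed genes are recovered with matching sign", {
  sim <- simulate_ase(sim_config(
    n_tumors = 16, n_sites_per_chrom = c(chr1 = 600, chrX = 20),
    lost_chromosome = NULL, deleted_segment = NULL, seed = 61
  ))
  caf <- compute_caf(filter_sites(sim$counts))
  calls <- call_outliers(caf_zscores(caf, mask = build_mask(NULL)))
  res <- suppressMessages(
    correlate_burden(sim$expression, outlier_burden(calls)))
  hits <- correlation_hits(res)
  rep_genes <- sim$truth$repressed_genes$gene_id
  expect_gte(mean(rep_genes %in% hits$gene_id), 0.9)
  expect_true(all(hits$sign[hits$gene_id %in% rep_genes] == "negative"))
})
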