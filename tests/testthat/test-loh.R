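clonality_fixture <- function(x_means, autosome_caf = 0.5) {
  n <- length(x_means)
  rows <- list(rep(autosome_caf, n), x_means, x_means)
  make_counts(rows, depth = 1000,
              chrom = c("chr1", "chrX", "chrX"),
              pos = c(100L, 100L, 200L),
              gene = c("a1", "x1", "x2"))
}

test_that("clonality calls use strict skew thresholds on chrX means", {
  caf <- compute_caf(clonality_fixture(c(0.10, 0.50, 0.75, 0.90)))
  calls <- call_clonality(caf)
  expect_equal(calls$call,
               c("clonal-B-silenced", "not-skewed", "not-skewed",
                 "clonal-A-silenced"))
  expect_equal(calls$chrx_mean_caf, c(0.10, 0.50, 0.75, 0.90))
  # boundary: exactly 0.75 is NOT skewed (strict inequality)
  expect_equal(calls$call[3], "not-skewed")
  # autosome data and site order do not affect the call
  caf2 <- compute_caf(clonality_fixture(c(0.10, 0.50, 0.75, 0.90),
                                        autosome_caf = 0.05))
  expect_equal(call_clonality(caf2)$call, calls$call)
  expect_equal(call_clonality(caf[rev(seq_len(nrow(caf))), ])$call, calls$call)
  # missing chrX is an error
  auto_only <- dplyr::filter(caf, chrom != "chrX")
  expect_error(call_clonality(auto_only), "no chrX sites")
})

test_that("a cohort-wide lost chromosome is flagged on all tumors", {
  sim <- small_sim(seed = 17)   # chr2 monosomy, residual CAF 0.15
  caf <- compute_caf(filter_sites(sim$counts))
  reg <- scan_concerted_loh(caf)
  chr2 <- dplyr::filter(reg, region_type == "chromosome", chrom == "chr2")
  expect_equal(chr2$verdict, "concerted-LOH")
  expect_equal(chr2$frac_skewed_tumors, 1)
  expect_lt(chr2$mean_caf, 0.25)
  expect_lte(chr2$p_value, 1e-3)
  # balanced autosome is not flagged
  chr1 <- dplyr::filter(reg, region_type == "chromosome", chrom == "chr1")
  expect_equal(chr1$verdict, "balanced")
})

test_that("a fully deleted segment is detected as a skewed run", {
  sim <- simulate_ase(sim_config(
    n_tumors = 10, n_sites_per_chrom = c(chr1 = 80, chr7 = 100, chrX = 20),
    lost_chromosome = NULL,
    deleted_segment = list("chr7", 0, 6e7), deleted_segment_caf = 0,
    depth_mean = 150, seed = 23
  ))
  # unfiltered CAF: the minor-allele filter would remove hemizygous sites
  caf <- compute_caf(sim$counts)
  reg <- scan_concerted_loh(caf)
  seg <- dplyr::filter(reg, region_type == "segment", chrom == "chr7",
                       verdict == "concerted-LOH")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$mean_caf, 0)
  expect_lt(seg$end, 6e7 + 1)
})

test_that("event-free data produces no concerted-LOH flags", {
  sim <- simulate_ase(sim_config(
    n_tumors = 12, n_sites_per_chrom = c(chr1 = 200, chr2 = 200),
    x_inactivation = FALSE, lost_chromosome = NULL, deleted_segment = NULL,
    outlier_rate = 0, seed = 31
  ))
  caf <- compute_caf(sim$counts)
  reg <- scan_concerted_loh(caf)
  expect_equal(sum(reg$verdict == "concerted-LOH"), 0)
  # masking then re-scanning stays clean
  mask <- build_mask(reg)
  kept <- caf[!caf$chrom %in% "chrX", ]
  expect_equal(sum(scan_concerted_loh(kept)$verdict == "concerted-LOH"), 0)
})

test_that("the exclusion mask unions chrX, flagged regions and user extras", {
  base <- build_mask(NULL)
  expect_equal(base$chrom, "chrX")
  expect_equal(base$name, "chrX-clonality")

  sim <- small_sim(seed = 17)
  reg <- scan_concerted_loh(compute_caf(filter_sites(sim$counts)))
  user <- region_mask("chr1", 0, 5e6, "user")
  m <- build_mask(reg, extra = user)
  expect_setequal(m$chrom, c("chr1", "chr2", "chrX"))
  # overlapping extras merge with the flagged chromosome interval
  overlap <- region_mask("chr2", 1000, 2000, "user")
  m2 <- build_mask(reg, extra = overlap)
  expect_equal(sum(m2$chrom == "chr2"), 1)
  expect_match(m2$name[m2$chrom == "chr2"], "concerted-LOH")
})

test_that("tumors with private chromosome-scale skew are excluded from burden", {
  sim <- small_sim(seed = 17)
  counts <- sim$counts
  # give one tumor a private loss of chr1 (BALB reads wiped out)
  pick <- counts$chrom == "chr1" & counts$sample == "T03"
  counts$count_a[pick] <- counts$count_a[pick] + counts$count_b[pick]
  counts$count_b[pick] <- 0L
  caf <- compute_caf(counts)
  mask <- build_mask(scan_concerted_loh(caf))
  rt <- retained_tumors(caf, mask)
  expect_false(rt$retained[rt$sample == "T03"])
  expect_match(rt$offending_chroms[rt$sample == "T03"], "chr1")
  expect_true(all(rt$retained[rt$sample != "T03"]))
})
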