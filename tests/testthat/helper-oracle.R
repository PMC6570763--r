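# Independent brute-force reimplementation of the Z-score / outlier-calling
# arithmetic, written as straight-line loops from first principles. Used to
# cross-check the package's vectorized pipeline; deliberately shares no code
# with it.

# caf: sites x samples numeric matrix (NA allowed); gene: per-site gene id;
# masked: per-site logical. Include-self mean/SD (n - 1), flags at
# |Z| >= thresh (inclusive) or > thresh (exclusive).
oracle_outliers <- function(caf, gene, masked, z_thresh = 2,
                            inclusive = TRUE, min_n = 3) {
  n_sites <- nrow(caf)
  n_samp <- ncol(caf)
  z <- matrix(NA_real_, n_sites, n_samp)
  flag <- matrix(NA_integer_, n_sites, n_samp)
  for (i in seq_len(n_sites)) {
    if (masked[i]) next
    vals <- caf[i, ]
    ok <- !is.na(vals)
    if (sum(ok) < min_n) next
    m <- sum(vals[ok]) / sum(ok)
    ss <- 0
    for (v in vals[ok]) ss <- ss + (v - m)^2
    s <- sqrt(ss / (sum(ok) - 1))
    if (s == 0) next
    for (j in seq_len(n_samp)) {
      if (!ok[j]) next
      z[i, j] <- (vals[j] - m) / s
      hit_hi <- if (inclusive) z[i, j] >= z_thresh else z[i, j] > z_thresh
      hit_lo <- if (inclusive) z[i, j] <= -z_thresh else z[i, j] < -z_thresh
      flag[i, j] <- if (hit_hi) 1L else if (hit_lo) -1L else 0L
    }
  }
  tumor_counts <- integer(n_samp)
  for (j in seq_len(n_samp)) {
    cnt <- 0L
    for (i in seq_len(n_sites)) {
      if (!is.na(flag[i, j]) && abs(flag[i, j]) == 1L) cnt <- cnt + 1L
    }
    tumor_counts[j] <- cnt
  }
  genes <- unique(gene[!masked])
  gene_counts <- integer(length(genes))
  names(gene_counts) <- genes
  for (g in genes) {
    rows <- which(gene == g & !masked)
    cnt <- 0L
    for (j in seq_len(n_samp)) {
      any_hit <- FALSE
      for (i in rows) {
        if (!is.na(flag[i, j]) && abs(flag[i, j]) == 1L) any_hit <- TRUE
      }
      if (any_hit) cnt <- cnt + 1L
    }
    gene_counts[g] <- cnt
  }
  list(z = z, flag = flag, tumor_counts = tumor_counts,
       gene_counts = gene_counts)
}

# Assemble a long CAF tibble from a matrix, for feeding the package side.
caf_tibble_from_matrix <- function(caf, gene, chrom = NULL, pos = NULL) {
  n_sites <- nrow(caf)
  n_samp <- ncol(caf)
  if (is.null(chrom)) chrom <- rep("chr1", n_sites)
  if (is.null(pos)) pos <- seq_len(n_sites) * 100L
  samples <- sprintf("T%02d", seq_len(n_samp))
  purrr::map_dfr(seq_len(n_sites), function(i) {
    tibble::tibble(
      site_id = paste0(chrom[i], ":", pos[i]), chrom = chrom[i],
      pos = as.integer(pos[i]), gene_id = gene[i], sample = samples,
      count_a = NA_integer_, count_b = NA_integer_, total = NA_integer_,
      caf = caf[i, ]
    )
  })
}

# Hand-rolled Benjamini-Hochberg step-up, independent of stats::p.adjust.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- ranked * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Vectorized Monte-Carlo oracle for the no-event null: draws sites from the
# generator's stated null (truncated-Gaussian site CAF, negative-binomial
# depth, binomial counts), standardizes each site across samples with
# include-self mean/SD, and measures outlier rates. Matrix arithmetic only;
# shares no code with the package pipeline.
oracle_null_mc <- function(n_sites, n_samp = 20, depth_mean = 10000,
                           depth_size = 5, center = 0.511, spread = 0.096,
                           z_thresh = 2, sites_per_gene = 3) {
  p <- pmin(pmax(rnorm(n_sites, center, spread), 0.05), 0.95)
  depth <- matrix(rnbinom(n_sites * n_samp, mu = depth_mean, size = depth_size),
                  nrow = n_sites)
  b <- matrix(rbinom(n_sites * n_samp, as.vector(depth), rep(p, n_samp)),
              nrow = n_sites)
  caf <- ifelse(depth > 0, b / depth, NA)
  m <- rowMeans(caf, na.rm = TRUE)
  nn <- rowSums(!is.na(caf))
  s <- sqrt(rowSums((caf - m)^2, na.rm = TRUE) / (nn - 1))
  z <- (caf - m) / s
  hit <- !is.na(z) & abs(z) >= z_thresh
  per_site_rate <- rowSums(hit) / nn
  site_zero <- rowSums(hit) == 0
  n_genes <- floor(n_sites / sites_per_gene)
  gene_of <- rep(seq_len(n_genes), each = sites_per_gene)[seq_len(n_sites)]
  gene_zero <- tapply(site_zero, gene_of, all)
  list(
    rate = mean(hit[!is.na(z)]),
    rate_se = sd(per_site_rate) / sqrt(n_sites),
    site_zero_frac = mean(site_zero),
    gene_zero_frac = mean(gene_zero),
    gene_zero_se = sqrt(mean(gene_zero) * (1 - mean(gene_zero)) / n_genes)
  )
}
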