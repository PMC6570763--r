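#' Configuration for the F1 allele-specific-expression simulator
#'
#' Builds and validates the parameter set consumed by [simulate_ase()]. The
#' defaults describe a cohort resembling a clonal F1 tumor study: 20 tumors,
#' roughly 12,000 expressed SNV sites spread over 19 autosomes plus the X
#' chromosome, a per-site baseline BALB/c-allele frequency (CAF) centered at
#' 0.511 with SD 0.096 across sites, clonal X-inactivation in every tumor,
#' one whole-autosome loss shared by the whole cohort (chr4), a fully
#' hemizygous deleted segment at the start of chr7, sparse single-tumor
#' allelic-repression events, and a subset of genes whose expression is
#' negatively coupled to each tumor's planted event burden.
#'
#' @param n_tumors Number of tumor samples.
#' @param n_sites_per_chrom Named integer vector, sites per chromosome.
#'   Default: 600 on each of chr1--chr19 and 300 on chrX.
#' @param sites_per_gene Consecutive sites grouped into one gene.
#' @param depth_mean Expected total read depth per site and sample.
#' @param depth_dispersion Negative-binomial size parameter for depth (larger
#'   is closer to Poisson).
#' @param caf_center,caf_site_sd Mean and SD of the truncated-Gaussian
#'   baseline per-site CAF (clipped to \[0.05, 0.95\]).
#' @param overdispersion_rho Beta-binomial intra-class correlation in
#'   \[0, 1); 0 gives pure binomial sampling.
#' @param x_inactivation If `TRUE`, each tumor silences one parental X
#'   (chosen at random), forcing its chrX effective CAF to `x_skew` or
#'   `1 - x_skew`.
#' @param x_skew Residual minor-allele CAF on the inactivated X (skew is
#'   strong but not absolute).
#' @param lost_chromosome Chromosome lost in every tumor (monosomy), or
#'   `NULL` for none.
#' @param lost_chrom_caf Residual CAF on the lost chromosome.
#' @param deleted_segment Length-3 list or vector `(chrom, start, end)` in
#'   0-based half-open coordinates, or `NULL`. Sites inside have effective
#'   CAF exactly `deleted_segment_caf` (0 or 1).
#' @param deleted_segment_caf 0 (BALB allele deleted) or 1 (FVB deleted).
#' @param outlier_rate Per-(gene, tumor) probability of a planted
#'   allelic-ratio event. Events are only planted on chromosomes free of
#'   clonal aberrations, since events inside concerted-LOH regions are
#'   masked before outlier analysis and would be unobservable.
#' @param outlier_delta CAF shift magnitude of a planted event, in (0, 0.5];
#'   applied (with random sign) to all sites of the gene in that tumor.
#' @param repressed_gene_fraction Fraction of genes whose expression is
#'   coupled to the tumor's planted-event burden.
#' @param repression_slope Expression units (log2 RPKM-like) per planted
#'   event; negative for repression.
#' @param expr_baseline_mean,expr_baseline_sd Gaussian baseline expression
#'   per gene (log2 RPKM-like).
#' @param expr_noise_sd SD of per-(gene, tumor) expression noise.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   dataset exactly.
#'
#' @return A validated list of class `vloh_sim_config`.
#' @seealso [simulate_ase()]
#' @export
sim_config <- function(n_tumors = 20,
                       n_sites_per_chrom = NULL,
                       sites_per_gene = 3,
                       depth_mean = 100,
                       depth_dispersion = 5,
                       caf_center = 0.511,
                       caf_site_sd = 0.096,
                       overdispersion_rho = 0.01,
                       x_inactivation = TRUE,
                       x_skew = 0.05,
                       lost_chromosome = "chr4",
                       lost_chrom_caf = 0.15,
                       deleted_segment = list("chr7", 0L, 2e7),
                       deleted_segment_caf = 0,
                       outlier_rate = 0.05,
                       outlier_delta = 0.3,
                       repressed_gene_fraction = 0.05,
                       repression_slope = -3,
                       expr_baseline_mean = 5,
                       expr_baseline_sd = 2,
                       expr_noise_sd = 1,
                       seed = 1L) {
  if (is.null(n_sites_per_chrom)) {
    n_sites_per_chrom <- c(
      setNames(rep(600L, 19), paste0("chr", 1:19)),
      chrX = 300L
    )
  }
  assert_scalar_number(n_tumors, "n_tumors", lower = 2)
  if (is.null(names(n_sites_per_chrom)) || any(names(n_sites_per_chrom) == "")) {
    abort("`n_sites_per_chrom` must be a named vector of per-chromosome site counts")
  }
  if (any(n_sites_per_chrom < 1)) abort("all chromosome site counts must be >= 1")
  assert_scalar_number(sites_per_gene, "sites_per_gene", lower = 1)
  if (!is.numeric(depth_mean) || length(depth_mean) != 1 || is.na(depth_mean) ||
      depth_mean <= 0) {
    abort("configuration error: `depth_mean` must be a positive number")
  }
  assert_scalar_number(depth_dispersion, "depth_dispersion", lower = 1e-6)
  assert_scalar_number(caf_center, "caf_center", lower = 1e-6, upper = 1 - 1e-6)
  assert_scalar_number(caf_site_sd, "caf_site_sd", lower = 0)
  assert_scalar_number(overdispersion_rho, "overdispersion_rho", lower = 0, upper = 1 - 1e-9)
  assert_scalar_number(x_skew, "x_skew", lower = 0, upper = 0.25)
  assert_scalar_number(lost_chrom_caf, "lost_chrom_caf", lower = 0, upper = 1)
  assert_scalar_number(outlier_rate, "outlier_rate", lower = 0, upper = 1)
  if (!is.numeric(outlier_delta) || length(outlier_delta) != 1 ||
      is.na(outlier_delta) || outlier_delta <= 0 || outlier_delta > 0.5) {
    abort("configuration error: `outlier_delta` must lie in (0, 0.5]")
  }
  assert_scalar_number(repressed_gene_fraction, "repressed_gene_fraction",
    lower = 0, upper = 1)
  assert_scalar_number(repression_slope, "repression_slope")
  assert_scalar_number(expr_baseline_mean, "expr_baseline_mean")
  assert_scalar_number(expr_baseline_sd, "expr_baseline_sd", lower = 0)
  assert_scalar_number(expr_noise_sd, "expr_noise_sd", lower = 0)
  assert_scalar_number(seed, "seed")
  if (!is.null(deleted_segment)) {
    if (length(deleted_segment) != 3) {
      abort("`deleted_segment` must be (chrom, start, end) or NULL")
    }
    deleted_segment <- list(
      chrom = as.character(deleted_segment[[1]]),
      start = as.numeric(deleted_segment[[2]]),
      end = as.numeric(deleted_segment[[3]])
    )
    if (deleted_segment$start >= deleted_segment$end) {
      abort("`deleted_segment` start must be < end (0-based half-open)")
    }
  }
  if (!deleted_segment_caf %in% c(0, 1)) {
    abort("`deleted_segment_caf` must be exactly 0 or 1")
  }
  if (!is.null(lost_chromosome)) lost_chromosome <- as.character(lost_chromosome)

  structure(
    list(
      n_tumors = as.integer(n_tumors),
      n_sites_per_chrom = setNames(as.integer(n_sites_per_chrom), names(n_sites_per_chrom)),
      sites_per_gene = as.integer(sites_per_gene),
      depth_mean = depth_mean,
      depth_dispersion = depth_dispersion,
      caf_center = caf_center,
      caf_site_sd = caf_site_sd,
      overdispersion_rho = overdispersion_rho,
      x_inactivation = isTRUE(x_inactivation),
      x_skew = x_skew,
      lost_chromosome = lost_chromosome,
      lost_chrom_caf = lost_chrom_caf,
      deleted_segment = deleted_segment,
      deleted_segment_caf = deleted_segment_caf,
      outlier_rate = outlier_rate,
      outlier_delta = outlier_delta,
      repressed_gene_fraction = repressed_gene_fraction,
      repression_slope = repression_slope,
      expr_baseline_mean = expr_baseline_mean,
      expr_baseline_sd = expr_baseline_sd,
      expr_noise_sd = expr_noise_sd,
      seed = as.integer(seed)
    ),
    class = "vloh_sim_config"
  )
}

#' @export
print.vloh_sim_config <- function(x, ...) {
  cat("<vloh_sim_config>\n")
  cat(sprintf(
    "  %d tumors, %d sites on %d chromosomes, %d site(s)/gene\n",
    x$n_tumors, sum(x$n_sites_per_chrom), length(x$n_sites_per_chrom),
    x$sites_per_gene
  ))
  cat(sprintf(
    "  baseline CAF %.3f +/- %.3f, depth NB(mu=%g, size=%g), rho=%g\n",
    x$caf_center, x$caf_site_sd, x$depth_mean, x$depth_dispersion,
    x$overdispersion_rho
  ))
  cat(sprintf(
    "  events: X-inactivation=%s, lost=%s, segment=%s, outlier rate=%g delta=%g\n",
    x$x_inactivation, x$lost_chromosome %||% "none",
    if (is.null(x$deleted_segment)) "none" else
      sprintf("%s:%g-%g", x$deleted_segment$chrom, x$deleted_segment$start,
              x$deleted_segment$end),
    x$outlier_rate, x$outlier_delta
  ))
  invisible(x)
}
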