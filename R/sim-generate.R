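#' Simulate an F1 tumor allele-specific-expression dataset
#'
#' Draws a cohort of F1 tumor samples with per-site strain-A (FVB-like) and
#' strain-B (BALB-like) allele counts, a gene expression matrix, and a
#' ground-truth manifest of every planted event.
#'
#' Per site and tumor, total depth is negative-binomial
#' (`depth_mean`, `depth_dispersion`) and the strain-B count is
#' beta-binomial around the site's *effective* CAF (binomial when
#' `overdispersion_rho = 0`). The effective CAF starts at the site's
#' truncated-Gaussian baseline and is then overridden by, in order: the
#' tumor's X-inactivation skew on chrX, `lost_chrom_caf` on the lost
#' chromosome, exactly `deleted_segment_caf` inside the deleted segment, and
#' finally shifted by `+/- outlier_delta` (clamped to \[0, 1\]) for planted
#' (gene, tumor) events, which act on every site of the gene. Expression of
#' repressed genes is `baseline + repression_slope * (planted burden -
#' cohort mean burden) + noise`; the burden term is centered so that coupled
#' genes keep a realistic mean expression level while the correlation with
#' burden is untouched.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `vloh_sim` with elements
#'   \describe{
#'     \item{variants}{tibble: `site_id, chrom, pos, allele_a, allele_b, gene_id`}
#'     \item{counts}{long tibble: variant columns plus `sample, count_a, count_b`}
#'     \item{expression}{long tibble: `gene_id, sample, expr` (log2 RPKM-like)}
#'     \item{truth}{ground-truth manifest (class `vloh_sim_truth`): per-tumor
#'       silenced X parent, lost-chromosome events, planted outliers with
#'       direction, repressed genes with their true slope, and the config}
#'   }
#' @examples
#' sim <- simulate_ase(sim_config(
#'   n_tumors = 6,
#'   n_sites_per_chrom = c(chr1 = 30, chrX = 12),
#'   lost_chromosome = NULL, deleted_segment = NULL, seed = 7
#' ))
#' dplyr::count(sim$counts, sample)
#' @export
simulate_ase <- function(config) {
  if (!inherits(config, "vloh_sim_config")) {
    abort("`config` must be created with sim_config()")
  }
  withr::with_seed(config$seed, simulate_ase_impl(config))
}

simulate_ase_impl <- function(config) {
  chroms <- names(config$n_sites_per_chrom)
  samples <- sprintf("T%02d", seq_len(config$n_tumors))
  bases <- c("A", "C", "G", "T")

  # --- variant sites -------------------------------------------------------
  variants <- purrr::map_dfr(chroms, function(ch) {
    n <- config$n_sites_per_chrom[[ch]]
    pos <- sort(sample.int(2e8, n))
    allele_a <- sample(bases, n, replace = TRUE)
    allele_b <- vapply(allele_a, function(a) sample(setdiff(bases, a), 1), "")
    gene_idx <- ceiling(seq_len(n) / config$sites_per_gene)
    tibble(
      chrom = ch,
      pos = pos,
      allele_a = allele_a,
      allele_b = unname(allele_b),
      gene_id = sprintf("%s_g%04d", ch, gene_idx)
    )
  })
  variants <- arrange_genome(variants)
  variants$site_id <- paste0(variants$chrom, ":", variants$pos)
  variants <- variants[, c("site_id", "chrom", "pos", "allele_a", "allele_b", "gene_id")]
  variants <- as_tibble(variants)
  n_sites <- nrow(variants)

  baseline <- pmin(pmax(
    rnorm(n_sites, config$caf_center, config$caf_site_sd), 0.05), 0.95)

  # --- clonal events -------------------------------------------------------
  x_parent <- if (config$x_inactivation) {
    sample(c("A-silenced", "B-silenced"), config$n_tumors, replace = TRUE)
  } else {
    rep("none", config$n_tumors)
  }

  on_x <- is_x_chrom(variants$chrom)
  on_lost <- if (!is.null(config$lost_chromosome)) {
    variants$chrom == config$lost_chromosome
  } else {
    rep(FALSE, n_sites)
  }
  in_segment <- if (!is.null(config$deleted_segment)) {
    seg <- config$deleted_segment
    variants$chrom == seg$chrom &
      (variants$pos - 1) >= seg$start & (variants$pos - 1) < seg$end
  } else {
    rep(FALSE, n_sites)
  }

  # effective CAF: sites x tumors
  eff <- matrix(baseline, nrow = n_sites, ncol = config$n_tumors)
  if (config$x_inactivation) {
    # A-silenced: FVB X inactive, expression mostly BALB -> CAF near 1.
    x_caf <- ifelse(x_parent == "A-silenced", 1 - config$x_skew, config$x_skew)
    eff[on_x, ] <- matrix(x_caf, nrow = sum(on_x), ncol = config$n_tumors,
                          byrow = TRUE)
  }
  if (any(on_lost)) eff[on_lost, ] <- config$lost_chrom_caf
  if (any(in_segment)) eff[in_segment, ] <- config$deleted_segment_caf

  # --- planted single-tumor outliers --------------------------------------
  clonal_chroms <- character(0)
  if (config$x_inactivation) clonal_chroms <- c(clonal_chroms, chroms[is_x_chrom(chroms)])
  if (!is.null(config$lost_chromosome)) clonal_chroms <- c(clonal_chroms, config$lost_chromosome)
  if (!is.null(config$deleted_segment)) {
    seg_genes <- unique(variants$gene_id[in_segment])
  } else {
    seg_genes <- character(0)
  }
  eligible_genes <- setdiff(
    unique(variants$gene_id[!variants$chrom %in% clonal_chroms]),
    seg_genes
  )

  planted <- tibble(gene_id = character(0), sample = character(0),
                    direction = character(0))
  if (config$outlier_rate > 0 && length(eligible_genes) > 0) {
    grid <- expand.grid(gene_id = eligible_genes, sample = samples,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    hit <- stats::runif(nrow(grid)) < config$outlier_rate
    if (any(hit)) {
      planted <- as_tibble(grid[hit, , drop = FALSE])
      planted$direction <- sample(c("down", "up"), nrow(planted), replace = TRUE)
      planted <- arrange(planted, .data$gene_id, .data$sample)
    }
  }
  if (nrow(planted) > 0) {
    gene_rows <- split(seq_len(n_sites), variants$gene_id)
    col_of <- match(planted$sample, samples)
    shift <- ifelse(planted$direction == "up", config$outlier_delta,
                    -config$outlier_delta)
    for (k in seq_len(nrow(planted))) {
      rows <- gene_rows[[planted$gene_id[k]]]
      eff[rows, col_of[k]] <- pmin(pmax(eff[rows, col_of[k]] + shift[k], 0), 1)
    }
  }

  # --- allele counts -------------------------------------------------------
  total <- matrix(
    rnbinom(n_sites * config$n_tumors, mu = config$depth_mean,
            size = config$depth_dispersion),
    nrow = n_sites
  )
  count_b <- rbetabinom_mat(total, eff, config$overdispersion_rho)
  count_a <- total - count_b

  counts <- tidyr::expand_grid(site_id = variants$site_id, sample = samples)
  counts <- left_join(counts, variants, by = "site_id")
  counts$count_a <- as.integer(count_a[cbind(
    match(counts$site_id, variants$site_id), match(counts$sample, samples))])
  counts$count_b <- as.integer(count_b[cbind(
    match(counts$site_id, variants$site_id), match(counts$sample, samples))])
  counts <- counts[, c("site_id", "chrom", "pos", "gene_id", "sample",
                       "count_a", "count_b")]

  # --- expression ----------------------------------------------------------
  genes <- unique(variants$gene_id)
  repressed <- character(0)
  if (config$repressed_gene_fraction > 0) {
    n_rep <- round(config$repressed_gene_fraction * length(genes))
    repressed <- sort(sample(genes, n_rep))
  }
  burden <- table(factor(planted$sample, levels = samples))
  burden <- as.numeric(burden)
  burden_c <- burden - mean(burden)

  base_expr <- rnorm(length(genes), config$expr_baseline_mean,
                     config$expr_baseline_sd)
  expression <- tidyr::expand_grid(gene_id = genes, sample = samples)
  expression$expr <- base_expr[match(expression$gene_id, genes)] +
    rnorm(nrow(expression), 0, config$expr_noise_sd)
  is_rep <- expression$gene_id %in% repressed
  expression$expr[is_rep] <- expression$expr[is_rep] +
    config$repression_slope * burden_c[match(expression$sample[is_rep], samples)]

  truth <- structure(
    list(
      schema_version = 1L,
      x_inactivated_parent = tibble(sample = samples, silenced = x_parent),
      lost_chromosome_events = if (!is.null(config$lost_chromosome)) {
        tidyr::expand_grid(sample = samples, chrom = config$lost_chromosome)
      } else {
        tibble(sample = character(0), chrom = character(0))
      },
      deleted_segment = config$deleted_segment,
      planted_outliers = planted,
      repressed_genes = tibble(gene_id = repressed,
                               slope = rep(config$repression_slope,
                                           length(repressed))),
      planted_burden = tibble(sample = samples, n_planted = burden),
      config = config
    ),
    class = "vloh_sim_truth"
  )

  structure(
    list(variants = variants, counts = as_tibble(counts),
         expression = as_tibble(expression), truth = truth),
    class = "vloh_sim"
  )
}

# Beta-binomial draw for a matrix of sizes and probabilities; rho is the
# intra-class correlation. Degenerate p (0/1) and rho = 0 short-circuit.
rbetabinom_mat <- function(size, prob, rho) {
  out <- matrix(0L, nrow = nrow(size), ncol = ncol(size))
  n <- length(size)
  p <- as.vector(prob)
  s <- as.vector(size)
  draw <- integer(n)
  deg0 <- p <= 0
  deg1 <- p >= 1
  mid <- !deg0 & !deg1
  draw[deg1] <- s[deg1]
  if (any(mid)) {
    if (rho > 0) {
      a <- p[mid] * (1 - rho) / rho
      b <- (1 - p[mid]) * (1 - rho) / rho
      pp <- rbeta(sum(mid), a, b)
    } else {
      pp <- p[mid]
    }
    draw[mid] <- rbinom(sum(mid), s[mid], pp)
  }
  out[] <- draw
  out
}

#' @export
print.vloh_sim <- function(x, ...) {
  cat("<vloh_sim>\n")
  cat(sprintf("  %d sites x %d tumors, %d genes\n",
              nrow(x$variants), length(unique(x$counts$sample)),
              length(unique(x$variants$gene_id))))
  cat(sprintf("  planted outliers: %d; repressed genes: %d\n",
              nrow(x$truth$planted_outliers), nrow(x$truth$repressed_genes)))
  invisible(x)
}
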