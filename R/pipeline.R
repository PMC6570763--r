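#' Pipeline configuration
#'
#' Collects the inputs and every stage parameter of the V-LOH analysis with
#' defaults matching the study conventions (minor-allele filter at 15, skew
#' thresholds 0.25/0.75, |Z| >= 2, nominal per-sample outlier rate 1/20,
#' expression floor 0.5 log2 RPKM, correlation thresholds |r| > 0.7 and
#' p < 0.01, assumed 1% chance-correlation rate). Inputs may be file paths
#' (read with the package readers) or in-memory tibbles.
#'
#' @param variants Variant table path or tibble.
#' @param counts Allele-count table path or tibble.
#' @param expression Expression table path or tibble, or `NULL` to skip the
#'   correlation stage.
#' @param extra_mask Optional BED path or mask tibble force-masked on top of
#'   the detected regions.
#' @param out_dir Output directory for all intermediates and the report.
#' @param min_minor,filter_scope,filter_rule See [filter_sites()].
#' @param skew_low,skew_high Skew thresholds shared by clonality calling and
#'   the concerted-LOH scan.
#' @param loh_alpha,tumor_frac,site_frac,min_run See [scan_concerted_loh()].
#' @param z_thresh,z_boundary,z_method See [caf_zscores()] and
#'   [call_outliers()].
#' @param per_sample_rate Nominal per-tumor outlier rate for the Poisson
#'   null.
#' @param min_level Expression floor for [filter_expressed()].
#' @param r_cut,p_cut Correlation hit thresholds.
#' @param sign_p_cut P cutoff for the sign-bias summary.
#' @param null_rate Assumed chance-correlation rate for
#'   [correlated_fraction_test()].
#' @param normality_n Sites sampled by the normality screen.
#' @param x_chrom Name of the X chromosome.
#' @param seed Seed for the normality screen's site draw.
#' @return A list of class `vloh_config`.
#' @export
vloh_config <- function(variants, counts, expression = NULL,
                        extra_mask = NULL, out_dir = "vloh-results",
                        min_minor = 15, filter_scope = "cohort",
                        filter_rule = "minor",
                        skew_low = 0.25, skew_high = 0.75,
                        loh_alpha = 1e-3, tumor_frac = 1, site_frac = 0.9,
                        min_run = 10,
                        z_thresh = 2, z_boundary = "inclusive",
                        z_method = "include",
                        per_sample_rate = 1 / 20,
                        min_level = 0.5, r_cut = 0.7, p_cut = 0.01,
                        sign_p_cut = 1e-6, null_rate = 0.01,
                        normality_n = 50, x_chrom = "chrX", seed = 1L) {
  structure(
    list(
      variants = variants, counts = counts, expression = expression,
      extra_mask = extra_mask, out_dir = out_dir,
      min_minor = min_minor, filter_scope = filter_scope,
      filter_rule = filter_rule,
      skew_low = skew_low, skew_high = skew_high, loh_alpha = loh_alpha,
      tumor_frac = tumor_frac, site_frac = site_frac, min_run = min_run,
      z_thresh = z_thresh, z_boundary = z_boundary, z_method = z_method,
      per_sample_rate = per_sample_rate, min_level = min_level,
      r_cut = r_cut, p_cut = p_cut, sign_p_cut = sign_p_cut,
      null_rate = null_rate, normality_n = normality_n,
      x_chrom = x_chrom, seed = as.integer(seed)
    ),
    class = "vloh_config"
  )
}

resolve_input <- function(x, reader, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(sprintf("%s file not found: %s", what, x))
    return(reader(x))
  }
  if (is.data.frame(x)) return(x)
  abort(sprintf("%s must be a file path or a data frame", what))
}

#' Run the full V-LOH analysis
#'
#' Executes filter -> CAF -> clonality and concerted-LOH mask -> Z-scores and
#' outlier calls -> Poisson/binomial enrichment -> burden-expression
#' correlation, writing every intermediate table plus a YAML report to
#' `config$out_dir`. A stage failure aborts with the stage name and cause.
#' Reruns with the same configuration are byte-identical.
#'
#' @param config A [vloh_config()] object.
#' @return Invisibly, a list of class `vloh_result` with the report and all
#'   in-memory stage outputs (`caf`, `clonality`, `regions`, `mask`,
#'   `zscores`, `calls`, `enrichment`, `burden`, `correlations`, ...).
#' @export
run_vloh <- function(config) {
  stopifnot(inherits(config, "vloh_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)

  variants <- stage("read-variants", resolve_input(config$variants, read_variants, "variant"))
  counts <- stage("read-counts", resolve_input(
    config$counts, function(x) read_counts(x, variants = variants), "count"))
  expression <- stage("read-expression", resolve_input(
    config$expression, read_expression, "expression"))
  extra_mask <- stage("read-mask", resolve_input(config$extra_mask, read_bed, "mask"))

  filtered <- stage("filter", filter_sites(
    counts, min_minor = config$min_minor, scope = config$filter_scope,
    rule = config$filter_rule))
  caf <- stage("caf", compute_caf(filtered))
  site_stats <- stage("caf", caf_site_stats(caf))

  clonality <- stage("clonality", call_clonality(
    caf, low = config$skew_low, high = config$skew_high,
    x_chrom = config$x_chrom))
  regions <- stage("concerted-loh", scan_concerted_loh(
    caf, low = config$skew_low, high = config$skew_high,
    alpha = config$loh_alpha, tumor_frac = config$tumor_frac,
    site_frac = config$site_frac, min_run = config$min_run))
  mask <- stage("mask", build_mask(regions, extra = extra_mask,
                                   x_chrom = config$x_chrom))

  # summary statistics follow the masking step: the headline CAF
  # distribution and the normality screen describe the eSNVs that remain
  # after concerted-LOH regions are excluded
  caf_unmasked <- caf[!site_in_mask(caf$chrom, caf$pos, mask), , drop = FALSE]
  caf_summary <- stage("caf", summarize_caf(caf_unmasked))
  normality <- stage("normality", normality_screen(
    caf_unmasked,
    n_sample = min(config$normality_n, length(unique(caf_unmasked$site_id))),
    seed = config$seed))

  zscores <- stage("zscores", caf_zscores(caf, mask = mask,
                                          method = config$z_method))
  calls <- stage("outliers", call_outliers(zscores, z_thresh = config$z_thresh,
                                           boundary = config$z_boundary))
  n_samples <- length(unique(counts$sample))
  enrichment <- stage("enrichment", enrichment_test(
    calls, n_samples = n_samples, per_sample_rate = config$per_sample_rate))
  varieg <- stage("variegation", variegation_report(calls))

  retained <- stage("retained-tumors", retained_tumors(
    caf, mask, low = config$skew_low, high = config$skew_high))
  kept <- retained$sample[retained$retained]
  burden <- stage("burden", outlier_burden(calls, tumors = kept))

  correlations <- NULL
  corr_summary <- NULL
  sign_bias <- NULL
  if (!is.null(expression)) {
    expressed <- stage("expression-filter", filter_expressed(
      expression, min_level = config$min_level, samples = kept))
    correlations <- stage("correlation", correlate_burden(expressed, burden))
    hits <- correlation_hits(correlations, r_cut = config$r_cut,
                             p_cut = config$p_cut)
    n_tested <- sum(!correlations$skipped)
    corr_summary <- stage("correlation", correlated_fraction_test(
      nrow(hits), max(n_tested, 1), null_rate = config$null_rate))
    sign_bias <- stage("correlation", sign_summary(
      correlations, p_cut = config$sign_p_cut))
  }

  # ---- write intermediates ----------------------------------------------
  write_counts(filtered, p("filtered_counts.tsv"))
  readr::write_tsv(site_stats, p("caf_site_stats.tsv"), progress = FALSE)
  readr::write_tsv(clonality, p("clonality.tsv"), progress = FALSE)
  readr::write_tsv(regions, p("concerted_loh.tsv"), progress = FALSE)
  write_bed(mask, p("mask.bed"))
  readr::write_tsv(zscores, p("zscores.tsv"), progress = FALSE)
  readr::write_tsv(calls$flags, p("outlier_flags.tsv"), progress = FALSE)
  readr::write_tsv(calls$gene_tumors, p("gene_outliers.tsv"), progress = FALSE)
  readr::write_tsv(retained, p("retained_tumors.tsv"), progress = FALSE)
  readr::write_tsv(burden, p("tumor_burden.tsv"), progress = FALSE)
  if (!is.null(correlations)) {
    readr::write_tsv(as_tibble(correlations), p("correlations.tsv"),
                     progress = FALSE)
  }

  report <- list(
    tool = "vloh",
    version = as.character(packageVersion("vloh")),
    seed = config$seed,
    parameters = config[!names(config) %in%
                          c("variants", "counts", "expression", "extra_mask",
                            "out_dir")],
    inputs = list(
      n_sites_input = length(unique(counts$site_id)),
      n_sites_retained = length(unique(filtered$site_id)),
      n_samples = n_samples,
      n_genes_expression = if (is.null(expression)) 0L else
        length(unique(expression$gene_id))
    ),
    caf_summary = as.list(caf_summary),
    normality = list(pass_fraction = normality$pass_fraction,
                     n_tested = normality$n_tested,
                     n_skipped = normality$n_skipped),
    clonality = list(
      n_clonal = sum(clonality$call != "not-skewed"),
      n_tumors = nrow(clonality)
    ),
    concerted_loh = list(
      flagged_regions = regions$region[regions$verdict == "concerted-LOH"]
    ),
    outliers = list(
      n_flagged = sum(abs(calls$flags$flag) == 1, na.rm = TRUE),
      n_unmasked_entries = sum(!is.na(calls$flags$flag)),
      pct_genes_with_outlier = 100 * enrichment$observed_with_fraction,
      enrichment_p = enrichment$p_value,
      enrichment_log10_p = enrichment$log10_p,
      enrichment_method = enrichment$method
    ),
    burden = list(retained_tumors = kept,
                  n_retained = length(kept)),
    correlation = if (is.null(correlations)) NULL else list(
      n_tested = sum(!correlations$skipped),
      n_hits = corr_summary$n_hits,
      hit_rate = corr_summary$observed_rate,
      enrichment_p = corr_summary$p_value,
      enrichment_log10_p = corr_summary$log10_p,
      sign_bias_n = sign_bias$n,
      fraction_negative = sign_bias$fraction_negative
    )
  )
  yaml::write_yaml(report, p("report.yaml"), precision = 15)

  invisible(structure(
    list(report = report, variants = variants, counts = counts,
         filtered = filtered, caf = caf, site_stats = site_stats,
         caf_summary = caf_summary, normality = normality,
         clonality = clonality, regions = regions, mask = mask,
         zscores = zscores, calls = calls, enrichment = enrichment,
         variegation = varieg, retained = retained, burden = burden,
         correlations = correlations, correlation_summary = corr_summary,
         sign_bias = sign_bias, out_dir = config$out_dir),
    class = "vloh_result"
  ))
}

#' @export
print.vloh_result <- function(x, ...) {
  cat(render_report_text(x$report), sep = "\n")
  invisible(x)
}

#' Render a pipeline report
#'
#' Reads the `report.yaml` written by [run_vloh()] from a results directory
#' and renders a human-readable summary.
#'
#' @param dir Results directory.
#' @return The summary text, invisibly; it is also printed.
#' @export
render_report <- function(dir) {
  path <- file.path(dir, "report.yaml")
  if (!file.exists(path)) abort(sprintf("no report.yaml in %s", dir))
  txt <- render_report_text(yaml::read_yaml(path))
  cat(txt, sep = "\n")
  invisible(txt)
}

render_report_text <- function(r) {
  lines <- c(
    sprintf("V-LOH analysis report (vloh %s, seed %s)", r$version, r$seed),
    sprintf("  sites: %d input, %d after read-support filter; %d tumors",
            r$inputs$n_sites_input, r$inputs$n_sites_retained,
            r$inputs$n_samples),
    sprintf("  CAF: mean of site means %.3f, SD %.3f over %d sites",
            r$caf_summary$mean_caf, r$caf_summary$sd_caf,
            r$caf_summary$n_sites),
    sprintf("  normality screen: %.0f%% of %d sampled sites pass Shapiro-Wilk",
            100 * r$normality$pass_fraction, r$normality$n_tested),
    sprintf("  clonality: %d of %d tumors X-skewed",
            r$clonality$n_clonal, r$clonality$n_tumors),
    sprintf("  concerted LOH: %s",
            if (length(r$concerted_loh$flagged_regions) == 0) "none" else
              paste(unlist(r$concerted_loh$flagged_regions), collapse = ", ")),
    sprintf("  outliers: %d flagged entries; %.1f%% of genes with >= 1 outlier tumor (p = %.3g, %s)",
            r$outliers$n_flagged, r$outliers$pct_genes_with_outlier,
            r$outliers$enrichment_p, r$outliers$enrichment_method)
  )
  if (!is.null(r$correlation)) {
    lines <- c(lines, sprintf(
      "  correlation screen: %d of %d genes hit (%.1f%%, p = %.3g); %.1f%% negative at p < cutoff",
      r$correlation$n_hits, r$correlation$n_tested,
      100 * r$correlation$hit_rate, r$correlation$enrichment_p,
      100 * (r$correlation$fraction_negative %||% NA_real_)))
  }
  lines
}
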