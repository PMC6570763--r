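#' Filter eSNV sites by read support
#'
#' Reproduces the depth filter that keeps the analysis on genes consistently
#' expressed across the cohort. Two rules are available:
#'
#' * `rule = "minor"` (default): a site is retained when its minor-strain
#'   allele count reaches `min_minor`. Under `scope = "cohort"` counts are
#'   summed across samples before taking the minor strain; under
#'   `scope = "per_sample"` every sample must individually satisfy the rule
#'   (stricter).
#' * `rule = "total"`: the same scopes applied to total (A + B) read counts
#'   rather than the minor strain.
#'
#' The boundary is inclusive ("at least"), and retention is monotone: a
#' smaller threshold retains a superset of sites.
#'
#' @param counts Long allele-count tibble (see [read_counts()]).
#' @param min_minor Minimum count, default 15.
#' @param scope `"cohort"` or `"per_sample"`.
#' @param rule `"minor"` or `"total"`.
#' @return The filtered count tibble (possibly empty, with a warning).
#' @export
filter_sites <- function(counts, min_minor = 15,
                         scope = c("cohort", "per_sample"),
                         rule = c("minor", "total")) {
  scope <- match.arg(scope)
  rule <- match.arg(rule)
  assert_columns(counts, c("site_id", "sample", "count_a", "count_b"),
                 "count table")
  assert_scalar_number(min_minor, "min_minor", lower = 0)

  stat <- if (scope == "cohort") {
    per_site <- counts |>
      group_by(.data$site_id) |>
      summarise(a = sum(.data$count_a), b = sum(.data$count_b),
                .groups = "drop")
    per_site$value <- if (rule == "minor") pmin(per_site$a, per_site$b) else
      per_site$a + per_site$b
    per_site
  } else {
    per_site <- counts |>
      group_by(.data$site_id) |>
      summarise(
        value = if (rule == "minor") {
          min(pmin(.data$count_a, .data$count_b))
        } else {
          min(.data$count_a + .data$count_b)
        },
        .groups = "drop"
      )
    per_site
  }
  keep <- stat$site_id[stat$value >= min_minor]
  out <- counts[counts$site_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn(sprintf("no sites pass the read-support filter (min_minor = %g, %s/%s)",
                 min_minor, rule, scope))
  }
  out
}

#' Convert allele counts to BALB/c-allele frequencies (CAF)
#'
#' CAF is the strain-B (BALB-like) fraction of reads at a site:
#' `count_b / (count_a + count_b)`. Entries with zero total depth become
#' missing (`NA`) rather than zero — a zero would fabricate allelic loss.
#' Ratios expressed on the strain-A (FVB-like) scale convert as
#' `CAF = 1 - value` (see [fvb_to_caf()]).
#'
#' @param counts Long allele-count tibble.
#' @return The tibble with `total` and `caf` columns appended.
#' @export
compute_caf <- function(counts) {
  assert_columns(counts, c("site_id", "sample", "count_a", "count_b"),
                 "count table")
  out <- mutate(counts,
    total = .data$count_a + .data$count_b,
    caf = dplyr::if_else(.data$total > 0,
                         .data$count_b / .data$total, NA_real_)
  )
  as_tibble(out)
}

#' Convert a strain-A (FVB) allelic ratio to CAF
#'
#' @param value Numeric vector of strain-A allele frequencies.
#' @return `1 - value`, the BALB/c-allele frequency.
#' @examples
#' fvb_to_caf(0.3) # 0.7
#' @export
fvb_to_caf <- function(value) {
  if (any(value < 0 | value > 1, na.rm = TRUE)) {
    abort("allelic ratios must lie in [0, 1]")
  }
  1 - value
}

#' Per-site CAF statistics
#'
#' Missing-aware per-site mean, SD and non-missing sample count across the
#' cohort. The SD convention is the sample SD (n - 1 denominator) by
#' default; set `population = TRUE` for the n denominator.
#'
#' @param caf CAF tibble from [compute_caf()].
#' @param population Use the population SD convention.
#' @return A tibble `site_id, chrom, pos, gene_id, mean_caf, sd_caf, n`.
#' @export
caf_site_stats <- function(caf, population = FALSE) {
  assert_columns(caf, c("site_id", "sample", "caf"), "CAF table")
  extra <- intersect(c("chrom", "pos", "gene_id"), names(caf))
  caf |>
    group_by(dplyr::across(dplyr::all_of(c("site_id", extra)))) |>
    summarise(
      mean_caf = mean(.data$caf, na.rm = TRUE),
      sd_caf = caf_sd(.data$caf, population = population),
      n = sum(!is.na(.data$caf)),
      .groups = "drop"
    ) |>
    mutate(mean_caf = dplyr::if_else(is.nan(.data$mean_caf), NA_real_,
                                     .data$mean_caf))
}

#' Cohort-level CAF summary
#'
#' Mean and SD of the per-site mean CAFs — the "average mean CAF" headline
#' statistic of a balanced F1 cohort (about 0.5 when no allele is favored).
#' Sites with no usable CAF values are excluded with a warning.
#'
#' @param caf CAF tibble from [compute_caf()].
#' @param population Use the population SD convention for both levels.
#' @return A one-row tibble `mean_caf, sd_caf, n_sites`.
#' @export
summarize_caf <- function(caf, population = FALSE) {
  stats <- caf_site_stats(caf, population = population)
  if (nrow(stats) == 0) abort("summarize_caf() needs at least one site")
  dropped <- sum(is.na(stats$mean_caf))
  if (dropped > 0) {
    warn(sprintf("%d site(s) with no non-missing CAF values excluded from the summary",
                 dropped))
    stats <- stats[!is.na(stats$mean_caf), ]
  }
  tibble(
    mean_caf = mean(stats$mean_caf),
    sd_caf = if (nrow(stats) > 1) caf_sd(stats$mean_caf, population = population) else 0,
    n_sites = nrow(stats)
  )
}

#' Shapiro-Wilk normality screen of sampled sites
#'
#' Draws `n_sample` sites at random (reproducibly, from `seed`) and tests
#' each site's CAF values across the cohort for normality with the
#' Shapiro-Wilk test. Sites with fewer than 3 non-missing values or zero
#' variance cannot be tested and are reported as skipped.
#'
#' @param caf CAF tibble from [compute_caf()].
#' @param n_sample Number of sites to sample (default 50).
#' @param alpha Significance level; a site "passes" when `p > alpha`.
#' @param seed Integer seed for the site draw.
#' @return A list with `pass_fraction` (among testable sites), `n_tested`,
#'   `n_skipped`, and `results`, a tibble `site_id, p_value, pass, skipped`.
#' @export
normality_screen <- function(caf, n_sample = 50, alpha = 0.05, seed = 1L) {
  assert_columns(caf, c("site_id", "sample", "caf"), "CAF table")
  sites <- unique(caf$site_id)
  if (n_sample > length(sites)) {
    abort(sprintf("n_sample (%d) exceeds the number of sites (%d)",
                  n_sample, length(sites)))
  }
  chosen <- withr::with_seed(seed, sample(sites, n_sample))
  vals <- split(caf$caf[caf$site_id %in% chosen],
                caf$site_id[caf$site_id %in% chosen])
  res <- purrr::map_dfr(chosen, function(s) {
    x <- vals[[s]]
    x <- x[!is.na(x)]
    if (length(x) < 3 || length(unique(x)) == 1) {
      return(tibble(site_id = s, p_value = NA_real_, pass = NA,
                    skipped = TRUE))
    }
    p <- shapiro.test(x)$p.value
    tibble(site_id = s, p_value = p, pass = p > alpha, skipped = FALSE)
  })
  n_skipped <- sum(res$skipped)
  if (n_skipped > 0) {
    inform(sprintf("normality screen skipped %d untestable site(s)", n_skipped))
  }
  tested <- res[!res$skipped, ]
  list(
    pass_fraction = if (nrow(tested) > 0) mean(tested$pass) else NA_real_,
    n_tested = nrow(tested),
    n_skipped = n_skipped,
    results = res
  )
}
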