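#' Call tumor clonality from X-chromosome allelic skew
#'
#' X-inactivation is mitotically heritable, so a tumor descended from a
#' single cell expresses chrX genes almost exclusively from one parent. Each
#' tumor's mean CAF over chrX sites is compared to skew thresholds with
#' strict inequality: `< low` means the BALB-like X is silenced
#' (`clonal-B-silenced`, expressed alleles mostly strain A), `> high` means
#' the FVB-like X is silenced (`clonal-A-silenced`); values at or between
#' the thresholds are `not-skewed`. A mean of exactly `high` (or `low`) is
#' therefore not a clonal call.
#'
#' @param caf CAF tibble from [compute_caf()].
#' @param low,high Skew thresholds (defaults 0.25 / 0.75).
#' @param x_chrom Name of the X chromosome in the data.
#' @return A tibble `sample, chrx_mean_caf, n_sites, call`.
#' @export
call_clonality <- function(caf, low = 0.25, high = 0.75, x_chrom = "chrX") {
  assert_columns(caf, c("chrom", "sample", "caf"), "CAF table")
  x <- caf[is_x_chrom(caf$chrom, x_chrom), , drop = FALSE]
  if (nrow(x) == 0) {
    abort(sprintf("no %s sites present: clonality cannot be called", x_chrom))
  }
  x |>
    group_by(.data$sample) |>
    summarise(
      chrx_mean_caf = mean(.data$caf, na.rm = TRUE),
      n_sites = sum(!is.na(.data$caf)),
      .groups = "drop"
    ) |>
    mutate(call = dplyr::case_when(
      .data$chrx_mean_caf < low ~ "clonal-B-silenced",
      .data$chrx_mean_caf > high ~ "clonal-A-silenced",
      TRUE ~ "not-skewed"
    ))
}

#' Scan for cohort-wide concerted LOH
#'
#' Flags regions where essentially every tumor shows the same allelic loss:
#' whole chromosomes whose sites are predominantly skewed in (almost) all
#' tumors, and maximal runs of at least `min_run` consecutive
#' cohort-skewed sites (segment-scale events such as a hemizygous deletion).
#'
#' Allelic loss is judged on means, which are tight even at moderate read
#' depth: a *site* is skewed when its per-site mean CAF (across tumors) is
#' `< low` or `> high`, and a *tumor* is skewed on a region when its mean
#' CAF over the region's sites is beyond the same thresholds. A chromosome
#' is a candidate when at least `site_frac` of its sites are skewed **and**
#' at least `tumor_frac` of the tumors are skewed on it (default 1: all
#' tumors display the loss); a run of `>= min_run` consecutive skewed sites
#' on a non-flagged chromosome is a candidate segment. Each candidate is
#' then tested for location: a two-sided one-sample t-test of its per-site
#' mean CAFs against 0.5, falling back to a sign test when the site means
#' are (nearly) constant or fewer than 5 — the verdict `concerted-LOH`
#' requires both the threshold rule and `p_value <= alpha`. The choice of
#' test is a documented convention. A chromosome skewed in *different*
#' directions per tumor (the X under random X-inactivation) has balanced
#' site means and is deliberately not flagged here; the X is always force-
#' masked by [build_mask()] instead.
#'
#' @param caf CAF tibble from [compute_caf()].
#' @param low,high Skew thresholds on mean CAF.
#' @param alpha Significance level for the location test (default `1e-3`).
#' @param tumor_frac Fraction of tumors that must be skewed on a flagged
#'   chromosome (default 1, i.e. all; 0.9 tolerates single discordant
#'   samples).
#' @param site_frac Fraction of a chromosome's sites that must be skewed to
#'   flag the whole chromosome.
#' @param min_run Minimum run length for segment detection.
#' @return A tibble with one row per chromosome plus one per detected
#'   segment: `region_type, region, chrom, start, end, n_sites, mean_caf,
#'   frac_skewed_sites, frac_skewed_tumors, p_value, verdict` (coordinates
#'   0-based half-open; whole-chromosome rows use a fixed large end
#'   sentinel). Per-tumor region means are attached as attribute
#'   `tumor_means`.
#' @export
scan_concerted_loh <- function(caf, low = 0.25, high = 0.75, alpha = 1e-3,
                               tumor_frac = 1, site_frac = 0.9,
                               min_run = 10) {
  assert_columns(caf, c("site_id", "chrom", "pos", "sample", "caf"),
                 "CAF table")
  per_site <- caf |>
    group_by(.data$site_id, .data$chrom, .data$pos) |>
    summarise(site_mean = mean(.data$caf, na.rm = TRUE), .groups = "drop") |>
    arrange(chrom_rank(.data$chrom), .data$pos)
  per_site$skewed <- !is.na(per_site$site_mean) &
    (per_site$site_mean < low | per_site$site_mean > high)

  tumor_means <- caf |>
    group_by(.data$chrom, .data$sample) |>
    summarise(mean_caf = mean(.data$caf, na.rm = TRUE), .groups = "drop")

  region_row <- function(ch, sites, type) {
    m <- sites$site_mean[!is.na(sites$site_mean)]
    tm <- if (type == "chromosome") {
      tumor_means$mean_caf[tumor_means$chrom == ch]
    } else {
      tc <- caf[caf$site_id %in% sites$site_id, ] |>
        group_by(.data$sample) |>
        summarise(mean_caf = mean(.data$caf, na.rm = TRUE), .groups = "drop")
      tc$mean_caf
    }
    tm <- tm[!is.na(tm)]
    start <- if (type == "chromosome") 0 else as.numeric(min(sites$pos) - 1)
    end <- if (type == "chromosome") WHOLE_CHROM_END else
      as.numeric(max(sites$pos))
    tibble(
      region_type = type,
      region = if (type == "chromosome") ch else
        sprintf("%s:%.0f-%.0f", ch, start, end),
      chrom = ch,
      start = start,
      end = end,
      n_sites = nrow(sites),
      mean_caf = mean(m),
      frac_skewed_sites = mean(sites$skewed),
      frac_skewed_tumors = mean(tm < low | tm > high),
      p_value = location_test(m)
    )
  }

  chrom_rows <- purrr::map_dfr(unique(per_site$chrom), function(ch) {
    region_row(ch, per_site[per_site$chrom == ch, ], "chromosome")
  })
  chrom_rows$verdict <- ifelse(
    chrom_rows$frac_skewed_sites >= site_frac &
      chrom_rows$frac_skewed_tumors >= tumor_frac &
      !is.na(chrom_rows$p_value) & chrom_rows$p_value <= alpha,
    "concerted-LOH", "balanced"
  )

  flagged_chroms <- chrom_rows$chrom[chrom_rows$verdict == "concerted-LOH"]
  seg_rows <- purrr::map_dfr(
    setdiff(unique(per_site$chrom), flagged_chroms),
    function(ch) {
      s <- per_site[per_site$chrom == ch, ]
      runs <- rle(s$skewed)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      keep <- which(runs$values & runs$lengths >= min_run)
      purrr::map_dfr(keep, function(k) {
        row <- region_row(ch, s[starts[k]:ends[k], ], "segment")
        row$verdict <- ifelse(!is.na(row$p_value) & row$p_value <= alpha,
                              "concerted-LOH", "balanced")
        row
      })
    }
  )

  out <- bind_rows(chrom_rows, seg_rows)
  out <- out[order(chrom_rank(out$chrom), out$start, out$region_type), ]
  attr(out, "tumor_means") <- tumor_means
  out
}

# Sentinel end coordinate for whole-chromosome mask intervals: longer than
# any mouse chromosome, keeps the mask a valid BED without a genome file.
WHOLE_CHROM_END <- 2^29

# Two-sided one-sample location test of x against 0.5. t-test when the
# values vary and n >= 5; otherwise an exact sign test (values equal to 0.5
# are dropped, as is conventional).
location_test <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (length(x) >= 5 && stats::sd(x) > sqrt(.Machine$double.eps)) {
    return(t.test(x, mu = 0.5)$p.value)
  }
  s <- x[x != 0.5]
  if (length(s) == 0) return(1)
  binom.test(sum(s > 0.5), length(s), 0.5)$p.value
}

#' Build the exclusion mask for outlier analysis
#'
#' Unions the regions flagged as concerted LOH, the whole X chromosome
#' (always excluded: X-inactivation skew would otherwise flood the outlier
#' scan), and any user-supplied extra mask, then normalizes and merges
#' overlaps.
#'
#' @param results Result tibble from [scan_concerted_loh()], or `NULL`.
#' @param extra Optional extra mask tibble (e.g. from [read_bed()]).
#' @param x_chrom Name of the X chromosome.
#' @return A mask tibble `chrom, start, end, name`.
#' @export
build_mask <- function(results = NULL, extra = NULL, x_chrom = "chrX") {
  pieces <- list(
    tibble(chrom = x_chrom, start = 0, end = WHOLE_CHROM_END,
           name = "chrX-clonality")
  )
  if (!is.null(results) && nrow(results) > 0) {
    hit <- results[results$verdict == "concerted-LOH", , drop = FALSE]
    if (nrow(hit) > 0) {
      pieces <- c(pieces, list(tibble(
        chrom = hit$chrom, start = hit$start, end = hit$end,
        name = "concerted-LOH"
      )))
    }
  }
  if (!is.null(extra) && nrow(extra) > 0) {
    assert_columns(extra, c("chrom", "start", "end"), "extra mask")
    if (!"name" %in% names(extra)) extra$name <- "user"
    pieces <- c(pieces, list(extra[, c("chrom", "start", "end", "name")]))
  }
  merge_mask(bind_rows(pieces))
}

#' Tumors free of private concerted LOH
#'
#' Identifies the tumors eligible for burden counting: a tumor is retained
#' when, outside the masked regions, none of its chromosomes shows a
#' chromosome-scale allelic skew of its own (per-tumor mean CAF `< low` or
#' `> high` over the chromosome's unmasked sites). Cohort-wide events are
#' already masked, so this drops only tumors with *private* chromosome-scale
#' aberrations. The selection rule is a documented convention.
#'
#' @param caf CAF tibble from [compute_caf()].
#' @param mask Mask tibble from [build_mask()].
#' @param low,high Skew thresholds.
#' @param min_sites Minimum unmasked sites for a chromosome mean to count.
#' @return A tibble `sample, retained, offending_chroms`.
#' @export
retained_tumors <- function(caf, mask, low = 0.25, high = 0.75,
                            min_sites = 10) {
  assert_columns(caf, c("chrom", "pos", "sample", "caf"), "CAF table")
  keep <- !site_in_mask(caf$chrom, caf$pos, mask)
  unmasked <- caf[keep, , drop = FALSE]
  per <- unmasked |>
    group_by(.data$sample, .data$chrom) |>
    summarise(mean_caf = mean(.data$caf, na.rm = TRUE),
              n = sum(!is.na(.data$caf)), .groups = "drop") |>
    filter(.data$n >= min_sites) |>
    mutate(skewed = .data$mean_caf < low | .data$mean_caf > high)
  per |>
    group_by(.data$sample) |>
    summarise(
      retained = !any(.data$skewed),
      offending_chroms = paste(.data$chrom[.data$skewed], collapse = ","),
      .groups = "drop"
    )
}
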