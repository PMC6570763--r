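#' Per-site cohort Z-scores of CAF
#'
#' For every eSNV the CAF of each tumor is standardized against the cohort:
#' `Z = (value - mean) / sd`, where mean and SD are taken over the tumors at
#' that site *including* the evaluated sample (`method = "include"`,
#' default). Leave-one-out standardization (`method = "loo"`), which
#' recomputes mean and SD from the other samples, is available as a stricter
#' alternative. Sites inside the mask, entries with missing CAF, sites with
#' fewer than `min_n` non-missing samples, and zero-SD sites all yield
#' missing Z and are marked `masked`; zero-SD and low-n sites are reported.
#'
#' @param caf CAF tibble from [compute_caf()].
#' @param mask Optional mask tibble ([build_mask()] / [read_bed()]).
#' @param method `"include"` (cohort mean/SD include the sample) or
#'   `"loo"` (leave-one-out).
#' @param min_n Minimum non-missing samples per site (default 3).
#' @param population Use the population SD convention.
#' @return A tibble `site_id, chrom, pos, gene_id, sample, caf, z, masked`
#'   with attribute `excluded_sites` (zero-SD or low-n site ids).
#' @export
caf_zscores <- function(caf, mask = NULL, method = c("include", "loo"),
                        min_n = 3, population = FALSE) {
  method <- match.arg(method)
  assert_columns(caf, c("site_id", "chrom", "pos", "gene_id", "sample", "caf"),
                 "CAF table")
  out <- caf[, c("site_id", "chrom", "pos", "gene_id", "sample", "caf")]
  out$masked_region <- site_in_mask(out$chrom, out$pos, mask)

  z_one <- function(x, region_masked) {
    use <- x
    use[region_masked] <- NA_real_
    nn <- sum(!is.na(use))
    if (nn < min_n) return(list(z = rep(NA_real_, length(x)), excluded = nn > 0))
    if (method == "include") {
      m <- mean(use, na.rm = TRUE)
      s <- caf_sd(use, population = population)
      if (is.na(s) || s == 0) {
        return(list(z = rep(NA_real_, length(x)), excluded = TRUE))
      }
      list(z = (use - m) / s, excluded = FALSE)
    } else {
      z <- vapply(seq_along(use), function(i) {
        if (is.na(use[i])) return(NA_real_)
        rest <- use[-i]
        m <- mean(rest, na.rm = TRUE)
        s <- caf_sd(rest, population = population)
        if (is.na(s) || s == 0) return(NA_real_)
        (use[i] - m) / s
      }, 0)
      list(z = z, excluded = all(is.na(z)))
    }
  }

  split_idx <- split(seq_len(nrow(out)), out$site_id)
  z <- rep(NA_real_, nrow(out))
  excluded <- character(0)
  for (s in names(split_idx)) {
    idx <- split_idx[[s]]
    if (all(out$masked_region[idx])) next
    res <- z_one(out$caf[idx], out$masked_region[idx])
    z[idx] <- res$z
    if (res$excluded) excluded <- c(excluded, s)
  }
  out$z <- z
  out$masked <- out$masked_region | is.na(out$z)
  out$masked_region <- NULL
  if (length(excluded) > 0) {
    inform(sprintf(
      "%d site(s) excluded from Z-scores (zero SD or < %d usable samples)",
      length(excluded), min_n))
  }
  attr(out, "excluded_sites") <- excluded
  as_tibble(out)
}

#' Call signed allelic-ratio outliers
#'
#' Thresholds the Z matrix into signed flags: `+1` for Z at/above
#' `z_thresh`, `-1` for Z at/below `-z_thresh`, `0` otherwise, `NA` where
#' masked. With `boundary = "inclusive"` (default) a Z of exactly
#' `z_thresh` is an outlier; `"exclusive"` uses strict inequalities. Per
#' tumor the eSNV-level outlier burden is enumerated, and per gene the
#' number of tumors in which at least one of the gene's sites is flagged.
#'
#' @param z Z-score tibble from [caf_zscores()].
#' @param z_thresh Threshold, default 2.
#' @param boundary `"inclusive"` (`>=`/`<=`) or `"exclusive"` (`>`/`<`).
#' @return An object of class `vloh_outliers`: a list with
#'   \describe{
#'     \item{flags}{long tibble `site_id, chrom, pos, gene_id, sample, caf, z, flag`}
#'     \item{tumor_burden}{tibble `sample, n_outliers` (eSNV-level)}
#'     \item{gene_tumors}{tibble `gene_id, n_sites, n_tumor_outliers`, one
#'       row per gene with at least one unmasked site}
#'     \item{params}{threshold and boundary used}
#'   }
#' @export
call_outliers <- function(z, z_thresh = 2,
                          boundary = c("inclusive", "exclusive")) {
  boundary <- match.arg(boundary)
  assert_columns(z, c("site_id", "gene_id", "sample", "z", "masked"),
                 "Z-score table")
  assert_scalar_number(z_thresh, "z_thresh", lower = 0)
  flags <- z
  if (boundary == "inclusive") {
    flags$flag <- dplyr::case_when(
      flags$masked | is.na(flags$z) ~ NA_integer_,
      flags$z >= z_thresh ~ 1L,
      flags$z <= -z_thresh ~ -1L,
      TRUE ~ 0L
    )
  } else {
    flags$flag <- dplyr::case_when(
      flags$masked | is.na(flags$z) ~ NA_integer_,
      flags$z > z_thresh ~ 1L,
      flags$z < -z_thresh ~ -1L,
      TRUE ~ 0L
    )
  }
  tumor_burden <- flags |>
    group_by(.data$sample) |>
    summarise(n_outliers = sum(abs(.data$flag) == 1, na.rm = TRUE),
              .groups = "drop")
  gene_tumors <- flags |>
    filter(!is.na(.data$flag)) |>
    group_by(.data$gene_id) |>
    summarise(
      n_sites = dplyr::n_distinct(.data$site_id),
      n_tumor_outliers = dplyr::n_distinct(.data$sample[abs(.data$flag) == 1]),
      .groups = "drop"
    )
  structure(
    list(flags = as_tibble(flags), tumor_burden = tumor_burden,
         gene_tumors = gene_tumors,
         params = list(z_thresh = z_thresh, boundary = boundary)),
    class = "vloh_outliers"
  )
}

#' @export
print.vloh_outliers <- function(x, ...) {
  cat("<vloh_outliers>\n")
  cat(sprintf("  |Z| %s %g; %d unmasked entries, %d flagged; %d genes\n",
              if (x$params$boundary == "inclusive") ">=" else ">",
              x$params$z_thresh, sum(!is.na(x$flags$flag)),
              sum(abs(x$flags$flag) == 1, na.rm = TRUE), nrow(x$gene_tumors)))
  invisible(x)
}

#' Per-tumor eSNV outlier burden
#'
#' Counts, per tumor, the eSNVs whose absolute Z-score exceeds the
#' threshold, optionally restricted to a subset of tumors (e.g. those free
#' of private concerted LOH, see [retained_tumors()]).
#'
#' @param calls A `vloh_outliers` object.
#' @param tumors Optional character vector of samples to keep.
#' @return A tibble `sample, n_outliers`.
#' @export
outlier_burden <- function(calls, tumors = NULL) {
  stopifnot(inherits(calls, "vloh_outliers"))
  burden <- calls$tumor_burden
  if (!is.null(tumors)) burden <- burden[burden$sample %in% tumors, ]
  burden
}

#' Poisson expectation of a zero-outlier gene
#'
#' Under a random-outlier null each tumor independently contributes an
#' outlier with probability `per_sample_rate`, so the number of outlier
#' tumors per gene is Poisson with `lambda = n_samples * per_sample_rate`
#' and the chance of *no* outlier is `exp(-lambda)`. At the study's scale
#' (20 tumors, nominal rate 1/20) this is `exp(-1) = 0.3679`; its complement
#' (~63%) is the expected fraction of genes with one or more outliers.
#'
#' @param n_samples Number of tumors.
#' @param per_sample_rate Per-tumor outlier probability in \[0, 1\].
#' @return The zero-outlier probability `exp(-n_samples * per_sample_rate)`.
#' @examples
#' poisson_zero_expectation(20, 1 / 20) # 0.3679
#' @export
poisson_zero_expectation <- function(n_samples, per_sample_rate) {
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  assert_scalar_number(per_sample_rate, "per_sample_rate", lower = 0, upper = 1)
  exp(-n_samples * per_sample_rate)
}

#' Binomial test of gene-level outlier enrichment
#'
#' Tests whether fewer genes than expected are outlier-free. Under the
#' Poisson null a gene is outlier-free with probability
#' `p0 = exp(-n_samples * per_sample_rate)`; the one-sided p-value is the
#' binomial probability of observing at most the observed number of
#' zero-outlier genes among `n_genes` (equivalently, at least the observed
#' number of with-outlier genes at success probability `1 - p0`). The
#' computation is exact (`pbinom`) up to `n_genes = 10^4` and switches to a
#' continuity-corrected normal approximation above; the method used is
#' reported.
#'
#' Supply either a `vloh_outliers` object as `calls`, or the printed counts
#' directly via `n_genes` and `n_with_outlier`.
#'
#' @param calls A `vloh_outliers` object, or `NULL` when counts are given.
#' @param n_samples Number of tumors behind the calls.
#' @param per_sample_rate Nominal per-tumor outlier rate (default the
#'   1-in-20 convention; the Gaussian two-tail rate 0.0455 is a sensible
#'   alternative).
#' @param n_genes,n_with_outlier Printed counts, used when `calls` is NULL.
#' @return A one-row tibble of class `vloh_enrichment`:
#'   `n_genes, n_with_outlier, observed_zero_fraction,
#'   expected_zero_probability, observed_with_fraction, p_value, log10_p,
#'   method`.
#' @examples
#' enrichment_test(n_samples = 20, n_genes = 3044, n_with_outlier = 2634)
#' @export
enrichment_test <- function(calls = NULL, n_samples,
                            per_sample_rate = 1 / 20,
                            n_genes = NULL, n_with_outlier = NULL) {
  if (!is.null(calls)) {
    stopifnot(inherits(calls, "vloh_outliers"))
    n_genes <- nrow(calls$gene_tumors)
    n_with_outlier <- sum(calls$gene_tumors$n_tumor_outliers >= 1)
  }
  if (is.null(n_genes) || is.null(n_with_outlier)) {
    abort("either `calls` or both `n_genes` and `n_with_outlier` are required")
  }
  if (n_genes == 0) abort("enrichment_test() needs at least one gene")
  if (n_with_outlier > n_genes) abort("n_with_outlier cannot exceed n_genes")
  p0 <- poisson_zero_expectation(n_samples, per_sample_rate)
  k0 <- n_genes - n_with_outlier
  if (n_genes <= 1e4) {
    method <- "exact-binomial"
    logp <- pbinom(k0, n_genes, p0, lower.tail = TRUE, log.p = TRUE)
  } else {
    method <- "normal-approximation"
    mu <- n_genes * p0
    sig <- sqrt(n_genes * p0 * (1 - p0))
    logp <- pnorm((k0 + 0.5 - mu) / sig, log.p = TRUE)
  }
  res <- tibble(
    n_genes = n_genes,
    n_with_outlier = n_with_outlier,
    observed_zero_fraction = k0 / n_genes,
    expected_zero_probability = p0,
    observed_with_fraction = n_with_outlier / n_genes,
    p_value = exp(logp),
    log10_p = logp / log(10),
    method = method
  )
  class(res) <- c("vloh_enrichment", class(res))
  res
}

#' Long-format variegation summary
#'
#' Renders the outlier calls in the layout used for variegation displays:
#' one row per unmasked (site, tumor) cell with its signed flag, plus a
#' per-gene multiplicity histogram (how many genes have 0, 1, 2, ... outlier
#' tumors). The histogram sums to the number of genes.
#'
#' @param calls A `vloh_outliers` object.
#' @return A list with `cells` (tibble `site_id, chrom, pos, gene_id,
#'   sample, flag`) and `multiplicity` (tibble `n_tumor_outliers, n_genes`).
#' @export
variegation_report <- function(calls) {
  stopifnot(inherits(calls, "vloh_outliers"))
  cells <- calls$flags |>
    filter(!is.na(.data$flag)) |>
    select("site_id", "chrom", "pos", "gene_id", "sample", "flag")
  multiplicity <- calls$gene_tumors |>
    dplyr::count(.data$n_tumor_outliers, name = "n_genes") |>
    arrange(.data$n_tumor_outliers)
  list(cells = as_tibble(cells), multiplicity = as_tibble(multiplicity))
}
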