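# Internal helpers shared across modules.

# Canonical chromosome ordering: numeric chromosomes first (natural order),
# then X, Y, M/MT, then anything else alphabetically. Accepts names with or
# without a "chr" prefix.
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(core))
  special <- match(toupper(core), c("X", "Y", "M", "MT"))
  rank <- ifelse(!is.na(num), num,
    ifelse(!is.na(special), 1000 + special, NA_real_)
  )
  other <- is.na(rank)
  if (any(other)) {
    rank[other] <- 2000 + as.integer(factor(core[other], levels = sort(unique(core[other]))))
  }
  rank
}

#' @noRd
arrange_genome <- function(df) {
  df[order(chrom_rank(df$chrom), df$pos), , drop = FALSE]
}

is_x_chrom <- function(chrom, x_chrom = "chrX") {
  chrom == x_chrom | sub("^chr", "", chrom) == sub("^chr", "", x_chrom)
}

# Sample standard deviation (n - 1) with optional population (n) convention.
caf_sd <- function(x, population = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- stats::sd(x)
  if (population) s * sqrt((n - 1) / n) else s
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must contain columns: %s (missing: %s)",
      what, paste(cols, collapse = ", "), paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must not be NULL", name))
  }
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}

# Order sample ids by first appearance, preserving the input layout.
sample_levels <- function(x) unique(as.character(x))
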