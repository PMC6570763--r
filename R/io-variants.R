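#' Read strain-informative variant sites
#'
#' Loads the table of expressed SNVs (eSNVs) that distinguish the two
#' parental strains. Two dialects are supported:
#'
#' * **tsv** — tab-separated with header columns `chrom, pos, allele_a,
#'   allele_b, gene_id` (an optional leading `site_id` column is accepted and
#'   checked); `pos` is 1-based.
#' * **vcf** — a sites-only VCF parsed with \pkg{vcfR}; `REF` is taken as the
#'   strain-A allele, `ALT` as strain-B, and the gene assignment is read from
#'   the `GENE=` key of the INFO field. Multiallelic records (a comma in
#'   `ALT`) are rejected: one site must name exactly one informative allele
#'   per strain.
#'
#' Records are validated (identical alleles or duplicated `(chrom, pos)` are
#' errors, with the offending line reported) and returned in genome order.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A tibble with columns
#'   `site_id, chrom, pos, allele_a, allele_b, gene_id`.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("variant file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  v <- if (format == "vcf") read_variants_vcf(path) else read_variants_tsv(path)
  validate_variants(v, path)
}

read_variants_tsv <- function(path) {
  v <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    allele_a = readr::col_character(),
    allele_b = readr::col_character(),
    gene_id = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  assert_columns(v, c("chrom", "pos", "allele_a", "allele_b", "gene_id"),
                 sprintf("variant table %s", basename(path)))
  v
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    abort(sprintf(
      "multiallelic VCF record at %s:%s (ALT = %s): split or drop multiallelic sites before import",
      fix$CHROM[which(multi)[1]], fix$POS[which(multi)[1]],
      fix$ALT[which(multi)[1]]
    ))
  }
  gene <- sub(".*(?:^|;)GENE=([^;]+).*", "\\1", fix$INFO)
  no_gene <- is.na(fix$INFO) | !grepl("(^|;)GENE=", fix$INFO)
  if (any(no_gene)) {
    abort(sprintf(
      "VCF record at %s:%s has no GENE= key in INFO; a gene assignment is required",
      fix$CHROM[which(no_gene)[1]], fix$POS[which(no_gene)[1]]
    ))
  }
  tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    allele_a = fix$REF,
    allele_b = fix$ALT,
    gene_id = gene
  )
}

validate_variants <- function(v, path = "<variants>") {
  bad <- which(is.na(v$chrom) | is.na(v$pos) | is.na(v$allele_a) |
                 is.na(v$allele_b) | is.na(v$gene_id))
  if (length(bad) > 0) {
    abort(sprintf("malformed variant record at line %d of %s (missing field)",
                  bad[1] + 1L, path))
  }
  same <- which(v$allele_a == v$allele_b)
  if (length(same) > 0) {
    abort(sprintf(
      "validation error at line %d of %s: allele_a equals allele_b ('%s')",
      same[1] + 1L, path, v$allele_a[same[1]]
    ))
  }
  key <- paste0(v$chrom, ":", v$pos)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("duplicate variant position %s in %s", key[dup[1]], path))
  }
  v <- arrange_genome(v)
  v$site_id <- paste0(v$chrom, ":", v$pos)
  as_tibble(v[, c("site_id", "chrom", "pos", "allele_a", "allele_b", "gene_id")])
}

#' Write variant sites as TSV
#'
#' Inverse of [read_variants()] for the TSV dialect; columns are written in
#' the fixed order `site_id, chrom, pos, allele_a, allele_b, gene_id` in
#' genome order, so output is byte-deterministic.
#'
#' @param variants Variant tibble (as returned by [read_variants()] or
#'   [simulate_ase()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variants <- function(variants, path) {
  assert_columns(variants, c("chrom", "pos", "allele_a", "allele_b", "gene_id"),
                 "variant table")
  v <- arrange_genome(variants)
  v$site_id <- paste0(v$chrom, ":", v$pos)
  readr::write_tsv(v[, c("site_id", "chrom", "pos", "allele_a", "allele_b",
                         "gene_id")], path, progress = FALSE)
  invisible(path)
}
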