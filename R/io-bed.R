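#' Construct a region mask
#'
#' A region mask is a tibble of genomic intervals in 0-based half-open (BED)
#' coordinates with a provenance label per interval. Overlapping or abutting
#' intervals on a chromosome are merged and labels combined.
#'
#' @param chrom,start,end Parallel vectors defining the intervals.
#' @param name Provenance label(s), recycled.
#' @return A normalized mask tibble `chrom, start, end, name`.
#' @export
region_mask <- function(chrom = character(0), start = numeric(0),
                        end = numeric(0), name = "user") {
  if (length(chrom) == 0) {
    return(tibble(chrom = character(0), start = numeric(0),
                  end = numeric(0), name = character(0)))
  }
  if (any(start >= end)) {
    abort("invalid interval: start must be < end (0-based half-open)")
  }
  if (any(start < 0)) abort("invalid interval: start must be >= 0")
  merge_mask(tibble(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end),
                    name = rep_len(as.character(name), length(chrom))))
}

# Normalize: sort and merge overlapping/abutting intervals per chromosome,
# concatenating distinct provenance labels.
merge_mask <- function(mask) {
  if (nrow(mask) == 0) return(as_tibble(mask))
  parts <- split(mask, mask$chrom)
  merged <- purrr::map_dfr(parts, function(m) {
    ir <- IRanges::IRanges(start = m$start + 1, end = m$end)
    red <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, red)
    labels <- vapply(seq_along(red), function(i) {
      src <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
      paste(unique(m$name[src]), collapse = ",")
    }, "")
    tibble(chrom = m$chrom[1], start = IRanges::start(red) - 1,
           end = as.numeric(IRanges::end(red)), name = labels)
  })
  merged <- merged[order(chrom_rank(merged$chrom), merged$start), ]
  as_tibble(merged)
}

#' Read a BED mask file
#'
#' Reads BED3 or BED3+name (0-based half-open), validates `start < end`, and
#' returns a normalized mask with overlapping intervals merged. Intervals on
#' chromosomes absent from `known_chroms` (when given) trigger a warning but
#' are retained.
#'
#' @param path BED file path.
#' @param known_chroms Optional character vector of expected chromosome
#'   names.
#' @return A mask tibble as from [region_mask()].
#' @export
read_bed <- function(path, known_chroms = NULL) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), comment = "#", progress = FALSE)
  if (nrow(raw) == 0) return(region_mask())
  if (ncol(raw) < 3) abort(sprintf("BED file %s needs at least 3 columns", path))
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("non-numeric coordinates in BED file %s", path))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("invalid BED interval at line %d of %s: start >= end",
                  bad[1], path))
  }
  name <- if (ncol(raw) >= 4) raw[[4]] else rep("user", nrow(raw))
  if (!is.null(known_chroms)) {
    unknown <- setdiff(unique(raw[[1]]), known_chroms)
    if (length(unknown) > 0) {
      warn(sprintf("BED interval(s) on unknown chromosome(s): %s (retained)",
                   paste(unknown, collapse = ", ")))
    }
  }
  region_mask(raw[[1]], start, end, name)
}

#' Write a region mask as BED3+name
#'
#' @param mask Mask tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(mask, path) {
  assert_columns(mask, c("chrom", "start", "end", "name"), "region mask")
  out <- mask
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# TRUE for sites (1-based positions) falling inside the mask.
site_in_mask <- function(chrom, pos, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(rep(FALSE, length(chrom)))
  hit <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(mask))) {
    hit <- hit | (chrom == mask$chrom[i] &
                    (pos - 1) >= mask$start[i] & (pos - 1) < mask$end[i])
  }
  hit
}
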