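## Shared helpers for the variant table layout.
##
## A variant table is a tibble with one row per site: chrom, pos (1-based),
## ref, alt, vtype ("SNP"/"INDEL", NA for multiallelic records), qd, then one
## gt_<sample> column per sample holding the unphased diploid dosage
## (0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing) and one dp_<sample>
## column with the per-sample read depth.

gt_cols <- function(x) grep("^gt_", names(x), value = TRUE)
dp_cols <- function(x) grep("^dp_", names(x), value = TRUE)

#' Sample names carried by a variant table
#'
#' @param x A variant table (tibble with `gt_<sample>` columns).
#' @return Character vector of sample names.
#' @export
variant_samples <- function(x) sub("^gt_", "", gt_cols(x))

#' Extract the genotype dosage matrix from a variant table
#'
#' @param x A variant table.
#' @param samples Samples to extract (default: all).
#' @return Integer matrix, sites in rows, samples in columns; entries are
#'   diploid alt-allele dosages in `{0, 1, 2}` with `NA` for missing calls.
#' @export
gt_matrix <- function(x, samples = variant_samples(x)) {
  cols <- paste0("gt_", samples)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("no such sample column(s): ", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(x[cols]))
  storage.mode(m) <- "integer"
  colnames(m) <- samples
  m
}

#' Percentage as printed in summary tables
#'
#' All headline fractions in the package (sharing spectra, HIGH-impact
#' fractions, TE sharing levels) are reported through this helper: percent of
#' `total`, rounded to two decimals.
#'
#' @param n Numerator count(s).
#' @param total Denominator count.
#' @return Numeric percentage(s) rounded to 2 decimals.
#' @export
percent_of <- function(n, total) round(100 * n / total, 2)

#' Tile chromosomes into non-overlapping windows
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window Window width in bp.
#' @param full_only Drop the trailing partial window at each chromosome end?
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
tile_windows <- function(chrom_lengths, window = 50000, full_only = FALSE) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)), window > 0)
  map_dfr(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    out <- tibble(chrom = ch, start = starts, end = ends)
    if (full_only) out <- out[out$end - out$start == window, , drop = FALSE]
    out
  })
}

#' Bases covered in every sample, per window
#'
#' Coverage masks give, per sample, the intervals where that sample has
#' adequate depth (>= 5x in the simulator). The covered-bases accounting used
#' for diversity denominators counts only bases where *all* samples are
#' covered, mirroring per-chromosome "covered bases" summaries.
#'
#' @param windows Tibble of windows (`chrom`, `start`, `end`, 0-based half-open).
#' @param masks Tibble of covered intervals (`sample`, `chrom`, `start`, `end`),
#'   or `NULL` meaning everything is covered.
#' @param samples Samples that must all be covered (default: all in `masks`).
#' @return `windows` with a `covered_bases` column appended.
#' @export
window_covered_bases <- function(windows, masks = NULL, samples = NULL) {
  if (is.null(masks)) {
    return(mutate(windows, covered_bases = .data$end - .data$start))
  }
  samples <- samples %||% unique(masks$sample)
  masks <- filter(masks, .data$sample %in% .env$samples)
  n_s <- length(samples)
  out <- map_dfr(split(windows, windows$chrom), function(w) {
    ch <- w$chrom[[1]]
    m <- filter(masks, .data$chrom == ch)
    glen <- max(w$end)
    if (nrow(m) == 0) {
      w$covered_bases <- 0L
      return(w)
    }
    cov <- IRanges::coverage(
      IRanges::IRanges(start = m$start + 1L, end = pmin(m$end, glen)),
      width = glen
    )
    all_cov <- cumsum(c(0L, as.integer(as.integer(cov) == n_s)))
    w$covered_bases <- all_cov[w$end + 1L] - all_cov[w$start + 1L]
    w
  })
  arrange(out, match(.data$chrom, unique(windows$chrom)), .data$start)
}

## TRUE for positions (1-based) jointly covered by every sample in `masks`
jointly_covered <- function(chrom, pos, masks, samples = NULL) {
  if (is.null(masks)) return(rep(TRUE, length(pos)))
  samples <- samples %||% unique(masks$sample)
  masks <- filter(masks, .data$sample %in% .env$samples)
  n_s <- length(samples)
  out <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    m <- filter(masks, .data$chrom == ch)
    if (nrow(m) == 0) next
    glen <- max(m$end, pos[i])
    cov <- IRanges::coverage(
      IRanges::IRanges(start = m$start + 1L, end = pmin(m$end, glen)),
      width = glen
    )
    out[i] <- as.integer(cov)[pos[i]] == n_s
  }
  out
}

harmonic_a1 <- function(n) sum(1 / seq_len(n - 1))
harmonic_a2 <- function(n) sum(1 / seq_len(n - 1)^2)

## order a variant table by chromosome (first-appearance order of
## chrom_order if given) then position
sort_variants <- function(x, chrom_order = NULL) {
  chrom_order <- chrom_order %||% unique(x$chrom)
  arrange(x, match(.data$chrom, chrom_order), .data$pos)
}
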