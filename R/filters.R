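## Post-calling filter cascade, applied to the joint multi-sample call set in
## a fixed order: site quality (per-genotype DP mask + site QD cutoff) ->
## biallelic -> SNP-near-INDEL spacing -> INDEL spacing/length -> missingness.
## Each removed record is attributed to the first stage that fails it, so the
## per-stage counts in the filter report always sum back to the input count.

#' Depth and quality-by-depth filtering
#'
#' A sample's genotype is set to missing when its depth is below `min_dp`
#' (missing depth counts as failing), which reproduces both the depth filter
#' and the covered-bases accounting with one mechanism; a site is removed
#' when its summed depth across samples is below `min_dp` or its
#' quality-by-depth is below `min_qd`. Sites with no QD annotation are
#' rejected with a warning, as the rule cannot be evaluated for them.
#'
#' @param x Variant table.
#' @param min_dp Minimum per-sample depth; genotypes below it are masked, and
#'   sites whose total depth is below it are dropped.
#' @param min_qd Minimum site QD; sites below it are dropped.
#' @param samples Samples whose genotypes are masked (default: all).
#' @return Filtered variant table.
#' @export
filter_site_quality <- function(x, min_dp = 5, min_qd = 20,
                                samples = variant_samples(x)) {
  for (s in samples) {
    dp <- x[[paste0("dp_", s)]]
    if (is.null(dp)) next
    low <- is.na(dp) | dp < min_dp
    x[[paste0("gt_", s)]][low] <- NA_integer_
  }
  no_qd <- is.na(x$qd)
  if (any(no_qd)) {
    warn(sprintf("%d record(s) dropped: missing QD annotation", sum(no_qd)))
  }
  x <- x[!site_dp_fail(x, min_dp, samples), , drop = FALSE]
  filter(x, !is.na(.data$qd), .data$qd >= min_qd)
}

site_dp_fail <- function(x, min_dp, samples = variant_samples(x)) {
  cols <- intersect(paste0("dp_", samples), names(x))
  if (length(cols) == 0) return(rep(FALSE, nrow(x)))
  total <- rowSums(as.matrix(as.data.frame(x[cols])), na.rm = TRUE)
  total < min_dp
}

#' Keep only biallelic records
#'
#' @param x Variant table.
#' @return Records with exactly one ALT allele.
#' @export
filter_biallelic <- function(x) {
  filter(x, !grepl(",", .data$alt, fixed = TRUE))
}

#' Remove SNPs close to INDELs
#'
#' A SNP is removed when any INDEL in `x` (the set as given, i.e. before any
#' INDEL-specific filtering) lies within `window_bp` on the same chromosome;
#' distance is POS-to-POS and the boundary is inclusive (a SNP exactly
#' `window_bp` away is removed).
#'
#' @param x Variant table.
#' @param window_bp Exclusion window, bp.
#' @return Filtered variant table.
#' @export
filter_snp_near_indel <- function(x, window_bp = 15) {
  is_indel <- !is.na(x$vtype) & x$vtype == "INDEL"
  is_snp <- !is.na(x$vtype) & x$vtype == "SNP"
  drop <- rep(FALSE, nrow(x))
  for (ch in unique(x$chrom[is_indel])) {
    ip <- sort(x$pos[is_indel & x$chrom == ch])
    si <- which(is_snp & x$chrom == ch)
    if (length(si) == 0) next
    near <- findInterval(x$pos[si] + window_bp, ip) -
      findInterval(x$pos[si] - window_bp - 1L, ip) > 0
    drop[si[near]] <- TRUE
  }
  x[!drop, , drop = FALSE]
}

#' INDEL spacing and length rules
#'
#' INDELs longer than `max_len` bp are discarded first; then any INDEL whose
#' POS lies closer than `min_gap` bp to another surviving INDEL on the same
#' chromosome is removed — both members of a too-close pair go (a pair
#' exactly `min_gap` apart is kept).
#'
#' @param x Variant table.
#' @param min_gap Minimum POS-to-POS distance between INDELs, bp.
#' @param max_len Maximum INDEL length (|len(alt) - len(ref)|), bp.
#' @return Filtered variant table.
#' @export
filter_indel_rules <- function(x, min_gap = 50, max_len = 100) {
  is_indel <- !is.na(x$vtype) & x$vtype == "INDEL"
  too_long <- is_indel & abs(nchar(x$alt) - nchar(x$ref)) > max_len
  x <- x[!too_long, , drop = FALSE]
  is_indel <- !is.na(x$vtype) & x$vtype == "INDEL"
  drop <- rep(FALSE, nrow(x))
  for (ch in unique(x$chrom[is_indel])) {
    ii <- which(is_indel & x$chrom == ch)
    p <- x$pos[ii]
    o <- order(p)
    p <- p[o]
    if (length(p) < 2) next
    gap <- diff(p)
    close_pair <- gap < min_gap
    bad <- c(close_pair, FALSE) | c(FALSE, close_pair)
    drop[ii[o][bad]] <- TRUE
  }
  x[!drop, , drop = FALSE]
}

#' Missingness filter
#'
#' A record is removed when its missing-genotype fraction among `samples`
#' exceeds `max_missing_fraction` (strictly more than half by default: with
#' eight clones a record survives four missing calls but not five).
#'
#' @param x Variant table.
#' @param max_missing_fraction Maximum tolerated missing fraction.
#' @param samples Samples counted (default: all).
#' @return Filtered variant table.
#' @export
filter_missingness <- function(x, max_missing_fraction = 0.5,
                               samples = variant_samples(x)) {
  gm <- gt_matrix(x, samples)
  n_missing <- rowSums(is.na(gm))
  x[n_missing <= max_missing_fraction * length(samples), , drop = FALSE]
}

#' Apply the full filter cascade
#'
#' Runs, in order: [filter_site_quality()], [filter_biallelic()],
#' [filter_snp_near_indel()], [filter_indel_rules()], [filter_missingness()].
#' The per-stage removal counts are attached as a `filter_report` attribute
#' (see [filter_report()]); each record is attributed to the first stage that
#' removed it, so `input = retained + sum(removed)`. The cascade is
#' idempotent: applying it twice equals applying it once.
#'
#' @param x Variant table.
#' @param min_dp,min_qd Site-quality thresholds.
#' @param snp_indel_window SNP-near-INDEL exclusion window, bp.
#' @param indel_min_gap,indel_max_len INDEL spacing / length rules.
#' @param max_missing_fraction Missingness cutoff.
#' @param samples Samples used for genotype masking and missingness counting.
#' @return Filtered variant table with a `filter_report` attribute.
#' @export
filter_cascade <- function(x,
                           min_dp = 5, min_qd = 20,
                           snp_indel_window = 15,
                           indel_min_gap = 50, indel_max_len = 100,
                           max_missing_fraction = 0.5,
                           samples = variant_samples(x)) {
  counts <- c(input = nrow(x))
  ## too-long INDELs are their own report stage even though
  ## filter_indel_rules applies both rules
  counts["dp_fail"] <- sum(site_dp_fail(x, min_dp, samples))
  x1 <- filter_site_quality(x, min_dp, min_qd, samples)
  counts["qd_fail"] <- nrow(x) - nrow(x1) - counts[["dp_fail"]]
  x2 <- filter_biallelic(x1)
  counts["multiallelic"] <- nrow(x1) - nrow(x2)
  x3 <- filter_snp_near_indel(x2, snp_indel_window)
  counts["snp_near_indel"] <- nrow(x2) - nrow(x3)
  is_indel <- !is.na(x3$vtype) & x3$vtype == "INDEL"
  n_long <- sum(is_indel & abs(nchar(x3$alt) - nchar(x3$ref)) > indel_max_len)
  x4 <- filter_indel_rules(x3, indel_min_gap, indel_max_len)
  counts["indel_too_long"] <- n_long
  counts["indel_spacing"] <- nrow(x3) - nrow(x4) - n_long
  x5 <- filter_missingness(x4, max_missing_fraction, samples)
  counts["missingness"] <- nrow(x4) - nrow(x5)
  counts["retained"] <- nrow(x5)
  report <- tibble(
    stage = names(counts),
    n = as.integer(counts)
  )
  attr(x5, "filter_report") <- report
  x5
}

#' Per-stage counts of the last filter cascade
#'
#' @param x Result of [filter_cascade()].
#' @return Tibble with `stage` and `n`; stages other than `input` and
#'   `retained` count removed records, attributed to the first failing stage.
#' @export
filter_report <- function(x) {
  rep <- attr(x, "filter_report")
  if (is.null(rep)) abort("no filter_report attribute; run filter_cascade() first")
  rep
}
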