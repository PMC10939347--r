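## Windowed diversity statistics for the clone panel. Unphased diploid
## genotypes are treated as allele counts, so a panel of n clones contributes
## 2n haplotypes; pi, Watterson's theta and Tajima's D depend only on the
## per-site allele frequencies, never on phase. Statistics are computed on
## the complete-case polymorphic SNP set so the haplotype count is constant
## across sites.

#' Per-site nucleotide diversity
#'
#' Unbiased expected heterozygosity of one biallelic site:
#' `2 c (m - c) / (m (m - 1))` for `c` alt alleles among `m` haplotypes —
#' the fraction of mismatching pairs among all `choose(m, 2)` haplotype
#' pairs. Vectorized over `c`.
#'
#' @param alt_count Alt-allele count(s) `c`, `0 <= c <= m`.
#' @param haplotypes Haplotype sample size `m` (>= 2).
#' @return Per-site pi value(s) in `[0, 0.5...]`; 0 for monomorphic sites.
#' @export
site_pi <- function(alt_count, haplotypes) {
  stopifnot(haplotypes >= 2, all(alt_count >= 0), all(alt_count <= haplotypes))
  2 * alt_count * (haplotypes - alt_count) / (haplotypes * (haplotypes - 1))
}

#' Tajima's D from segregating sites and the pi sum
#'
#' Standard Tajima (1989) normalization of the difference between the
#' pairwise-diversity estimator (`pi_sum`) and the Watterson estimator
#' (`S / a1`). Vectorized over `S` and `pi_sum`. Undefined (NA) when `S` is 0
#' or the variance term vanishes.
#'
#' @param S Segregating-site count(s).
#' @param pi_sum Sum of [site_pi()] over the same sites.
#' @param n Haplotype sample size (>= 4 for a meaningful variance).
#' @return Tajima's D value(s).
#' @export
tajima_d <- function(S, pi_sum, n) {
  stopifnot(n >= 2)
  a1 <- harmonic_a1(n)
  a2 <- harmonic_a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  out <- (pi_sum - S / a1) / denom
  out[S == 0 | denom == 0 | !is.finite(out)] <- NA_real_
  out
}

#' Watterson's theta
#'
#' @param S Segregating-site count(s).
#' @param n Haplotype sample size.
#' @return `S / a1(n)` (per window/region, not per bp).
#' @export
watterson_theta <- function(S, n) S / harmonic_a1(n)

#' Windowed diversity statistics
#'
#' Computes, per non-overlapping window: covered bases (bases where every
#' clone is covered, from the masks), segregating sites S, the pi sum,
#' Watterson's theta `S / a1` and Tajima's D. Sites are reduced to the
#' complete-case polymorphic SNPs among `samples` before windowing.
#'
#' Because the printed unit of per-bp diversity is ambiguous in this kind of
#' table, both the raw per-window sums (`pi_sum`, `theta_w`) and
#' per-covered-bp values scaled by 1e3 (`pi_per_kbp`, `theta_per_kbp`,
#' "per-kbp equivalents") are emitted.
#'
#' @param x Variant table (filtered; will be reduced internally).
#' @param chrom_lengths Named chromosome lengths, bp.
#' @param samples Clones analyzed.
#' @param masks Coverage masks (see [window_covered_bases()]); `NULL` means
#'   fully covered.
#' @param window Window width, bp.
#' @return Tibble of windows with `covered_bases`, `S`, `pi_sum`, `theta_w`,
#'   `tajima_d`, `pi_per_kbp`, `theta_per_kbp`.
#' @export
windowed_diversity <- function(x, chrom_lengths,
                               samples = variant_samples(x),
                               masks = NULL, window = 50000) {
  sites <- polymorphic_sites(
    filter(x, .data$vtype == "SNP"),
    samples = samples, require_complete = TRUE
  )
  n_hap <- 2L * length(samples)
  gm <- gt_matrix(sites, samples)
  alt <- rowSums(gm)
  pi_site <- site_pi(alt, n_hap)
  wins <- tile_windows(chrom_lengths, window)
  wins <- window_covered_bases(wins, masks, samples)
  per_site <- tibble(
    chrom = sites$chrom,
    start = floor((sites$pos - 1) / window) * window,
    pi = pi_site
  )
  agg <- per_site |>
    group_by(.data$chrom, .data$start) |>
    summarise(S = dplyr::n(), pi_sum = sum(.data$pi), .groups = "drop")
  wins |>
    left_join(agg, by = c("chrom", "start")) |>
    mutate(
      S = coalesce(.data$S, 0L),
      pi_sum = coalesce(.data$pi_sum, 0),
      theta_w = watterson_theta(.data$S, n_hap),
      tajima_d = tajima_d(.data$S, .data$pi_sum, n_hap),
      pi_per_kbp = ifelse(.data$covered_bases > 0,
                          1e3 * .data$pi_sum / .data$covered_bases, NA_real_),
      theta_per_kbp = ifelse(.data$covered_bases > 0,
                             1e3 * .data$theta_w / .data$covered_bases, NA_real_)
    )
}

#' Per-chromosome (and genome-wide) diversity summary
#'
#' Aggregates [windowed_diversity()] windows: chromosome-level S and pi sums
#' are the sums over windows, theta and Tajima's D are recomputed from the
#' aggregated totals, covered bases are summed. A `Genome` row aggregates
#' everything.
#'
#' @param windows Result of [windowed_diversity()].
#' @param n_haplotypes Haplotype sample size used for the windows.
#' @return Tibble: one row per chromosome plus `Genome`, with
#'   `covered_bases`, `S`, `pi_sum`, `theta_w`, `tajima_d`, `pi_per_kbp`,
#'   `theta_per_kbp`.
#' @export
chromosome_diversity <- function(windows, n_haplotypes) {
  agg <- function(w, label) {
    tibble(
      region = label,
      covered_bases = sum(w$covered_bases),
      S = sum(w$S),
      pi_sum = sum(w$pi_sum)
    )
  }
  rows <- bind_rows(
    agg(windows, "Genome"),
    map_dfr(split(windows, windows$chrom), ~ agg(.x, .x$chrom[[1]]))
  )
  rows |>
    mutate(
      theta_w = watterson_theta(.data$S, n_haplotypes),
      tajima_d = tajima_d(.data$S, .data$pi_sum, n_haplotypes),
      pi_per_kbp = 1e3 * .data$pi_sum / .data$covered_bases,
      theta_per_kbp = 1e3 * .data$theta_w / .data$covered_bases
    )
}
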