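## Rate-threshold classification of genome windows into very-low / very-high
## variability regions, computed on the full clone-vs-reference variant set
## (not just the clone-polymorphic subset) with coverage-aware denominators.

#' Per-window variant counts and rates
#'
#' @param x Variant table (full filtered clone-vs-reference set).
#' @param chrom_lengths Named chromosome lengths, bp.
#' @param masks Coverage masks or `NULL`.
#' @param samples Samples whose joint coverage defines covered bases.
#' @param window Window width, bp.
#' @return Window tibble with `n_snp`, `n_indel`, `covered_bases`,
#'   `low_cov_bp`, `snp_per_kbp`, `indel_per_kbp` (rates over covered kbp;
#'   `NA` when nothing is covered).
#' @export
window_variant_density <- function(x, chrom_lengths, masks = NULL,
                                   samples = NULL, window = 50000) {
  wins <- tile_windows(chrom_lengths, window)
  wins <- window_covered_bases(wins, masks, samples)
  if (!is.null(samples)) {
    ## only sites actually carried by the analyzed panel count; records
    ## where every panel sample is hom-ref (e.g. outgroup-only variants)
    ## are not part of its variation against the reference
    carried <- rowSums(gt_matrix(x, samples) >= 1L, na.rm = TRUE) > 0
    x <- x[carried, , drop = FALSE]
  }
  ## rates are computed over jointly covered bases, so only variants inside
  ## the jointly covered territory enter the numerator — otherwise windows
  ## with partial coverage get inflated rates
  x <- x[jointly_covered(x$chrom, x$pos, masks, samples), , drop = FALSE]
  counts <- x |>
    filter(!is.na(.data$vtype)) |>
    mutate(start = floor((.data$pos - 1) / window) * window) |>
    count(.data$chrom, .data$start, .data$vtype) |>
    pivot_wider(names_from = "vtype", values_from = "n", values_fill = 0L)
  for (col in c("SNP", "INDEL")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  wins |>
    left_join(rename(counts, n_snp = "SNP", n_indel = "INDEL"),
              by = c("chrom", "start")) |>
    mutate(
      n_snp = coalesce(.data$n_snp, 0L),
      n_indel = coalesce(.data$n_indel, 0L),
      low_cov_bp = (.data$end - .data$start) - .data$covered_bases,
      snp_per_kbp = ifelse(.data$covered_bases > 0,
                           1e3 * .data$n_snp / .data$covered_bases, NA_real_),
      indel_per_kbp = ifelse(.data$covered_bases > 0,
                             1e3 * .data$n_indel / .data$covered_bases, NA_real_)
    )
}

#' Classify windows into low/high variability regions
#'
#' SNP classes: `LOW` at 1 SNP/kbp or rarer, `HIGH` at 1 SNP per 50 bp
#' (20/kbp) or more frequent. INDEL classes: `LOW_INDEL` below 0.2/kbp,
#' `HIGH_INDEL` above 2/kbp. Windows with zero covered bases stay
#' unclassified and break region merging. Adjacent same-class windows are
#' merged into maximal regions (idempotent).
#'
#' @param x Variant table, or a precomputed [window_variant_density()] tibble.
#' @param chrom_lengths,masks,samples,window Passed to
#'   [window_variant_density()] when `x` is a variant table.
#' @param low_snp,high_snp,low_indel,high_indel Rate thresholds, per kbp.
#' @return Region tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `class`, `variant_count`, `rate_per_kbp` (over covered bases).
#' @export
classify_density_regions <- function(x, chrom_lengths = NULL, masks = NULL,
                                     samples = NULL, window = 50000,
                                     low_snp = 1, high_snp = 20,
                                     low_indel = 0.2, high_indel = 2) {
  wins <- if (!is.null(x$snp_per_kbp)) {
    x
  } else {
    window_variant_density(x, chrom_lengths, masks, samples, window)
  }
  wins <- wins |>
    mutate(
      snp_class = case_when(
        is.na(.data$snp_per_kbp) ~ NA_character_,
        .data$snp_per_kbp <= low_snp ~ "LOW",
        .data$snp_per_kbp >= high_snp ~ "HIGH",
        TRUE ~ "MID"
      ),
      indel_class = case_when(
        is.na(.data$indel_per_kbp) ~ NA_character_,
        .data$indel_per_kbp < low_indel ~ "LOW_INDEL",
        .data$indel_per_kbp > high_indel ~ "HIGH_INDEL",
        TRUE ~ "MID_INDEL"
      )
    )
  merge_track <- function(wins, class_col, count_col, keep) {
    if (!any(wins[[class_col]] %in% keep)) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    class = character(), variant_count = integer(),
                    rate_per_kbp = double()))
    }
    wins |>
      group_by(.data$chrom) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(run = cumsum(
        coalesce(.data[[class_col]] != lag(.data[[class_col]]), TRUE) |
          is.na(.data[[class_col]]) |
          coalesce(is.na(lag(.data[[class_col]])), TRUE)
      )) |>
      filter(.data[[class_col]] %in% keep) |>
      group_by(.data$chrom, .data$run) |>
      summarise(
        start = min(.data$start), end = max(.data$end),
        class = .data[[class_col]][1],
        variant_count = sum(.data[[count_col]]),
        covered = sum(.data$covered_bases),
        .groups = "drop"
      ) |>
      mutate(rate_per_kbp = 1e3 * .data$variant_count / .data$covered) |>
      select(-"run", -"covered")
  }
  bind_rows(
    merge_track(wins, "snp_class", "n_snp", c("LOW", "HIGH")),
    merge_track(wins, "indel_class", "n_indel", c("LOW_INDEL", "HIGH_INDEL"))
  ) |>
    arrange(.data$class, .data$chrom, .data$start)
}

#' Total extent per density class
#'
#' @param regions Result of [classify_density_regions()].
#' @return Tibble `class`, `n_regions`, `mbp` (total extent in Mbp).
#' @export
density_summary <- function(regions) {
  regions |>
    group_by(.data$class) |>
    summarise(
      n_regions = dplyr::n(),
      mbp = sum(.data$end - .data$start) / 1e6,
      .groups = "drop"
    )
}

#' Are variant counts independent of coverage availability?
#'
#' Spearman rank correlation between per-window variant count and the amount
#' of low-coverage sequence in the window, with a permutation p-value. Used
#' to check that apparent low/high-variability regions are not artifacts of
#' coverage for variant calling.
#'
#' @param windows Result of [window_variant_density()].
#' @param what `"n_snp"` or `"n_indel"`.
#' @param n_perm Number of permutations for the p-value.
#' @return Tibble `rho`, `p_value`, `n_windows`. `rho` is `NA` for constant
#'   inputs.
#' @export
coverage_independence <- function(windows, what = "n_snp", n_perm = 999) {
  ok <- !is.na(windows[[what]]) & !is.na(windows$low_cov_bp)
  windows <- windows[ok, , drop = FALSE]
  v <- windows[[what]]
  lc <- windows$low_cov_bp
  if (sd(v) == 0 || sd(lc) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n_windows = length(v)))
  }
  rho <- cor(rank(v), rank(lc))
  perm <- vapply(seq_len(n_perm), function(i) {
    cor(rank(v), rank(sample(lc)))
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  tibble(rho = rho, p_value = p, n_windows = length(v))
}
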