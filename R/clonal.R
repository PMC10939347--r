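## Intra-varietal (clone-level) classification of variants: which sites are
## polymorphic within the clone panel, which are unique to a single clone,
## and the sharing / missingness spectra. Genotypes are unphased diploid
## dosages, so 0/1 and 1/0 are the same call by construction.

#' Sites polymorphic within the clone panel
#'
#' A site is polymorphic when at least one clone has a different genotype
#' call from the remaining clones, i.e. at least two distinct non-missing
#' dosages occur. With `require_complete = TRUE` (the default, matching the
#' no-missing-data analysis set) sites with any missing call among `samples`
#' are excluded first.
#'
#' @param x Variant table.
#' @param samples Clones to compare (default: all samples; pass the clone
#'   subset explicitly when an outgroup is present).
#' @param require_complete Drop sites with any missing genotype first?
#' @return The polymorphic subset of `x`.
#' @export
polymorphic_sites <- function(x, samples = variant_samples(x),
                              require_complete = TRUE) {
  gm <- gt_matrix(x, samples)
  if (require_complete) {
    keep <- rowSums(is.na(gm)) == 0
    x <- x[keep, , drop = FALSE]
    gm <- gm[keep, , drop = FALSE]
  }
  n_distinct_gt <- apply(gm, 1, function(g) length(unique(g[!is.na(g)])))
  x[n_distinct_gt >= 2, , drop = FALSE]
}

#' Clone-unique genotypes
#'
#' A site is unique to clone *c* when *c*'s genotype differs from all other
#' clones and all other clones are mutually identical (e.g. one clone `0/1`
#' against seven clones `1/1`). Sites with two or more distinct minority
#' genotypes are polymorphic but not clone-unique. Input should be the
#' complete-case polymorphic set ([polymorphic_sites()]); sites with missing
#' calls are never assigned.
#'
#' @param x Variant table (polymorphic, complete-case sites).
#' @param samples Clones to compare.
#' @return `x` restricted to clone-unique sites, with a `clone` column naming
#'   the divergent clone. Each site appears at most once.
#' @export
clone_unique_variants <- function(x, samples = variant_samples(x)) {
  gm <- gt_matrix(x, samples)
  n <- length(samples)
  assign_clone <- apply(gm, 1, function(g) {
    if (anyNA(g)) return(NA_character_)
    tab <- table(g)
    if (length(tab) != 2 || min(tab) != 1) return(NA_character_)
    minority <- as.integer(names(tab)[which.min(tab)])
    samples[which(g == minority)]
  })
  out <- x[!is.na(assign_clone), , drop = FALSE]
  out$clone <- assign_clone[!is.na(assign_clone)]
  out
}

#' Sharing and missingness spectra
#'
#' Two exact per-site spectra over the clone panel: for m in 0..n, the number
#' of sites with a valid (non-missing) genotype in exactly m clones; and for
#' k in 0..n, the number of sites whose non-reference state (dosage >= 1) is
#' carried by exactly k clones. Percentages are reported to two decimals via
#' [percent_of()].
#'
#' @param x Variant table.
#' @param samples Clones counted.
#' @return Long tibble with columns `spectrum` (`"valid_genotypes"` or
#'   `"nonref_carriers"`), `k`, `n_sites`, `percent`. Each spectrum sums to
#'   `nrow(x)`.
#' @export
sharing_spectra <- function(x, samples = variant_samples(x)) {
  gm <- gt_matrix(x, samples)
  n <- length(samples)
  total <- nrow(x)
  m_valid <- rowSums(!is.na(gm))
  k_carrier <- rowSums(gm >= 1L, na.rm = TRUE)
  spectrum_tbl <- function(label, v) {
    counts <- tabulate(v + 1L, nbins = n + 1L)
    tibble(
      spectrum = label, k = 0:n, n_sites = counts,
      percent = percent_of(counts, total)
    )
  }
  bind_rows(
    spectrum_tbl("valid_genotypes", m_valid),
    spectrum_tbl("nonref_carriers", k_carrier)
  )
}

#' Per-window density of clone-unique variants
#'
#' Counts clone-unique variants per clone in tumbling windows (1 Mbp by
#' default; a smaller `window` such as 1 kbp gives the resolution used to
#' pick high-mutation fragments). `stride` below `window` gives sliding
#' windows.
#'
#' @param unique_variants Result of [clone_unique_variants()].
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param window Window width, bp.
#' @param stride Window stride, bp (default: tumbling, `stride = window`).
#' @param clones Clones to report (default: those present; clones with no
#'   unique variants get all-zero tracks).
#' @return Tibble `clone`, `chrom`, `start`, `end`, `n_unique`,
#'   `per_mbp` (count scaled to a 1 Mbp equivalent).
#' @export
unique_variant_density <- function(unique_variants, chrom_lengths,
                                   window = 1e6, stride = window,
                                   clones = NULL) {
  clones <- clones %||% sort(unique(unique_variants$clone))
  grid <- map_dfr(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[[ch]] - 1, by = stride)
    tibble(chrom = ch, start = starts,
           end = pmin(starts + window, chrom_lengths[[ch]]))
  })
  grid <- tidyr::crossing(clone = clones, grid)
  counts <- unique_variants |>
    filter(.data$clone %in% .env$clones) |>
    mutate(start = floor((.data$pos - 1) / stride) * stride) |>
    count(.data$clone, .data$chrom, .data$start, name = "n_unique")
  if (stride != window) {
    ## sliding windows: recount against every covering window
    counts <- map_dfr(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      n <- sum(unique_variants$clone == g$clone &
                 unique_variants$chrom == g$chrom &
                 unique_variants$pos > g$start &
                 unique_variants$pos <= g$end)
      mutate(g, n_unique = n)
    })
    out <- counts
  } else {
    out <- left_join(grid, counts, by = c("clone", "chrom", "start")) |>
      mutate(n_unique = coalesce(.data$n_unique, 0L))
  }
  mutate(out, per_mbp = .data$n_unique * 1e6 / (.data$end - .data$start))
}
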