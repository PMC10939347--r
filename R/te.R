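## Transposable-element insertion (TEI) sharing. Non-reference insertions
## are only pinpointed (1 bp), so per-clone detections of the same event
## scatter around the true insertion point; detections of the same family on
## the same chromosome are merged into one event when their pinpoints are
## less than 10 kbp apart. The pairwise rule is applied transitively
## (single linkage), so a chained cluster can span more than 10 kbp.

#' Cluster TE insertion pinpoints into shared events
#'
#' Single-linkage clustering per (method, chrom, family): insertions are
#' sorted by position and consecutive pinpoints closer than `radius` bp are
#' linked (`< radius`, so two pinpoints exactly `radius` apart are distinct
#' events). An event's sharing level `k` is the number of distinct clones in
#' the cluster; a clone detected twice in one cluster is counted once and
#' flagged.
#'
#' @param te TE insertion table (`chrom`, `pos`, `family`, `te_class`,
#'   `clone`, and optionally `method`).
#' @param radius Merge radius, bp.
#' @param require_family Merge only within a family? Set `FALSE` to merge on
#'   proximity alone.
#' @return Event tibble: `event_id`, `method`, `chrom`, `family`,
#'   `te_class`, `pos` (median pinpoint), `pos_min`, `pos_max`, `k`
#'   (distinct clones), `n_members`, `n_duplicate` (extra detections of an
#'   already-counted clone), `clones` (list column).
#' @export
cluster_tei <- function(te, radius = 10000, require_family = TRUE) {
  if (!"method" %in% names(te)) te$method <- "all"
  te$.fam <- if (require_family) te$family else ""
  keys <- c("method", "chrom", ".fam")
  te |>
    arrange(across(all_of(keys)), .data$pos) |>
    group_by(across(all_of(keys))) |>
    mutate(cluster = cumsum(c(TRUE, diff(.data$pos) >= radius))) |>
    group_by(across(all_of(c(keys, "cluster")))) |>
    summarise(
      te_class = .data$te_class[1],
      family = paste(sort(unique(.data$family)), collapse = ","),
      pos_rep = as.integer(round(stats::median(.data$pos))),
      pos_min = min(.data$pos), pos_max = max(.data$pos),
      k = dplyr::n_distinct(.data$clone),
      n_members = dplyr::n(),
      n_duplicate = dplyr::n() - dplyr::n_distinct(.data$clone),
      clones = list(sort(unique(.data$clone))),
      .groups = "drop"
    ) |>
    mutate(event_id = paste0(.data$method, "_", dplyr::row_number()),
           pos = .data$pos_rep) |>
    select("event_id", "method", "chrom", "family", "te_class", "pos",
           "pos_min", "pos_max", "k", "n_members", "n_duplicate", "clones")
}

#' TEI sharing spectrum
#'
#' Counts of events shared by exactly k clones, with percentages to two
#' decimals, per method.
#'
#' @param events Result of [cluster_tei()].
#' @param n_clones Panel size (levels `1..n_clones` are always reported).
#' @return Tibble `method`, `k`, `n_events`, `percent`.
#' @export
tei_sharing_spectrum <- function(events, n_clones = max(events$k)) {
  events |>
    group_by(.data$method) |>
    summarise(counts = list(tabulate(.data$k, nbins = .env$n_clones)),
              .groups = "drop") |>
    mutate(spec = map(.data$counts,
                      ~ tibble(k = seq_along(.x), n_events = .x))) |>
    select(-"counts") |>
    unnest("spec") |>
    group_by(.data$method) |>
    mutate(percent = percent_of(.data$n_events, sum(.data$n_events))) |>
    ungroup()
}

#' TEI counts per TE class
#'
#' @param events Result of [cluster_tei()].
#' @return Tibble `method`, `te_class`, `n_events`, ordered most common
#'   first.
#' @export
tei_class_counts <- function(events) {
  events |>
    count(.data$method, .data$te_class, name = "n_events") |>
    arrange(.data$method, desc(.data$n_events))
}

#' Correlation between per-clone unique TEIs and unique SNPs
#'
#' Spearman rank correlation (mid-ranks for ties) between the number of
#' clone-exclusive TE insertions and the number of clone-unique SNPs, with
#' an exact permutation p-value (full enumeration for up to 8 clones,
#' Monte-Carlo above that).
#'
#' @param unique_tei Named vector or tibble (`clone`, `n`) of clone-exclusive
#'   TEI counts.
#' @param unique_snp Same, for clone-unique SNP counts; clones are aligned by
#'   name when names are present.
#' @param n_perm Monte-Carlo permutation count used when exact enumeration is
#'   infeasible.
#' @return Tibble `rho`, `p_value`, `n`, `exact`.
#' @export
tei_snp_correlation <- function(unique_tei, unique_snp, n_perm = 10000) {
  as_counts <- function(v) {
    if (is.data.frame(v)) setNames(v$n, v$clone) else v
  }
  x <- as_counts(unique_tei)
  y <- as_counts(unique_snp)
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]
    y <- y[common]
  }
  n <- length(x)
  if (n < 4) abort("need at least 4 clones for a meaningful correlation")
  spearman_perm(x, y, n_perm)
}

spearman_rho <- function(rx, ry) cor(rx, ry)

spearman_perm <- function(x, y, n_perm = 10000) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho <- spearman_rho(rx, ry)
  exact <- n <= 8
  if (exact) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1, function(p) spearman_rho(rx, ry[p]))
    p_val <- mean(abs(stats) >= abs(rho) - 1e-12)
  } else {
    stats <- vapply(seq_len(n_perm), function(i) {
      spearman_rho(rx, sample(ry))
    }, numeric(1))
    p_val <- (1 + sum(abs(stats) >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
  tibble(rho = rho, p_value = p_val, n = n, exact = exact)
}

## all n! permutations of 1..n as a matrix (rows); n <= 8 keeps this small
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}
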