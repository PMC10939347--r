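## Construction of the sequence sets used for motif enrichment: a control
## set of 1500 bp fragments from the middle of mutation-free 10 kbp windows,
## and high / very-high mutation sets of 1 kbp windows (plus 250 bp flanks)
## where a single clone accumulated more than 5 / more than 10 mutations.
## "Mutations" are clone-unique variants by default, following the
## clone-unique analysis these sets feed on.

#' Control (mutation-free) sequence set
#'
#' Tiles each chromosome into non-overlapping 10 kbp windows (trailing
#' partial windows are skipped), keeps windows without any mutation for any
#' clone, and extracts each window's middle portion at window-relative
#' offsets `[4250, 5750)` — 1500 bp per fragment.
#'
#' @param mutations Tibble of mutation positions (`chrom`, `pos`; typically
#'   [clone_unique_variants()] output).
#' @param reference A [Biostrings::DNAStringSet].
#' @param window Window width, bp.
#' @param core Window-relative extraction offsets (0-based half-open).
#' @return Tibble `label` (`"CONTROL"`), `chrom`, `start`, `end`, `seq`.
#' @export
build_control_set <- function(mutations, reference, window = 10000,
                              core = c(4250, 5750)) {
  lens <- setNames(Biostrings::width(reference), names(reference))
  wins <- tile_windows(lens, window, full_only = TRUE)
  hit <- mutations |>
    mutate(start = floor((.data$pos - 1) / window) * window) |>
    distinct(.data$chrom, .data$start) |>
    mutate(has_mut = TRUE)
  clean <- wins |>
    left_join(hit, by = c("chrom", "start")) |>
    filter(is.na(.data$has_mut))
  if (nrow(clean) == 0) {
    return(tibble(label = character(), chrom = character(),
                  start = integer(), end = integer(), seq = character()))
  }
  frag_start <- clean$start + core[[1]]
  frag_end <- clean$start + core[[2]]
  tibble(
    label = "CONTROL",
    chrom = clean$chrom,
    start = as.integer(frag_start),
    end = as.integer(frag_end),
    seq = extract_fragments(reference, clean$chrom, frag_start, frag_end)
  )
}

#' High and very-high mutation sequence sets
#'
#' Counts mutations per clone in tumbling 1 kbp windows; windows where some
#' clone accumulated strictly more than `thresholds[1]` mutations enter the
#' HIGH set and strictly more than `thresholds[2]` the VERY_HIGH subset.
#' Each fragment is the window plus `flank` bp on each side (1500 bp total);
#' fragments running off a chromosome end are skipped.
#'
#' @param mutations Tibble (`clone`, `chrom`, `pos`).
#' @param reference A [Biostrings::DNAStringSet].
#' @param thresholds Numeric pair: HIGH and VERY_HIGH minimum counts
#'   (exclusive).
#' @param window Window width, bp.
#' @param flank Flank width each side, bp.
#' @param stride Window stride (default tumbling).
#' @return List of two tibbles, `high` and `very_high`, each with `label`,
#'   `chrom`, `start`, `end`, `seq`, `clone`, `n_mutations`. `very_high` is
#'   a subset of `high` (relabelled).
#' @export
build_mutation_sets <- function(mutations, reference, thresholds = c(5, 10),
                                window = 1000, flank = 250, stride = window) {
  lens <- setNames(Biostrings::width(reference), names(reference))
  counts <- mutations |>
    mutate(start = floor((.data$pos - 1) / stride) * stride) |>
    count(.data$clone, .data$chrom, .data$start, name = "n_mutations")
  pick <- function(min_count, label) {
    sel <- counts |>
      filter(.data$n_mutations > min_count) |>
      group_by(.data$chrom, .data$start) |>
      slice_max(.data$n_mutations, n = 1, with_ties = FALSE) |>
      ungroup() |>
      mutate(
        frag_start = .data$start - flank,
        frag_end = .data$start + window + flank
      ) |>
      filter(.data$frag_start >= 0,
             .data$frag_end <= lens[.data$chrom])
    tibble(
      label = label,
      chrom = sel$chrom,
      start = as.integer(sel$frag_start),
      end = as.integer(sel$frag_end),
      seq = extract_fragments(reference, sel$chrom, sel$frag_start, sel$frag_end),
      clone = sel$clone,
      n_mutations = sel$n_mutations
    )
  }
  list(
    high = pick(thresholds[[1]], "HIGH"),
    very_high = pick(thresholds[[2]], "VERY_HIGH")
  )
}

extract_fragments <- function(reference, chrom, start0, end0) {
  vapply(seq_along(chrom), function(i) {
    as.character(Biostrings::subseq(
      reference[[chrom[i]]], start = start0[i] + 1L, end = end0[i]
    ))
  }, character(1))
}

#' Write sequence sets as FASTA
#'
#' Headers are `chrom:start-end:label` (0-based half-open coordinates), so a
#' round trip preserves both sequence and provenance. Ready for
#' STREME-style motif tools.
#'
#' @param sets A named list of sequence-set tibbles (e.g. `control`, `high`,
#'   `very_high`), or a single tibble.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_sequence_sets <- function(sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.data.frame(sets)) sets <- list(set = sets)
  paths <- imap(sets, function(s, name) {
    p <- file.path(dir, paste0(name, ".fasta"))
    if (nrow(s) == 0) {
      writeLines(character(0), p)
      return(p)
    }
    dss <- Biostrings::DNAStringSet(s$seq)
    names(dss) <- sprintf("%s:%d-%d:%s", s$chrom, s$start, s$end, s$label)
    Biostrings::writeXStringSet(dss, p)
    p
  })
  invisible(unlist(paths))
}
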