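## Simplified HIGH-impact variant-effect classification over CDS gene
## models: stop gained / stop lost / start lost for SNPs (by re-translating
## the affected codon on the coding strand), frameshift for
## length-not-divisible-by-three INDELs fully inside the CDS, and splice-site
## calls for variants within 2 bp of a CDS/intron boundary on the intron
## side. Everything else is impact "other" — only the HIGH categories are
## analyzed downstream, so MODERATE/LOW/MODIFIER are deliberately lumped.

HIGH_EFFECTS <- c("stop_gained", "stop_lost", "start_lost",
                  "frameshift_variant", "splice_site_variant")

## Standard genetic code lookup on a codon string; returns "*" for stops.
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

## Per-gene precomputation: CDS segments sorted genomically, coding-order
## cumulative offsets, spliced coding sequence.
prepare_gene <- function(seg, reference) {
  seg <- arrange(seg, .data$start)
  strand <- seg$strand[[1]]
  chrom_seq <- reference[[seg$chrom[[1]]]]
  pieces <- vapply(seq_len(nrow(seg)), function(i) {
    as.character(Biostrings::subseq(chrom_seq, seg$start[i] + 1L, seg$end[i]))
  }, character(1))
  cds <- paste0(pieces, collapse = "")
  if (strand == "-") {
    cds <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cds))
    )
  }
  widths <- seg$end - seg$start
  ## coding-order offset of the first base of each genomic segment
  if (strand == "+") {
    seg$coding_offset <- cumsum(c(0L, head(widths, -1)))
  } else {
    after <- rev(cumsum(c(0L, rev(widths)[-length(widths)])))
    seg$coding_offset <- after
  }
  list(seg = seg, strand = strand, cds = cds, cds_len = sum(widths))
}

## coding coordinate (0-based) of genomic 0-based position p0 inside segment i
coding_coord <- function(gene, i, p0) {
  seg <- gene$seg
  if (gene$strand == "+") {
    seg$coding_offset[i] + (p0 - seg$start[i])
  } else {
    seg$coding_offset[i] + (seg$end[i] - 1L - p0)
  }
}

classify_one <- function(chrom, pos, ref, alt, vtype, gene) {
  seg <- gene$seg
  p0 <- pos - 1L
  seg_idx <- which(seg$start <= p0 & p0 < seg$end)
  n_seg <- nrow(seg)
  flag <- NA_character_

  splice_hit <- function(span_start, span_end) {
    ## internal CDS/intron boundaries, 2 bp on the intron side
    if (n_seg < 2) return(FALSE)
    donors <- seg$end[-n_seg]        # intron starts (0-based)
    acceptors <- seg$start[-1]       # intron ends
    any(span_start < donors + 2L & span_end > donors) ||
      any(span_start < acceptors & span_end > acceptors - 2L)
  }

  if (vtype == "SNP") {
    if (length(seg_idx) == 1) {
      cc <- coding_coord(gene, seg_idx, p0)
      codon_i <- cc %/% 3L
      in_codon <- cc %% 3L
      codon <- substr(gene$cds, 3L * codon_i + 1L, 3L * codon_i + 3L)
      alt_base <- if (gene$strand == "+") alt else DNA_COMP[[alt]]
      alt_codon <- codon
      substr(alt_codon, in_codon + 1L, in_codon + 1L) <- alt_base
      aa_ref <- translate_codon(codon)
      aa_alt <- translate_codon(alt_codon)
      effect <- if (codon_i == 0L && codon == "ATG" && alt_codon != "ATG") {
        "start_lost"
      } else if (aa_alt == "*" && aa_ref != "*") {
        "stop_gained"
      } else if (aa_ref == "*" && aa_alt != "*") {
        "stop_lost"
      } else {
        "none"
      }
      return(list(effect = effect, flag = flag))
    }
    if (splice_hit(p0, p0 + 1L)) {
      return(list(effect = "splice_site_variant", flag = flag))
    }
    return(list(effect = "none", flag = flag))
  }

  ## INDEL: affected genomic span (0-based half-open)
  len <- abs(nchar(alt) - nchar(ref))
  if (nchar(ref) > nchar(alt)) {
    span_start <- p0 + 1L
    span_end <- p0 + 1L + len
  } else {
    ## insertion point between p0 and p0 + 1
    span_start <- p0 + 1L
    span_end <- p0 + 1L
  }
  inside <- if (nchar(ref) > nchar(alt)) {
    which(seg$start <= span_start & span_end <= seg$end)
  } else {
    ## insertion: both flanking bases must be CDS for the inserted sequence
    ## to land inside the coding region
    which(seg$start <= p0 & p0 + 1L < seg$end)
  }
  overlaps <- which(pmax(span_start, seg$start) <
                      pmin(span_end, seg$end))
  if (length(inside) >= 1) {
    effect <- if (len %% 3L != 0L) "frameshift_variant" else "none"
    return(list(effect = effect, flag = flag))
  }
  if (length(overlaps) >= 1) {
    ## partial CDS-edge overlap: conservative splice call, flagged
    return(list(effect = "splice_site_variant", flag = "partial_cds_overlap"))
  }
  if (splice_hit(span_start, max(span_end, span_start + 1L))) {
    return(list(effect = "splice_site_variant", flag = flag))
  }
  list(effect = "none", flag = flag)
}

#' Classify variant effects against gene models
#'
#' For each variant overlapping a gene (with a 2 bp pad for splice sites),
#' emits the simplified effect call: `stop_gained`, `stop_lost`,
#' `start_lost` (SNPs, affected codon re-translated on the coding strand),
#' `frameshift_variant` (INDELs of length not divisible by 3 fully inside
#' the CDS), `splice_site_variant` (within 2 bp of an internal CDS/intron
#' boundary on the intron side; also the conservative, flagged call for
#' INDELs partially overlapping a CDS edge), or `none`. Impact is `HIGH` for
#' the five named effects and `other` otherwise. Variants are assumed
#' normalized (left-aligned, minimal representation).
#'
#' @param x Variant table (biallelic records; multiallelic rows are skipped).
#' @param genes Gene-model table ([read_gene_models()] layout).
#' @param reference A [Biostrings::DNAStringSet].
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `vtype`, `gene_id`,
#'   `effect`, `impact`, `flag` — one row per variant-gene pair with a gene
#'   overlap (variants hitting no gene are omitted).
#' @export
classify_variant_effects <- function(x, genes, reference) {
  x <- filter(x, !is.na(.data$vtype))
  gene_ids <- unique(genes$gene_id)
  prepped <- map(setNames(gene_ids, gene_ids), function(gid) {
    prepare_gene(genes[genes$gene_id == gid, , drop = FALSE], reference)
  })
  spans <- genes |>
    group_by(.data$gene_id, .data$chrom) |>
    summarise(gstart = min(.data$start) - 2L,
              gend = max(.data$end) + 2L, .groups = "drop")
  hits <- x |>
    mutate(.row = dplyr::row_number(),
           span_end = .data$pos - 1L + pmax(nchar(.data$ref), 1L)) |>
    inner_join(spans, by = "chrom", relationship = "many-to-many") |>
    filter(.data$span_end > .data$gstart, .data$pos - 1L < .data$gend)
  if (nrow(hits) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), vtype = character(),
                  gene_id = character(), effect = character(),
                  impact = character(), flag = character()))
  }
  calls <- map(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    classify_one(h$chrom, h$pos, h$ref, h$alt, h$vtype,
                 prepped[[h$gene_id]])
  })
  tibble(
    chrom = hits$chrom,
    pos = hits$pos,
    ref = hits$ref,
    alt = hits$alt,
    vtype = hits$vtype,
    gene_id = hits$gene_id,
    effect = map_chr(calls, "effect"),
    impact = ifelse(map_chr(calls, "effect") %in% HIGH_EFFECTS,
                    "HIGH", "other"),
    flag = map_chr(calls, ~ .x$flag %||% NA_character_)
  )
}

#' Summaries of HIGH-impact calls
#'
#' Counts and percentages of HIGH-impact calls among polymorphic SNPs and
#' INDELs, the per-effect-type breakdown, and (when clone-unique sites are
#' supplied) how many HIGH calls are exclusive to one clone.
#'
#' @param calls Result of [classify_variant_effects()].
#' @param polymorphic_totals Named vector, total polymorphic `SNP` and
#'   `INDEL` counts (the percentage denominators).
#' @param unique_sites Optional [clone_unique_variants()] result used to
#'   count clone-exclusive HIGH calls.
#' @return List of tibbles: `by_type` (`vtype`, `n_high`, `total`,
#'   `percent`, and `n_unique` if available) and `by_effect` (per
#'   `vtype`/`effect` HIGH counts with percentages among HIGH calls).
#' @export
summarize_high_impact <- function(calls, polymorphic_totals,
                                  unique_sites = NULL) {
  high <- calls |>
    filter(.data$impact == "HIGH") |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
             .data$vtype, .data$effect)
  by_type <- tibble(vtype = names(polymorphic_totals),
                    total = as.integer(polymorphic_totals)) |>
    left_join(count(high, .data$vtype, name = "n_high"), by = "vtype") |>
    mutate(n_high = coalesce(.data$n_high, 0L),
           percent = percent_of(.data$n_high, .data$total)) |>
    select("vtype", "n_high", "total", "percent")
  if (!is.null(unique_sites)) {
    uniq <- semi_join(high, unique_sites, by = c("chrom", "pos"))
    by_type <- left_join(
      by_type, count(uniq, .data$vtype, name = "n_unique"), by = "vtype"
    ) |>
      mutate(n_unique = coalesce(.data$n_unique, 0L))
  }
  by_effect <- high |>
    count(.data$vtype, .data$effect, name = "n") |>
    group_by(.data$vtype) |>
    mutate(percent = percent_of(.data$n, sum(.data$n))) |>
    ungroup()
  list(by_type = by_type, by_effect = by_effect)
}
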