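## Readers and writers for the standard interchange formats: VCF 4.2 for the
## variant table (via vcfR on the way in), FASTA via Biostrings, BED coverage
## masks and GFF3 gene models via rtracklayer, and TSV TE tables via readr.

DOSAGE_TO_GT <- c("0/0", "0/1", "1/1")
GT_TO_DOSAGE <- c(
  "0/0" = 0L, "0|0" = 0L,
  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
  "1/1" = 2L, "1|1" = 2L
)

#' Write a variant table as VCF 4.2
#'
#' Emits per-sample `GT:DP` and the site `QD` in INFO; positions are sorted
#' per chromosome before writing. Missing genotypes become `./.`.
#'
#' @param x Variant table.
#' @param path Output path.
#' @param chrom_lengths Optional named vector used for `##contig` headers
#'   (and for chromosome ordering).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, chrom_lengths = NULL) {
  if (nrow(x) == 0) abort("refusing to write an empty variant table")
  samples <- variant_samples(x)
  x <- sort_variants(x, names(chrom_lengths))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=clonescan",
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>",
              names(chrom_lengths), as.integer(chrom_lengths))
    },
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gm <- gt_matrix(x, samples)
  cells <- matrix("./.", nrow = nrow(x), ncol = length(samples))
  ok <- !is.na(gm)
  cells[ok] <- DOSAGE_TO_GT[gm[ok] + 1L]
  for (j in seq_along(samples)) {
    dp <- x[[paste0("dp_", samples[j])]]
    dp <- if (is.null(dp)) rep(".", nrow(x)) else as.character(dp)
    cells[, j] <- paste0(cells[, j], ":", dp)
  }
  info <- ifelse(is.na(x$qd), ".", paste0("QD=", format(x$qd, trim = TRUE)))
  lines <- paste(
    x$chrom, x$pos, ".", x$ref, x$alt, ".", ".", info, "GT:DP",
    apply(cells, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a multi-sample VCF into a variant table
#'
#' Parses with \pkg{vcfR} and converts to the package's tidy variant layout:
#' unphased genotypes become alt-allele dosages (`0/1` and `1/0` are the same
#' call), `./.` becomes `NA`, and `vtype` is `"SNP"` for 1 bp ref/alt,
#' `"INDEL"` for length-changing biallelic records, and `NA` for
#' multiallelic or other records.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A variant table tibble.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  samples <- colnames(gt)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  vtype <- dplyr::case_when(
    multi ~ NA_character_,
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 ~ "SNP",
    nchar(fix$REF) != nchar(fix$ALT) ~ "INDEL",
    TRUE ~ NA_character_
  )
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    vtype = vtype,
    qd = qd
  )
  for (s in samples) {
    out[[paste0("gt_", s)]] <- unname(GT_TO_DOSAGE[gt[, s]])
  }
  for (s in samples) {
    out[[paste0("dp_", s)]] <- as.integer(dp[, s])
  }
  out
}

#' Write per-sample coverage masks as BED files
#'
#' One 3-column BED per sample (`<sample>.bed`, 0-based half-open intervals
#' where that sample is adequately covered).
#'
#' @param masks Tibble (`sample`, `chrom`, `start`, `end`).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_coverage_masks <- function(masks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in unique(masks$sample)) {
    m <- filter(masks, .data$sample == s)
    readr::write_tsv(m[c("chrom", "start", "end")],
                     file.path(dir, paste0(s, ".bed")),
                     col_names = FALSE)
  }
  invisible(dir)
}

#' Read per-sample coverage masks from BED files
#'
#' @param paths Named character vector of BED paths (names are sample ids),
#'   or a directory containing `<sample>.bed` files.
#' @return Tibble (`sample`, `chrom`, `start`, `end`), 0-based half-open.
#' @export
read_coverage_masks <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.bed$", full.names = TRUE)
    paths <- setNames(files, sub("\\.bed$", "", basename(files)))
  }
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.bed$", "", basename(paths))
  }
  map_dfr(names(paths), function(s) {
    gr <- rtracklayer::import(paths[[s]], format = "BED")
    tibble(
      sample = s,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = as.integer(GenomicRanges::start(gr) - 1L),
      end = as.integer(GenomicRanges::end(gr))
    )
  })
}

#' Write toy gene models as GFF3
#'
#' @param genes Gene-model table (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `exon_rank`, `phase`; 0-based half-open CDS segments).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  spans <- genes |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gene_gr <- GenomicRanges::GRanges(
    spans$chrom,
    IRanges::IRanges(spans$start + 1L, spans$end),
    strand = spans$strand,
    type = "gene", ID = spans$gene_id
  )
  cds_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand,
    type = "CDS",
    ID = paste0(genes$gene_id, ".cds", genes$exon_rank),
    Parent = genes$gene_id,
    phase = as.integer(genes$phase)
  )
  gr <- c(gene_gr, cds_gr)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read CDS gene models from a GFF3 annotation
#'
#' Keeps `CDS` features only; on-disk 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention.
#'
#' @param path GFF3 path.
#' @return Gene-model table as in [write_gene_models()].
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "CDS"]
  parent <- as.character(S4Vectors::unstrsplit(gr$Parent, ","))
  out <- tibble(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = as.integer(GenomicRanges::start(gr) - 1L),
    end = as.integer(GenomicRanges::end(gr)),
    phase = as.integer(gr$phase)
  )
  out |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id) |>
    mutate(exon_rank = row_number()) |>
    ungroup() |>
    select("gene_id", "chrom", "strand", "start", "end", "exon_rank", "phase")
}

#' Write per-method TE insertion tables
#'
#' One tab-separated file per caller method (`te_<method>.tsv`) with columns
#' chrom, pos, family, te_class, clone, method. Empty inputs still produce
#' header-only files.
#'
#' @param te TE insertion table.
#' @param dir Output directory.
#' @param methods Methods to write (default: those present, or all configured
#'   method labels if supplied).
#' @return Paths written, invisibly.
#' @export
write_te_tables <- function(te, dir, methods = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  methods <- methods %||% unique(te$method)
  cols <- c("chrom", "pos", "family", "te_class", "clone", "method")
  paths <- map(methods, function(m) {
    p <- file.path(dir, paste0("te_", m, ".tsv"))
    tab <- filter(te, .data$method == m)
    if (nrow(tab) == 0) {
      tab <- tibble(chrom = character(), pos = integer(), family = character(),
                    te_class = character(), clone = character(),
                    method = character())
    }
    readr::write_tsv(tab[cols], p)
    p
  })
  invisible(unlist(paths))
}

#' Read TE insertion tables written by [write_te_tables()]
#'
#' @param paths TSV paths, or a directory of `te_*.tsv` files.
#' @return Combined TE insertion tibble.
#' @export
read_te_tables <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "^te_.*\\.tsv$", full.names = TRUE)
  }
  map_dfr(paths, function(p) {
    readr::read_tsv(
      p,
      col_types = readr::cols(
        chrom = readr::col_character(), pos = readr::col_integer(),
        family = readr::col_character(), te_class = readr::col_character(),
        clone = readr::col_character(), method = readr::col_character()
      )
    )
  })
}

#' Write every artifact of a simulated population to a directory
#'
#' Writes `reference.fasta`, `variants.vcf`, `genes.gff3`, per-sample
#' coverage masks under `masks/`, per-method TE tables under `te/`, and the
#' IBD tracts as `ibd_tracts.bed`.
#'
#' @param sim A [simulate_population()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "clone_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$reference, file.path(dir, "reference.fasta"))
  write_vcf(sim$variants, file.path(dir, "variants.vcf"),
            chrom_lengths = sim$config$chrom_lengths)
  write_gene_models(sim$genes, file.path(dir, "genes.gff3"))
  write_coverage_masks(sim$masks, file.path(dir, "masks"))
  write_te_tables(sim$te, file.path(dir, "te"), methods = sim$config$te_methods)
  readr::write_tsv(sim$truth$ibd_tracts, file.path(dir, "ibd_tracts.bed"),
                   col_names = FALSE)
  invisible(dir)
}
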