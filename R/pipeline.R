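## End-to-end orchestration: simulate (or read) -> filter -> clonal
## classification -> diversity -> relatedness -> density regions -> motif
## sequence sets -> effects -> TE sharing, with every artifact written to an
## output directory and a single machine-readable JSON summary of the
## headline numbers. All thresholds default to the analysis constants used
## throughout the package (DP 5, QD 20, 15 bp SNP-near-INDEL, 50 bp INDEL
## gap, 100 bp INDEL length, 50% missingness, 50 kbp windows, 1 kbp motif
## windows, 250 bp flanks, 4250-5750 control core, >5/>10 mutation
## thresholds, 10 kbp TE merge radius).

#' Pipeline configuration
#'
#' Either a `sim` block (a [sim_config()]) for a fully simulated run, or a
#' `paths` block naming on-disk inputs (`vcf`, `fasta`, `gff`, `te` tables,
#' `masks` directory). Thresholds default to the package's analysis
#' constants.
#'
#' @param out_dir Output directory.
#' @param sim A [sim_config()], or `NULL` when reading real inputs.
#' @param paths Named list of input paths (`vcf`, `fasta`, `gff`, `te`,
#'   `masks`), or `NULL` when simulating.
#' @param seed Seed for analysis-stage randomness (permutation p-values);
#'   simulation randomness is governed by `sim$seed`.
#' @param window Diversity/density window width, bp.
#' @param outgroup_sample Sample excluded from clone-level analyses (and
#'   used as the kinship outgroup), or `NULL`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), paths = NULL,
                            seed = 1L, window = 50000,
                            outgroup_sample = if (!is.null(sim) && sim$outgroup) "outgroup") {
  if (is.null(sim) && is.null(paths)) {
    abort("either a sim block or input paths are required")
  }
  structure(
    list(out_dir = out_dir, sim = sim, paths = paths, seed = as.integer(seed),
         window = window, outgroup_sample = outgroup_sample),
    class = "pipeline_config"
  )
}

#' Run the whole analysis pipeline
#'
#' Produces, under `config$out_dir`: the raw and filtered VCFs and filter
#' report, sharing/missingness spectra, clone-unique site BEDs and density
#' tracks, per-chromosome and windowed diversity tables, kinship and PCA
#' tables, density-region BEDs and summary, the three motif FASTA sets, the
#' effect-call table and HIGH-impact summary, TE event and sharing tables,
#' and `summary.json` collecting every headline number. Identical
#' configuration (including seeds) gives an identical summary.
#'
#' @param config A [pipeline_config()].
#' @return The summary (a list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  ## ---- inputs ----
  if (!is.null(config$sim)) {
    sim <- simulate_population(config$sim)
    variants <- sim$variants
    reference <- sim$reference
    genes <- sim$genes
    te <- sim$te
    masks <- sim$masks
    chrom_lengths <- config$sim$chrom_lengths
    write_vcf(variants, out("variants_raw.vcf"), chrom_lengths)
  } else {
    p <- config$paths
    variants <- read_vcf(p$vcf)
    reference <- Biostrings::readDNAStringSet(p$fasta)
    names(reference) <- sub("\\s.*$", "", names(reference))
    genes <- read_gene_models(p$gff)
    te <- read_te_tables(p$te)
    masks <- if (!is.null(p$masks)) read_coverage_masks(p$masks)
    chrom_lengths <- setNames(Biostrings::width(reference), names(reference))
    sim <- NULL
  }
  samples <- variant_samples(variants)
  clones <- setdiff(samples, config$outgroup_sample)

  ## ---- filter cascade ----
  filtered <- filter_cascade(variants, samples = clones)
  report <- filter_report(filtered)
  write_vcf(filtered, out("variants_filtered.vcf"), chrom_lengths)
  readr::write_tsv(report, out("filter_report.tsv"))

  ## ---- clonal classification ----
  spectra <- sharing_spectra(filtered, samples = clones)
  readr::write_tsv(spectra, out("sharing_spectra.tsv"))
  poly <- polymorphic_sites(filtered, samples = clones)
  uniq <- clone_unique_variants(poly, samples = clones)
  for (cl in unique(uniq$clone)) {
    u <- filter(uniq, .data$clone == cl)
    readr::write_tsv(
      tibble(chrom = u$chrom, start = u$pos - 1L, end = u$pos),
      out(paste0("unique_", cl, ".bed")), col_names = FALSE
    )
  }
  dens_tracks <- unique_variant_density(uniq, chrom_lengths, clones = clones)
  readr::write_tsv(dens_tracks, out("unique_density_1mbp.tsv"))

  ## ---- diversity ----
  wins <- windowed_diversity(filtered, chrom_lengths, samples = clones,
                             masks = masks, window = config$window)
  chrom_div <- chromosome_diversity(wins, 2L * length(clones))
  readr::write_tsv(wins, out("diversity_windows.tsv"))
  readr::write_tsv(chrom_div, out("diversity_chromosomes.tsv"))

  ## ---- relatedness ----
  kin <- kinship_matrix(filtered, samples = samples)
  readr::write_tsv(tidy(kin), out("kinship.tsv"))
  pca <- genotype_pca(filtered, samples = clones, k = 2)
  readr::write_tsv(tidy(pca), out("pca_scores.tsv"))

  ## ---- density regions ----
  dens_windows <- window_variant_density(filtered, chrom_lengths, masks,
                                         samples = clones,
                                         window = config$window)
  regions <- classify_density_regions(dens_windows)
  readr::write_tsv(regions, out("density_regions.tsv"))
  dens_sum <- density_summary(regions)
  readr::write_tsv(dens_sum, out("density_summary.tsv"))
  ## independence is judged on the coverage-corrected rate: the raw count is
  ## trivially tied to how much territory was callable
  cov_ind <- withr::with_seed(config$seed + 1L,
                              coverage_independence(dens_windows,
                                                    what = "snp_per_kbp"))

  ## ---- motif sequence sets ----
  sets <- c(
    list(control = build_control_set(uniq, reference)),
    build_mutation_sets(uniq[c("clone", "chrom", "pos")], reference)
  )
  write_sequence_sets(sets, out("motif_sets"))

  ## ---- effects ----
  effects <- classify_variant_effects(poly, genes, reference)
  readr::write_tsv(effects, out("effect_calls.tsv"))
  poly_totals <- c(
    SNP = sum(poly$vtype == "SNP", na.rm = TRUE),
    INDEL = sum(poly$vtype == "INDEL", na.rm = TRUE)
  )
  high <- summarize_high_impact(effects, poly_totals, unique_sites = uniq)
  readr::write_tsv(high$by_type, out("high_impact_by_type.tsv"))
  readr::write_tsv(high$by_effect, out("high_impact_by_effect.tsv"))

  ## ---- transposable elements ----
  events <- cluster_tei(te)
  readr::write_tsv(select(events, -"clones"), out("te_events.tsv"))
  te_spec <- tei_sharing_spectrum(events, n_clones = length(clones))
  readr::write_tsv(te_spec, out("te_sharing_spectrum.tsv"))
  te_classes <- tei_class_counts(events)
  readr::write_tsv(te_classes, out("te_class_counts.tsv"))
  uniq_snp_counts <- count(uniq, .data$clone, name = "n")
  excl <- events |>
    filter(.data$k == 1) |>
    mutate(clone = map_chr(.data$clones, 1)) |>
    count(.data$method, .data$clone, name = "n")
  te_cor <- map_dfr(unique(excl$method), function(m) {
    tei <- filter(excl, .data$method == m)
    tei <- left_join(tibble(clone = clones), tei["clone"] |> mutate(n = tei$n),
                     by = "clone") |>
      mutate(n = coalesce(.data$n, 0L))
    snp <- left_join(tibble(clone = clones), uniq_snp_counts, by = "clone") |>
      mutate(n = coalesce(.data$n, 0L))
    withr::with_seed(config$seed + 2L,
                     mutate(tei_snp_correlation(tei, snp), method = m))
  })
  readr::write_tsv(te_cor, out("te_snp_correlation.tsv"))

  ## ---- summary ----
  n_complete <- spectra$n_sites[spectra$spectrum == "valid_genotypes" &
                                  spectra$k == length(clones)]
  summary <- list(
    samples = samples,
    clones = clones,
    n_input = report$n[report$stage == "input"],
    n_retained = report$n[report$stage == "retained"],
    filter_report = setNames(as.list(report$n), report$stage),
    percent_complete = percent_of(n_complete, nrow(filtered)),
    n_polymorphic = nrow(poly),
    n_unique_total = nrow(uniq),
    percent_unique = percent_of(nrow(uniq), nrow(poly)),
    unique_per_clone = setNames(
      as.list(tabulate(factor(uniq$clone, levels = clones),
                       nbins = length(clones))), clones),
    genome_tajima_d = chrom_div$tajima_d[chrom_div$region == "Genome"],
    genome_pi_per_kbp = chrom_div$pi_per_kbp[chrom_div$region == "Genome"],
    genome_theta_per_kbp = chrom_div$theta_per_kbp[chrom_div$region == "Genome"],
    kinship_clone_range = range(
      tidy(kin) |>
        filter(.data$sample_i != .data$sample_j,
               .data$sample_i %in% clones, .data$sample_j %in% clones) |>
        pull(.data$kinship)
    ),
    pca_var_explained = pca$var_explained,
    pc1_extreme_sample = tidy(pca)$sample[which.max(abs(tidy(pca)$PC1))],
    density_mbp = setNames(as.list(dens_sum$mbp), dens_sum$class),
    coverage_independence = as.list(cov_ind),
    high_impact = setNames(as.list(high$by_type$percent), high$by_type$vtype),
    te_percent_exclusive = setNames(
      as.list(te_spec$percent[te_spec$k == 1]),
      unique(te_spec$method)
    ),
    te_snp_rho = setNames(as.list(te_cor$rho), te_cor$method)
  )
  if (!is.null(sim)) {
    summary$truth <- list(
      n_varietal = nrow(sim$truth$varietal),
      somatic_per_clone = setNames(
        as.list(tabulate(factor(sim$truth$somatic$clone, levels = clones),
                         nbins = length(clones))), clones)
    )
  }
  jsonlite::write_json(summary, out("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
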