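#' Configuration for the synthetic clone-population generator
#'
#' Bundles every tunable of [simulate_population()] with defaults emulating a
#' panel of eight whole-genome-sequenced clones of one variety: abundant
#' shared ("varietal") heterozygous variation against the reference genome,
#' low-variability identity-by-descent-like tracts, clone-specific somatic
#' mutations at heterogeneous per-clone rates (one strongly divergent clone),
#' genotype missingness, per-sample coverage dropouts, and pinpointed
#' transposable-element insertions whose sharing spectrum is dominated by
#' clone-exclusive events.
#'
#' @param seed Integer seed; the same seed and configuration give
#'   byte-identical outputs.
#' @param n_clones Number of clones in the panel.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param varietal_snp_rate Realized variety-vs-reference SNP rate outside IBD
#'   tracts, SNPs per kbp.
#' @param varietal_indel_rate Variety-vs-reference INDEL rate, INDELs per kbp.
#' @param ibd_fraction Fraction of the genome inside low-variability tracts.
#' @param ibd_rate Realized SNP rate inside tracts, SNPs per kbp (must be
#'   below `varietal_snp_rate`). Default 0.2: these tracts show low,
#'   "almost null" variability, well under the 1 SNP/kbp classification
#'   threshold even after clone-specific mutations accumulate on top.
#' @param somatic_rates Per-clone somatic SNP rates (SNPs per Mbp). `NULL`
#'   (default) draws the panel's rates at simulation time: the first clone at
#'   282 SNPs/Mbp and the remainder uniform in \[10, 28\].
#' @param somatic_indel_ratio Somatic INDELs per somatic SNP (clone-specific
#'   INDELs are planted at `somatic_rates * somatic_indel_ratio`).
#' @param somatic_hotspot_fraction Fraction of each clone's somatic SNPs
#'   concentrated into narrow clone-specific hotspots instead of being
#'   scattered uniformly. Clonal panels accumulate much of their variability
#'   in very narrow (kbp-scale) locations that differ between clones; the
#'   hotspots emulate that.
#' @param hotspot_width Hotspot width, bp (grid-aligned windows).
#' @param missing_rate Per-genotype missingness probability.
#' @param dropout_mean Expected number of low-coverage dropout intervals per
#'   sample per chromosome.
#' @param dropout_len Length range (bp) of a dropout interval.
#' @param low_qd_fraction Number of low-QD artifact sites, as a fraction of
#'   the true site count. Artifact sites carry random genotypes and a
#'   quality-by-depth below 20, so the filter cascade has real work to do.
#' @param freq_range Range of the population allele frequency drawn per locus
#'   (uniform); variety and outgroup genotypes are Hardy-Weinberg draws at
#'   that frequency, which is what makes clone-vs-outgroup kinship center on
#'   zero.
#' @param indel_max_len Maximum simulated INDEL length (bp). Lengths are a
#'   mixture of geometric(0.5) and uniform 50..`indel_max_len` draws so that
#'   the >100 bp length filter is actually exercised.
#' @param te_counts_by_sharing Named integer vector: number of TE insertion
#'   events shared by exactly k clones (names "1".."n_clones"), planted per
#'   caller method. The default scales a clone-exclusive-dominated spectrum
#'   (about 47% exclusive, about 1% shared by all) to 250 events.
#' @param te_methods Labels of the emulated TE callers; events are planted and
#'   later clustered per method.
#' @param te_jitter Pinpoint jitter, bp: each clone's pinpoint for a shared
#'   event is displaced uniformly in `[-te_jitter, te_jitter]` (kept well
#'   under half of the 10-kbp merge radius).
#' @param n_genes Number of toy protein-coding gene models placed on the
#'   reference (used by the effect classifier).
#' @param outgroup Add one unrelated accession ("outgroup") to the panel?
#' @param loh_fraction Fraction of somatic events simulated as
#'   loss-of-heterozygosity at an existing varietal het site (0/1 -> 1/1)
#'   instead of a het gain at a new site. Default 0 (het-gain only).
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_population()]
#' @export
sim_config <- function(seed = 1L,
                       n_clones = 8L,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                       varietal_snp_rate = 7.3,
                       varietal_indel_rate = 0.79,
                       ibd_fraction = 0.10,
                       ibd_rate = 0.2,
                       somatic_rates = NULL,
                       somatic_indel_ratio = 0.11,
                       somatic_hotspot_fraction = 0.3,
                       hotspot_width = 1000L,
                       missing_rate = 0.03,
                       dropout_mean = 1,
                       dropout_len = c(10000, 60000),
                       low_qd_fraction = 0.02,
                       freq_range = c(0.05, 0.95),
                       indel_max_len = 120L,
                       te_counts_by_sharing = NULL,
                       te_methods = c("popte2", "retroseq"),
                       te_jitter = 2000L,
                       n_genes = 60L,
                       outgroup = TRUE,
                       loh_fraction = 0) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (is.null(te_counts_by_sharing)) {
    te_counts_by_sharing <- default_te_spectrum(n_clones)
  }
  if (is.null(names(te_counts_by_sharing))) {
    names(te_counts_by_sharing) <- seq_along(te_counts_by_sharing)
  }
  cfg <- list(
    seed = as.integer(seed), n_clones = as.integer(n_clones),
    chrom_lengths = chrom_lengths,
    varietal_snp_rate = varietal_snp_rate,
    varietal_indel_rate = varietal_indel_rate,
    ibd_fraction = ibd_fraction, ibd_rate = ibd_rate,
    somatic_rates = somatic_rates,
    somatic_indel_ratio = somatic_indel_ratio,
    somatic_hotspot_fraction = somatic_hotspot_fraction,
    hotspot_width = as.integer(hotspot_width),
    missing_rate = missing_rate,
    dropout_mean = dropout_mean, dropout_len = dropout_len,
    low_qd_fraction = low_qd_fraction,
    freq_range = freq_range,
    indel_max_len = as.integer(indel_max_len),
    te_counts_by_sharing = te_counts_by_sharing,
    te_methods = te_methods, te_jitter = as.integer(te_jitter),
    n_genes = as.integer(n_genes),
    outgroup = isTRUE(outgroup),
    loh_fraction = loh_fraction
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

## Clone-exclusive-dominated sharing spectrum scaled to ~250 events per
## method: ~47% k=1, ~24% k=2, ~1% k=n, remainder spread over middle levels.
default_te_spectrum <- function(n_clones) {
  if (n_clones < 3) {
    out <- c(20, 5)[seq_len(n_clones)]
  } else {
    mid <- rep(71 %/% (n_clones - 3), n_clones - 3)
    if (length(mid) > 0) mid[1] <- mid[1] + 71 %% (n_clones - 3)
    out <- c(117, 59, mid, 3)
  }
  setNames(as.integer(out), seq_len(n_clones))
}

validate_sim_config <- function(cfg) {
  rates <- c(
    cfg$varietal_snp_rate, cfg$varietal_indel_rate, cfg$ibd_rate,
    cfg$missing_rate, cfg$low_qd_fraction, cfg$somatic_rates
  )
  if (any(rates < 0)) abort("all rates must be >= 0")
  if (cfg$ibd_fraction < 0 || cfg$ibd_fraction > 1) {
    abort("ibd_fraction must be in [0, 1]")
  }
  if (sum(cfg$chrom_lengths) <= 0) abort("sum of chrom_lengths must be > 0")
  if (cfg$ibd_rate > cfg$varietal_snp_rate) {
    abort("ibd_rate must not exceed varietal_snp_rate")
  }
  if (cfg$n_clones < 2) abort("need at least two clones")
  if (!is.null(cfg$somatic_rates) && length(cfg$somatic_rates) != cfg$n_clones) {
    abort("somatic_rates must have one entry per clone")
  }
  if (length(cfg$te_counts_by_sharing) != cfg$n_clones) {
    abort("te_counts_by_sharing must have one entry per sharing level 1..n_clones")
  }
  if (cfg$loh_fraction < 0 || cfg$loh_fraction > 1) {
    abort("loh_fraction must be in [0, 1]")
  }
  if (cfg$somatic_hotspot_fraction < 0 || cfg$somatic_hotspot_fraction > 1) {
    abort("somatic_hotspot_fraction must be in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  clones:", x$n_clones, if (x$outgroup) "+ outgroup" else "", "\n")
  cat("  genome:", length(x$chrom_lengths), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp\n")
  cat("  varietal rates:", x$varietal_snp_rate, "SNP/kbp,",
      x$varietal_indel_rate, "INDEL/kbp;",
      100 * x$ibd_fraction, "% IBD tracts at", x$ibd_rate, "SNP/kbp\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
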