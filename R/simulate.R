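## Synthetic clone-population generator.
##
## Model, in brief: a single diploid "variety" genome is drawn against a
## random reference at population loci (uniform allele frequency per locus,
## Hardy-Weinberg genotype). Every clone inherits the variety genotype at
## every locus (varietal variation), then accumulates its own clone-specific
## somatic het mutations at new positions. An optional unrelated outgroup is
## an independent Hardy-Weinberg draw at the same loci. Identity-by-descent
## tracts force the variety back to hom-ref at most tract loci, producing
## low-variability regions. Low-QD artifact sites, per-genotype missingness
## and per-sample coverage dropouts give the filter cascade realistic work.

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a clone population with a known truth set
#'
#' Generates a reference genome, a multi-sample variant table (clones plus an
#' optional unrelated outgroup), per-sample coverage masks, toy gene models,
#' per-method transposable-element insertion tables, and the truth set that
#' produced them. Identical `config` (including seed) gives identical output.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `clone_sim`: a list with elements `reference`
#'   (a [Biostrings::DNAStringSet]), `variants` (variant table, see
#'   [gt_matrix()]), `masks` (covered intervals per sample), `dropouts`
#'   (their complement), `genes` (CDS segment table), `te` (TE insertion
#'   pinpoints), `truth` (list: `varietal`, `somatic`, `ibd_tracts`,
#'   `te_events`, `artifacts`) and the realized `config`.
#' @examples
#' sim <- simulate_population(sim_config(seed = 42, chrom_lengths = c(chrA = 2e5)))
#' sim$truth$somatic
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    lens <- config$chrom_lengths
    chroms <- names(lens)
    clones <- paste0("clone_", seq_len(config$n_clones))
    samples <- c(clones, if (config$outgroup) "outgroup")

    if (is.null(config$somatic_rates)) {
      config$somatic_rates <-
        c(282, runif(config$n_clones - 1, 10, 28))
    }
    names(config$somatic_rates) <- clones

    ref_chars <- lapply(lens, function(L) sample(DNA_BASES, L, replace = TRUE))

    tracts <- draw_ibd_tracts(lens, config$ibd_fraction)

    genes <- place_gene_models(lens, config$n_genes)
    ref_chars <- patch_reference_for_genes(ref_chars, genes)

    ## per-clone somatic counts (Poisson around rate x genome size)
    genome_mbp <- sum(lens) / 1e6
    somatic_n <- vapply(
      config$somatic_rates,
      function(r) rpois(1, r * genome_mbp), integer(1)
    )
    somatic_indel_n <- vapply(
      config$somatic_rates,
      function(r) rpois(1, r * config$somatic_indel_ratio * genome_mbp),
      integer(1)
    )

    pieces <- lapply(chroms, function(ch) {
      simulate_chrom_variants(
        ch, ref_chars[[ch]], tracts, config, clones,
        somatic_share = lens[[ch]] / sum(lens),
        somatic_n = somatic_n, somatic_indel_n = somatic_indel_n
      )
    })
    variants <- bind_rows(map(pieces, "variants"))
    truth_varietal <- bind_rows(map(pieces, "varietal"))
    truth_somatic <- bind_rows(map(pieces, "somatic"))
    truth_artifacts <- bind_rows(map(pieces, "artifacts"))

    if (config$loh_fraction > 0) {
      conv <- convert_to_loh(variants, truth_somatic, clones, config$loh_fraction)
      variants <- conv$variants
      truth_somatic <- conv$somatic
    }

    variants <- add_site_annotations(variants, samples, config)
    cov <- draw_coverage(lens, samples, config)
    variants <- apply_missingness(variants, samples, cov$dropouts, config$missing_rate)
    variants <- sort_variants(variants, chroms)

    te <- simulate_te(lens, clones, config)

    structure(
      list(
        reference = Biostrings::DNAStringSet(
          setNames(vapply(ref_chars, paste0, character(1), collapse = ""), chroms)
        ),
        variants = variants,
        masks = cov$masks,
        dropouts = cov$dropouts,
        genes = genes,
        te = te$table,
        truth = list(
          varietal = truth_varietal,
          somatic = truth_somatic,
          ibd_tracts = tracts,
          te_events = te$events,
          artifacts = truth_artifacts
        ),
        samples = samples,
        clones = clones,
        config = config
      ),
      class = "clone_sim"
    )
  })
}

#' @export
print.clone_sim <- function(x, ...) {
  cat("<clone_sim>", length(x$clones), "clones",
      if (x$config$outgroup) "+ outgroup", "on",
      format(sum(x$config$chrom_lengths), big.mark = ","), "bp\n")
  cat("  sites:", nrow(x$variants),
      sprintf("(%d varietal, %d somatic, %d artifact)",
              nrow(x$truth$varietal), nrow(x$truth$somatic),
              nrow(x$truth$artifacts)), "\n")
  cat("  TE insertions:", nrow(x$te), "in", nrow(x$truth$te_events), "events\n")
  invisible(x)
}

## One contiguous tract per chromosome, boundaries on a 50-kbp grid so the
## tract is recoverable by window-rate classification.
draw_ibd_tracts <- function(lens, ibd_fraction) {
  grid <- 50000L
  map_dfr(names(lens), function(ch) {
    n_win <- floor(lens[[ch]] / grid)
    n_tract <- round(ibd_fraction * n_win)
    if (n_tract == 0) {
      return(tibble(chrom = character(), start = integer(), end = integer()))
    }
    s <- sample.int(n_win - n_tract + 1L, 1L) - 1L
    tibble(chrom = ch, start = s * grid, end = (s + n_tract) * grid)
  })
}

hwe_draw <- function(p) {
  u <- runif(length(p))
  q2 <- (1 - p)^2
  as.integer((u >= q2) + (u >= q2 + 2 * p * (1 - p)))
}

## E[1 - (1-p)^2] for p ~ U(a, b): expected probability that a diploid
## Hardy-Weinberg draw carries at least one non-reference allele.
mean_nonref_prob <- function(freq_range) {
  a <- freq_range[[1]]
  b <- freq_range[[2]]
  (a + b) - (a^2 + a * b + b^2) / 3
}

simulate_chrom_variants <- function(ch, ref, tracts, config, clones,
                                    somatic_share, somatic_n, somatic_indel_n) {
  L <- length(ref)
  p_nonref <- mean_nonref_prob(config$freq_range)
  lambda_snp <- config$varietal_snp_rate / 1000 / p_nonref
  lambda_ind <- config$varietal_indel_rate / 1000 / p_nonref

  n_snp <- rpois(1, lambda_snp * L)
  n_ind <- rpois(1, lambda_ind * L)
  n_som <- vapply(somatic_n, function(n) rbinom(1, n, somatic_share), integer(1))
  n_som_ind <- vapply(somatic_indel_n, function(n) rbinom(1, n, somatic_share), integer(1))

  n_true <- n_snp + n_ind + sum(n_som) + sum(n_som_ind)
  n_art <- rpois(1, config$low_qd_fraction * n_true)
  n_total <- n_true + n_art

  ## one draw without replacement guarantees no duplicate positions; a margin
  ## at both chromosome ends keeps deletion spans in bounds
  margin <- config$indel_max_len + 30L
  pos_all <- sample.int(L - 2L * margin, n_total) + margin
  idx <- cumsum(c(n_snp, n_ind, sum(n_som), sum(n_som_ind), n_art))

  tract_mask <- rep(FALSE, L)
  tr <- tracts[tracts$chrom == ch, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    tract_mask[(tr$start[i] + 1L):tr$end[i]] <- TRUE
  }

  out <- list()

  ## --- varietal loci (shared by all clones; outgroup independent) ---
  varietal_block <- function(pos, vtype) {
    ## IBD-like tracts are regions of depressed population polymorphism
    ## (such low-variability regions recur across accessions and even
    ## species), so tract *loci* are thinned for every sample rather than
    ## forcing only the variety back to hom-ref — which would manufacture
    ## opposite homozygotes against the outgroup and bias kinship downward.
    keep <- config$ibd_rate / config$varietal_snp_rate
    in_tract <- tract_mask[pos]
    pos <- pos[!in_tract | runif(length(pos)) < keep]
    n <- length(pos)
    if (n == 0) return(NULL)
    p <- runif(n, config$freq_range[[1]], config$freq_range[[2]])
    g_var <- hwe_draw(p)
    g_out <- if (config$outgroup) hwe_draw(p) else rep(0L, n)
    retain <- g_var > 0L | g_out > 0L
    tibble(
      chrom = ch, pos = pos[retain], vtype = vtype,
      g_var = g_var[retain], g_out = g_out[retain]
    )
  }

  snp_loci <- varietal_block(pos_all[seq_len(n_snp)], "SNP")
  ind_loci <- varietal_block(pos_all[seq2(idx[1] + 1L, idx[2])], "INDEL")

  build_rows <- function(loci) {
    if (is.null(loci) || nrow(loci) == 0) return(NULL)
    g <- matrix(rep(loci$g_var, length(clones)), ncol = length(clones))
    colnames(g) <- clones
    rows <- bind_cols(
      loci[c("chrom", "pos", "vtype")],
      as_tibble(g)
    )
    if (config$outgroup) rows$outgroup <- loci$g_out
    rows
  }
  out$varietal <- bind_rows(build_rows(snp_loci), build_rows(ind_loci))
  ## truth "varietal" = sites where the variety itself is non-reference;
  ## outgroup-only records sit in the VCF but are not varietal variation
  loci_all <- bind_rows(snp_loci, ind_loci)
  out$truth_varietal <- loci_all[loci_all$g_var > 0L,
                                 c("chrom", "pos", "vtype"), drop = FALSE]

  ## --- somatic clone-specific sites (het in exactly one clone) ---
  ## A fraction of each clone's somatic SNPs is concentrated into narrow
  ## clone-specific hotspot windows; the rest scatter uniformly.
  som_pool <- pos_all[seq2(idx[2] + 1L, idx[3])]
  som_ind_pos <- pos_all[seq2(idx[3] + 1L, idx[4])]
  placed <- place_somatic(som_pool, n_som, config, L, occupied = pos_all)
  somatic_rows <- function(pos, clone_of, vtype) {
    if (length(pos) == 0) return(NULL)
    g <- matrix(0L, nrow = length(pos), ncol = length(clones),
                dimnames = list(NULL, clones))
    g[cbind(seq_along(pos), match(clone_of, clones))] <- 1L
    rows <- bind_cols(
      tibble(chrom = ch, pos = as.integer(pos), vtype = vtype,
             clone = clone_of),
      as_tibble(g)
    )
    if (config$outgroup) rows$outgroup <- 0L
    rows
  }
  som <- bind_rows(
    somatic_rows(unlist(placed, use.names = FALSE),
                 rep(names(placed), lengths(placed)), "SNP"),
    somatic_rows(som_ind_pos, rep(names(n_som_ind), n_som_ind), "INDEL")
  )
  out$somatic_rows <- som

  ## --- low-QD artifact sites: random het noise across samples ---
  art_pos <- pos_all[seq2(idx[4] + 1L, idx[5])]
  if (length(art_pos) > 0) {
    n_samp <- length(clones) + config$outgroup
    g <- matrix(rbinom(length(art_pos) * n_samp, 1L, 0.3), ncol = n_samp)
    none <- rowSums(g) == 0L
    g[cbind(which(none), sample.int(n_samp, sum(none), replace = TRUE))] <- 1L
    colnames(g) <- c(clones, if (config$outgroup) "outgroup")
    art <- bind_cols(
      tibble(chrom = ch, pos = art_pos, vtype = "SNP"),
      as_tibble(g)
    )
  } else {
    art <- NULL
  }

  ## assemble the per-chromosome variant table with alleles
  if (!is.null(som) && nrow(som) == 0) som <- NULL
  tbl <- bind_rows(
    mutate(out$varietal, source = "varietal"),
    if (!is.null(som)) mutate(select(som, -"clone"), source = "somatic"),
    if (!is.null(art)) mutate(art, source = "artifact")
  )
  tbl <- draw_alleles(tbl, ref, config)

  gt <- tbl[c(clones, if (config$outgroup) "outgroup")]
  names(gt) <- paste0("gt_", names(gt))
  variants <- bind_cols(
    tbl[c("chrom", "pos", "ref", "alt", "vtype", "source")],
    gt
  )

  list(
    variants = variants,
    varietal = out$truth_varietal,
    somatic = if (is.null(som)) {
      tibble(clone = character(), chrom = character(),
             pos = integer(), vtype = character())
    } else {
      mutate(som[c("clone", "chrom", "pos", "vtype")], mechanism = "het_gain")
    },
    artifacts = if (is.null(art)) {
      tibble(chrom = character(), pos = integer())
    } else {
      art[c("chrom", "pos")]
    }
  )
}

## seq() that returns integer(0) when from > to (base seq errors there)
seq2 <- function(from, to) {
  if (from > to) integer(0) else seq.int(from, to)
}

## Per-clone somatic SNP positions: a hotspot fraction packed into
## grid-aligned windows (re-drawn when a window cannot host all of its
## mutations without position collisions), the rest uniform from the
## pre-reserved collision-free pool.
place_somatic <- function(pool, counts, config, L, occupied) {
  hw <- config$hotspot_width
  n_win <- floor(L / hw)
  res <- list()
  pool_i <- 0L
  for (cl in names(counts)) {
    n <- counts[[cl]]
    if (n == 0) {
      res[[cl]] <- integer(0)
      next
    }
    n_hot <- round(config$somatic_hotspot_fraction * n)
    n_unif <- n - n_hot
    pos_u <- pool[seq2(pool_i + 1L, pool_i + n_unif)]
    pool_i <- pool_i + n
    pos_h <- integer(0)
    if (n_hot > 0) {
      k_h <- max(1L, round(n_hot / 8))
      alloc <- tabulate(sample.int(k_h, n_hot, replace = TRUE), k_h)
      for (m in alloc[alloc > 0]) {
        repeat {
          w <- sample.int(n_win - 2L, 1L) * hw
          cand <- w + seq_len(hw)
          avail <- setdiff(cand, c(occupied, pos_h, pos_u))
          if (length(avail) >= m) break
        }
        pos_h <- c(pos_h, avail[sample.int(length(avail), m)])
      }
    }
    occupied <- c(occupied, pos_h)
    res[[cl]] <- as.integer(c(pos_u, pos_h))
  }
  res
}

draw_alleles <- function(tbl, ref, config) {
  n <- nrow(tbl)
  tbl$ref <- ref[tbl$pos]
  tbl$alt <- other_base(tbl$ref)
  is_ind <- tbl$vtype == "INDEL"
  n_ind <- sum(is_ind)
  if (n_ind > 0) {
    long <- runif(n_ind) < 0.02
    len <- ifelse(
      long,
      sample.int(config$indel_max_len - 50L, n_ind, replace = TRUE) + 50L,
      pmin(rgeom(n_ind, 0.5) + 1L, config$indel_max_len)
    )
    is_del <- runif(n_ind) < 0.5
    pos_i <- tbl$pos[is_ind]
    refs <- character(n_ind)
    alts <- character(n_ind)
    for (i in seq_len(n_ind)) {
      if (is_del[i]) {
        refs[i] <- paste0(ref[pos_i[i]:(pos_i[i] + len[i])], collapse = "")
        alts[i] <- ref[pos_i[i]]
      } else {
        refs[i] <- ref[pos_i[i]]
        alts[i] <- paste0(
          c(ref[pos_i[i]], sample(DNA_BASES, len[i], replace = TRUE)),
          collapse = ""
        )
      }
    }
    tbl$ref[is_ind] <- refs
    tbl$alt[is_ind] <- alts
  }
  tbl
}

other_base <- function(b) {
  alt <- sample(DNA_BASES, length(b), replace = TRUE)
  clash <- alt == b
  while (any(clash)) {
    alt[clash] <- sample(DNA_BASES, sum(clash), replace = TRUE)
    clash <- alt == b
  }
  alt
}

## site QD (constant 25 for true sites, < 20 for artifacts) and per-genotype
## depths (Poisson around the panel's mean filtered depth of 16x)
add_site_annotations <- function(variants, samples, config) {
  n <- nrow(variants)
  variants$qd <- ifelse(variants$source == "artifact",
                        round(runif(n, 5, 19.5), 2), 25)
  for (s in samples) {
    variants[[paste0("dp_", s)]] <- rpois(n, 16)
  }
  select(
    variants, "chrom", "pos", "ref", "alt", "vtype", "qd",
    starts_with("gt_"), starts_with("dp_")
  )
}

draw_coverage <- function(lens, samples, config) {
  grid <- expand_grid(sample = samples, chrom = names(lens))
  dropouts <- pmap(grid, function(sample, chrom) {
    L <- lens[[chrom]]
    k <- rpois(1, config$dropout_mean)
    if (k == 0) {
      return(tibble(sample = character(), chrom = character(),
                    start = integer(), end = integer()))
    }
    len <- round(runif(k, config$dropout_len[[1]], config$dropout_len[[2]]))
    start <- vapply(len, function(l) sample.int(L - l, 1L) - 1L, numeric(1))
    ir <- IRanges::reduce(IRanges::IRanges(start + 1, start + len))
    tibble(
      sample = sample, chrom = chrom,
      start = as.integer(IRanges::start(ir) - 1L),
      end = as.integer(IRanges::end(ir))
    )
  })
  dropouts <- bind_rows(dropouts)
  masks <- map_dfr(samples, function(s) {
    map_dfr(names(lens), function(ch) {
      d <- filter(dropouts, .data$sample == s, .data$chrom == ch)
      complement_intervals(d, lens[[ch]], ch, s)
    })
  })
  list(dropouts = dropouts, masks = masks)
}

complement_intervals <- function(d, L, chrom, sample) {
  if (nrow(d) == 0) {
    return(tibble(sample = sample, chrom = chrom, start = 0L, end = as.integer(L)))
  }
  ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = L)
  tibble(
    sample = sample, chrom = chrom,
    start = as.integer(IRanges::start(gaps) - 1L),
    end = as.integer(IRanges::end(gaps))
  )
}

apply_missingness <- function(variants, samples, dropouts, missing_rate) {
  n <- nrow(variants)
  for (s in samples) {
    col <- paste0("gt_", s)
    miss <- runif(n) < missing_rate
    d <- dropouts[dropouts$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      miss <- miss | (variants$chrom == d$chrom[i] &
                        variants$pos > d$start[i] &
                        variants$pos <= d$end[i])
    }
    variants[[col]][miss] <- NA_integer_
  }
  variants
}

convert_to_loh <- function(variants, somatic, clones, loh_fraction) {
  to_flip <- somatic$vtype == "SNP" & runif(nrow(somatic)) < loh_fraction
  used <- integer(0)
  for (i in which(to_flip)) {
    ## only sites still heterozygous in every clone are eligible, and a site
    ## hosts at most one LOH event
    cand <- setdiff(
      which(variants$source == "varietal" &
              variants[[paste0("gt_", somatic$clone[i])]] == 1L),
      used
    )
    if (length(cand) == 0) next
    j <- cand[sample.int(length(cand), 1)]
    used <- c(used, j)
    variants[[paste0("gt_", somatic$clone[i])]][j] <- 2L
    ## drop the corresponding het-gain row and re-point truth at the LOH site
    drop <- which(variants$chrom == somatic$chrom[i] &
                    variants$pos == somatic$pos[i])
    if (length(drop) == 1) variants <- variants[-drop, , drop = FALSE]
    somatic$chrom[i] <- variants$chrom[j]
    somatic$pos[i] <- variants$pos[j]
    somatic$mechanism[i] <- "loh"
  }
  list(variants = variants, somatic = somatic)
}

## ---- transposable elements -------------------------------------------------

TE_CLASSES <- c(LTR = 0.54, TIR = 0.25, MITE = 0.15, SINE = 0.06)

simulate_te <- function(lens, clones, config) {
  spacing <- 15000L
  slots <- map_dfr(names(lens), function(ch) {
    centers <- seq(spacing %/% 2, lens[[ch]] - spacing %/% 2, by = spacing)
    tibble(chrom = ch, center = as.integer(centers))
  })
  counts <- config$te_counts_by_sharing
  n_events <- sum(counts)
  if (n_events > nrow(slots)) {
    abort("genome too small for the requested number of TE events")
  }
  events_all <- list()
  table_all <- list()
  for (m in config$te_methods) {
    pick <- slots[sample.int(nrow(slots), n_events), , drop = FALSE]
    k <- rep(as.integer(names(counts)), counts)
    te_class <- sample(names(TE_CLASSES), n_events, replace = TRUE, prob = TE_CLASSES)
    family <- paste0(te_class, "_fam", sample.int(3, n_events, replace = TRUE))
    ev <- mutate(pick,
                 event_id = paste0(m, "_ev", seq_len(n_events)),
                 method = m, k = k, te_class = te_class, family = family)
    members <- map_dfr(seq_len(n_events), function(i) {
      who <- sample(clones, ev$k[i])
      tibble(
        method = m,
        chrom = ev$chrom[i],
        pos = ev$center[i] +
          as.integer(round(runif(ev$k[i], -config$te_jitter, config$te_jitter))),
        family = ev$family[i],
        te_class = ev$te_class[i],
        clone = who,
        event_id = ev$event_id[i]
      )
    })
    events_all[[m]] <- ev
    table_all[[m]] <- members
  }
  list(
    events = bind_rows(events_all)[
      c("event_id", "method", "chrom", "center", "family", "te_class", "k")
    ],
    table = select(bind_rows(table_all), -"event_id") |>
      arrange(.data$method, .data$chrom, .data$pos)
  )
}

## ---- toy gene models -------------------------------------------------------

## Non-overlapping toy genes: 1-3 CDS exons, total CDS length a multiple of 3.
## The reference is later patched so each gene starts with ATG, ends with TAA
## and has no internal in-frame stop codon.
place_gene_models <- function(lens, n_genes) {
  occupied <- lapply(lens, function(...) IRanges::IRanges())
  rows <- list()
  gi <- 0
  attempts <- 0
  while (gi < n_genes && attempts < n_genes * 50) {
    attempts <- attempts + 1
    ch <- sample(names(lens), 1, prob = lens)
    n_ex <- sample.int(3, 1)
    cds_len <- 3L * sample(100:400, 1)
    ex <- rep(cds_len %/% n_ex, n_ex)
    ex[n_ex] <- ex[n_ex] + cds_len - sum(ex)
    introns <- if (n_ex > 1) sample(60:200, n_ex - 1, replace = TRUE) else integer(0)
    span <- sum(ex) + sum(introns)
    if (lens[[ch]] <= span + 400) next
    s0 <- sample.int(lens[[ch]] - span - 200L, 1) + 100L
    cand <- IRanges::IRanges(s0 + 1L, s0 + span)
    if (length(IRanges::findOverlaps(
      cand, occupied[[ch]], maxgap = 100L
    )) > 0) next
    occupied[[ch]] <- c(occupied[[ch]], cand)
    gi <- gi + 1
    strand <- sample(c("+", "-"), 1)
    starts <- s0 + cumsum(c(0L, head(ex, -1) + introns))
    seg <- tibble(
      gene_id = sprintf("gene%03d", gi),
      chrom = ch, strand = strand,
      start = as.integer(starts),
      end = as.integer(starts + ex),
      exon_rank = seq_len(n_ex)
    )
    ## GFF phase: bases to skip to reach the next codon start, per segment in
    ## coding order
    widths <- ex
    if (strand == "-") widths <- rev(widths)
    phase_coding <- (3L - cumsum(c(0L, head(widths, -1))) %% 3L) %% 3L
    seg$phase <- if (strand == "-") rev(phase_coding) else phase_coding
    rows[[gi]] <- seg
  }
  bind_rows(rows)
}

## genomic 0-based positions of a gene's CDS in coding (5'->3') order
coding_positions <- function(seg) {
  pos <- unlist(Map(function(s, e) s:(e - 1L), seg$start, seg$end))
  if (seg$strand[[1]] == "-") rev(pos) else pos
}

patch_reference_for_genes <- function(ref_chars, genes) {
  if (nrow(genes) == 0) return(ref_chars)
  write_coding_base <- function(ref, cp, strand, i, base) {
    ref[cp[i] + 1L] <- if (strand == "+") base else DNA_COMP[[base]]
    ref
  }
  for (gid in unique(genes$gene_id)) {
    seg <- genes[genes$gene_id == gid, , drop = FALSE]
    ch <- seg$chrom[[1]]
    strand <- seg$strand[[1]]
    cp <- coding_positions(seg)
    ref <- ref_chars[[ch]]
    for (i in 1:3) ref <- write_coding_base(ref, cp, strand, i, c("A", "T", "G")[i])
    n <- length(cp)
    for (i in 1:3) {
      ref <- write_coding_base(ref, cp, strand, n - 3L + i, c("T", "A", "A")[i])
    }
    ## remove internal in-frame stops
    get_base <- function(i) {
      b <- ref[cp[i] + 1L]
      if (strand == "+") b else DNA_COMP[[b]]
    }
    n_codon <- n %/% 3L
    for (ci in seq2(2L, n_codon - 1L)) {
      codon <- paste0(get_base(3L * (ci - 1L) + 1L),
                      get_base(3L * (ci - 1L) + 2L),
                      get_base(3L * ci), collapse = "")
      if (codon %in% STOP_CODONS) {
        ref <- write_coding_base(ref, cp, strand, 3L * (ci - 1L) + 1L, "C")
      }
    }
    ref_chars[[ch]] <- ref
  }
  ref_chars
}
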