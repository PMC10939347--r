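# Builders and independent oracles shared across the test files.

library(dplyr, warn.conflicts = FALSE)
library(tibble)

# Tiny variant-table builder. `gt` is a sites x samples matrix (or vector for
# one sample) of dosages; depths default to a healthy constant.
make_variants <- function(chrom, pos, ref = "A", alt = "T", qd = 25,
                          gt = NULL, samples = NULL, dp = 20L) {
  n <- length(pos)
  if (is.null(gt)) gt <- matrix(1L, n, 2)
  if (is.vector(gt)) gt <- matrix(gt, ncol = 1)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(gt)))
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  vtype <- dplyr::case_when(
    grepl(",", alt) ~ NA_character_,
    nchar(ref) == 1 & nchar(alt) == 1 ~ "SNP",
    nchar(ref) != nchar(alt) ~ "INDEL",
    TRUE ~ NA_character_
  )
  x <- tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = ref, alt = alt, vtype = vtype, qd = rep_len(qd, n)
  )
  for (j in seq_len(ncol(gt))) {
    x[[paste0("gt_", samples[j])]] <- as.integer(gt[, j])
  }
  for (j in seq_len(ncol(gt))) {
    x[[paste0("dp_", samples[j])]] <- rep_len(as.integer(dp), n)
  }
  x
}

# random dosage matrix with optional missingness
random_gt <- function(n_sites, n_samples, p_missing = 0) {
  g <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
              n_sites, n_samples)
  if (p_missing > 0) {
    g[matrix(runif(length(g)) < p_missing, nrow(g))] <- NA_integer_
  }
  g
}

# ---- brute-force oracles -----------------------------------------------------

# O(n^2): SNPs to drop because an INDEL lies within +/- window bp (inclusive)
oracle_snp_near_indel_drop <- function(x, window = 15) {
  drop <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$vtype[i]) || x$vtype[i] != "SNP") next
    for (j in seq_len(nrow(x))) {
      if (is.na(x$vtype[j]) || x$vtype[j] != "INDEL") next
      if (x$chrom[i] == x$chrom[j] && abs(x$pos[i] - x$pos[j]) <= window) {
        drop[i] <- TRUE
      }
    }
  }
  drop
}

# O(n^2): INDELs to drop because another INDEL is closer than min_gap
oracle_indel_spacing_drop <- function(x, min_gap = 50) {
  drop <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$vtype[i]) || x$vtype[i] != "INDEL") next
    for (j in seq_len(nrow(x))) {
      if (i == j || is.na(x$vtype[j]) || x$vtype[j] != "INDEL") next
      if (x$chrom[i] == x$chrom[j] && abs(x$pos[i] - x$pos[j]) < min_gap) {
        drop[i] <- TRUE
      }
    }
  }
  drop
}

# mean pairwise Hamming distance over all haplotype pairs at one site:
# haplotype vector of 0/1 alleles
oracle_site_pi <- function(haps) {
  n <- length(haps)
  mism <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) mism <- mism + (haps[i] != haps[j])
  }
  mism / choose(n, 2)
}

# transitive closure of the pairwise "< radius apart, same chrom+family"
# relation; returns a cluster id per insertion (within one method)
oracle_te_clusters <- function(te, radius = 10000) {
  n <- nrow(te)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- te$chrom[i] == te$chrom[j] &
        te$family[i] == te$family[j] &
        abs(te$pos[i] - te$pos[j]) < radius
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# ---- whole-CDS re-translation oracle for effect calls ------------------------

translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3
  vapply(seq_len(n), function(i) {
    aa <- Biostrings::GENETIC_CODE[substr(cds, 3 * i - 2, 3 * i)]
    ifelse(is.na(aa), "X", aa)
  }, character(1))
}

extract_cds <- function(chars, seg) {
  pieces <- vapply(seq_len(nrow(seg)), function(i) {
    paste0(chars[(seg$start[i] + 1):seg$end[i]], collapse = "")
  }, character(1))
  cds <- paste0(pieces, collapse = "")
  if (seg$strand[[1]] == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  cds
}

# Re-translate the whole mutated CDS and diff the protein products.
# Planting domain: SNPs anywhere in the CDS; INDELs fully inside one CDS
# segment, not touching the first or last codon. In-frame INDELs map to
# "none" (the package's simplified category set never calls them HIGH).
oracle_effect <- function(chrom_chars, seg, pos, ref, alt) {
  p0 <- pos - 1L
  delta <- nchar(alt) - nchar(ref)
  mut <- chrom_chars
  seg_m <- seg
  if (delta == 0) {
    mut[pos] <- alt
  } else if (delta < 0) {
    del0 <- (p0 + 1):(p0 - delta)          # 0-based deleted positions
    mut <- mut[-(del0 + 1)]
    for (i in seq_len(nrow(seg_m))) {
      s <- seg$start[i]; e <- seg$end[i]
      seg_m$start[i] <- s - sum(del0 < s)
      seg_m$end[i] <- e - sum(del0 < s) - sum(del0 >= s & del0 < e)
    }
  } else {
    ins <- strsplit(substr(alt, 2, nchar(alt)), "")[[1]]
    mut <- append(mut, ins, after = pos)
    for (i in seq_len(nrow(seg_m))) {
      if (seg$start[i] >= pos) seg_m$start[i] <- seg$start[i] + delta
      if (seg$end[i] > p0 + 1) seg_m$end[i] <- seg$end[i] + delta
    }
  }
  cds_ref <- extract_cds(chrom_chars, seg)
  cds_mut <- extract_cds(mut, seg_m)
  if (nchar(cds_mut) %% 3 != 0) return("frameshift_variant")
  if (delta != 0) return("none")
  prot_ref <- translate_cds(cds_ref)
  prot_mut <- translate_cds(cds_mut)
  if (prot_ref[1] == "M" && substr(cds_ref, 1, 3) == "ATG" &&
      substr(cds_mut, 1, 3) != "ATG") {
    return("start_lost")
  }
  stop_ref <- match("*", prot_ref)
  stop_mut <- match("*", prot_mut)
  if (!is.na(stop_mut) && (is.na(stop_ref) || stop_mut < stop_ref)) {
    return("stop_gained")
  }
  if (!is.na(stop_ref) && (is.na(stop_mut) || stop_mut > stop_ref)) {
    return("stop_lost")
  }
  "none"
}

# reference with one two-exon gene: exon1 [100,130), intron, exon2 [190,250);
# CDS length 90 (30 codons), patched to start ATG / end TAA, no internal stops
build_toy_gene <- function(strand = "+", seed = 404) {
  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
    genes <- tibble::tibble(
      gene_id = "g1", chrom = "cA", strand = strand,
      start = c(100L, 190L), end = c(130L, 250L), exon_rank = 1:2,
      phase = c(0L, 0L)  # both exon widths are multiples of 3
    )
    ref_chars <- clonescan:::patch_reference_for_genes(list(cA = chars), genes)
    list(
      genes = genes,
      chars = ref_chars$cA,
      reference = Biostrings::DNAStringSet(
        c(cA = paste0(ref_chars$cA, collapse = ""))
      )
    )
  })
}

classify1 <- function(toy, pos, ref, alt) {
  x <- make_variants("cA", pos = pos, ref = ref, alt = alt,
                     gt = matrix(1L, length(pos), 1))
  classify_variant_effects(x, toy$genes, toy$reference)
}

# small simulated panel reused by several test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(sim_config(
        seed = 11,
        chrom_lengths = c(chrA = 5e5, chrB = 4e5),
        n_genes = 15,
        te_counts_by_sharing = stats::setNames(c(12, 6, 3, 2, 2, 2, 2, 1), 1:8)
      ))
    }
    cache
  }
})
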