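## Relatedness within the clone panel: the KING-robust within-pair kinship
## estimator (chosen over the homogeneous-population estimator because the
## panel mixes near-identical clones with an unrelated accession), a dosage
## PCA, and a Mendelian gene-dropping simulator for analytic IBD anchors.

#' KING-robust pairwise kinship
#'
#' For two diploid genotype dosage vectors over the same sites,
#' `phi = (N_hethet - 2 N_opp) / (N_het_i + N_het_j)` where `N_hethet` is the
#' number of sites heterozygous in both, `N_opp` the number of sites with
#' opposite homozygotes, and `N_het_x` the heterozygous-site count of each
#' sample. Sites missing in either sample are dropped. An identical pair with
#' at least one het site gives exactly 0.5 ("selfing"); unrelated
#' Hardy-Weinberg samples give 0 in expectation.
#'
#' @param gi,gj Integer dosage vectors (`0`, `1`, `2`, `NA`).
#' @return The kinship estimate, or `NA` (with a warning) when neither
#'   sample has a het site among the shared non-missing sites.
#' @export
king_kinship <- function(gi, gj) {
  stopifnot(length(gi) == length(gj))
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]
  gj <- gj[ok]
  n_hethet <- sum(gi == 1L & gj == 1L)
  n_opp <- sum(abs(gi - gj) == 2L)
  denom <- sum(gi == 1L) + sum(gj == 1L)
  if (denom == 0) {
    warn("no heterozygous sites in either sample; kinship undefined")
    return(NA_real_)
  }
  (n_hethet - 2 * n_opp) / denom
}

#' Pairwise kinship matrix for a variant table
#'
#' @param x Variant table.
#' @param samples Samples to include.
#' @return A symmetric `kinship_matrix` object; the diagonal is self-kinship
#'   (0.5 whenever the sample has any het site).
#' @export
kinship_matrix <- function(x, samples = variant_samples(x)) {
  gm <- gt_matrix(x, samples)
  n <- length(samples)
  phi <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n)) {
    for (j in i:n) {
      phi[i, j] <- phi[j, i] <- king_kinship(gm[, i], gm[, j])
    }
  }
  structure(phi, class = c("kinship_matrix", "matrix", "array"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix>", nrow(x), "samples\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Tidy a kinship matrix into pair rows
#'
#' @param x A [kinship_matrix()].
#' @param ... Unused.
#' @return Tibble `sample_i`, `sample_j`, `kinship` (upper triangle incl.
#'   diagonal).
#' @export
tidy.kinship_matrix <- function(x, ...) {
  samples <- rownames(x)
  idx <- which(upper.tri(x, diag = TRUE), arr.ind = TRUE)
  tibble(
    sample_i = samples[idx[, 1]],
    sample_j = samples[idx[, 2]],
    kinship = x[idx]
  )
}

#' Genotype PCA of the clone panel
#'
#' Principal components of the samples-by-sites dosage matrix restricted to
#' complete-case polymorphic sites. Columns are mean-centered; optional
#' `1/sqrt(2 p (1 - p))` scaling is exposed but off by default (plain
#' covariance PCA of dosages).
#'
#' @param x Variant table.
#' @param samples Samples to include.
#' @param k Number of components returned.
#' @param scale Apply allele-frequency scaling?
#' @return A `clone_pca` object: list with `scores` (tibble of sample
#'   coordinates), `var_explained` (fractions per returned component, from
#'   the full spectrum), `sdev`, `n_sites`.
#' @export
genotype_pca <- function(x, samples = variant_samples(x), k = 2,
                         scale = FALSE) {
  sites <- polymorphic_sites(x, samples = samples, require_complete = TRUE)
  gm <- t(gt_matrix(sites, samples))
  if (ncol(gm) == 0) {
    warn("no polymorphic sites; all coordinates are zero")
    k <- min(k, length(samples))
    scores <- as_tibble(matrix(0, length(samples), k,
                               dimnames = list(NULL, paste0("PC", seq_len(k)))))
    return(structure(
      list(scores = bind_cols(tibble(sample = samples), scores),
           var_explained = rep(NA_real_, k), sdev = numeric(0), n_sites = 0L),
      class = "clone_pca"
    ))
  }
  if (ncol(gm) < length(samples)) {
    warn("fewer polymorphic sites than samples; components are degenerate")
  }
  centered <- scale(gm, center = TRUE, scale = FALSE)
  if (scale) {
    p <- colMeans(gm) / 2
    w <- sqrt(2 * p * (1 - p))
    w[w == 0] <- 1
    centered <- sweep(centered, 2, w, "/")
  }
  pc <- prcomp(centered, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- bind_cols(tibble(sample = samples), scores)
  structure(
    list(scores = scores, var_explained = frac[seq_len(k)],
         sdev = pc$sdev, n_sites = ncol(gm)),
    class = "clone_pca"
  )
}

#' @export
print.clone_pca <- function(x, ...) {
  cat("<clone_pca>", nrow(x$scores), "samples,", x$n_sites, "sites\n")
  cat("  variance explained:",
      paste0(sprintf("PC%d %.2f%%", seq_along(x$var_explained),
                     100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.clone_pca <- function(x, ...) x$scores

#' @export
glance.clone_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_sites = x$n_sites,
    var_pc1 = x$var_explained[1],
    var_pc2 = if (length(x$var_explained) >= 2) x$var_explained[2] else NA_real_
  )
}

#' Mendelian gene-dropping IBD sharing
#'
#' Drops uniquely labelled founder alleles through a small fixed pedigree at
#' independent loci and reports the mean identical-by-descent allele-sharing
#' fraction between the two focal relatives (a locus where the pair shares
#' one allele IBD scores 1/2, both alleles 1). Expected values: 25% for
#' half-siblings (three founders, one shared parent), 50% for full siblings
#' and parent-offspring.
#'
#' @details The classical "fraction of the genome shared" equals twice the
#' kinship coefficient: 50% for parent-offspring and full siblings, 25% for
#' half-siblings. The estimator here is that allele-level sharing fraction,
#' so half-siblings give 25% and parent-offspring 50%.
#'
#' @param n_loci Number of independent loci.
#' @param relationship `"half_sibs"`, `"full_sibs"` or `"parent_offspring"`.
#' @return List: `percent` (mean sharing as a percentage), `per_locus`
#'   sharing scores, `n_loci`.
#' @export
ibd_gene_drop <- function(n_loci = 1e5,
                          relationship = c("half_sibs", "full_sibs",
                                           "parent_offspring")) {
  relationship <- match.arg(relationship)
  pick <- function(a1, a2) ifelse(runif(n_loci) < 0.5, a1, a2)
  ## founder alleles carry unique integer labels per locus
  founder <- function(i) list(2L * i - 1L, 2L * i)
  f1 <- founder(1)
  f2 <- founder(2)
  f3 <- founder(3)
  child <- function(p, q) list(pick(p[[1]], p[[2]]), pick(q[[1]], q[[2]]))
  pair <- switch(relationship,
    half_sibs = list(child(f1, f2), child(f1, f3)),
    full_sibs = list(child(f1, f2), child(f1, f2)),
    parent_offspring = {
      off <- child(f1, f2)
      list(f1, off)
    }
  )
  a <- pair[[1]]
  b <- pair[[2]]
  ## IBD allele-sharing score per locus: matched pairs / 2
  share <- (pmax((a[[1]] == b[[1]]) + (a[[2]] == b[[2]]),
                 (a[[1]] == b[[2]]) + (a[[2]] == b[[1]]))) / 2
  ## parent vs offspring share exactly one allele by construction; the
  ## max-matching above already handles which one
  list(
    percent = 100 * mean(share),
    per_locus = share,
    n_loci = n_loci
  )
}
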