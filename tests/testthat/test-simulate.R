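test_that("config invariants are enforced", {
  expect_error(sim_config(ibd_fraction = 1.5), "ibd_fraction")
  expect_error(sim_config(varietal_snp_rate = -1), "rates")
  expect_error(sim_config(ibd_rate = 10), "ibd_rate")
  expect_error(sim_config(n_clones = 1), "two clones")
  expect_error(sim_config(somatic_rates = c(1, 2)), "one entry per clone")
})

test_that("identical seed and config give byte-identical artifacts", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(cA = 2e5), n_genes = 4,
                    te_counts_by_sharing = setNames(c(4, 2, 1, 1, 1, 1, 1, 1), 1:8))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim(simulate_population(cfg), d1)
  write_sim(simulate_population(cfg), d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      label = f
    )
  }
  ## and a different seed changes the data
  cfg2 <- sim_config(seed = 6, chrom_lengths = c(cA = 2e5), n_genes = 4,
                     te_counts_by_sharing = setNames(c(4, 2, 1, 1, 1, 1, 1, 1), 1:8))
  expect_false(identical(simulate_population(cfg2)$variants,
                         simulate_population(cfg)$variants))
})

test_that("the simulated genotype structure matches the model", {
  sim <- small_sim()
  x <- sim$variants
  expect_false(any(duplicated(paste(x$chrom, x$pos))))
  gm <- gt_matrix(x, sim$clones)
  ## varietal truth sites: identical genotypes in all clones (ignoring
  ## missing); somatic: het in its clone, hom-ref in the others
  key <- paste(x$chrom, x$pos)
  vkey <- paste(sim$truth$varietal$chrom, sim$truth$varietal$pos)
  v_rows <- which(key %in% vkey)
  n_gt <- apply(gm[v_rows, ], 1, function(g) length(unique(g[!is.na(g)])))
  expect_true(all(n_gt <= 1 | is.na(n_gt)))
  som <- sim$truth$somatic
  srow <- match(paste(som$chrom, som$pos), key)
  expect_false(anyNA(srow))
  for (i in sample(seq_len(nrow(som)), 50)) {
    g <- gm[srow[i], ]
    own <- g[som$clone[i]]
    expect_true(is.na(own) || own == 1L)   # het unless masked as missing
    others <- g[setdiff(sim$clones, som$clone[i])]
    expect_true(all(others[!is.na(others)] == 0L))
  }
  ## somatic truth: each variant belongs to exactly one clone
  expect_false(any(duplicated(paste(som$chrom, som$pos))))
})

test_that("realized rates are Poisson-consistent with the configuration", {
  sim <- small_sim()
  cfg <- sim$config
  genome <- sum(cfg$chrom_lengths)
  tract_bp <- sum(sim$truth$ibd_tracts$end - sim$truth$ibd_tracts$start)
  ## varietal SNPs: rate outside tracts, thinned rate inside
  lambda <- cfg$varietal_snp_rate / 1000 * (genome - tract_bp) +
    cfg$ibd_rate / 1000 * tract_bp
  n_var <- sum(sim$truth$varietal$vtype == "SNP")
  expect_lt(abs(n_var - lambda), 4 * sqrt(lambda))
  ## per-clone somatic counts within Poisson error of rate x genome
  for (cl in sim$clones) {
    lam <- cfg$somatic_rates[[cl]] * genome / 1e6
    n <- sum(sim$truth$somatic$clone == cl & sim$truth$somatic$vtype == "SNP")
    expect_lt(abs(n - lam), 4 * sqrt(lam) + 1)
  }
  ## IBD tracts: realized variety SNP rate inside tracts below ibd_rate band
  in_tract <- 0
  for (j in seq_len(nrow(sim$truth$ibd_tracts))) {
    tr <- sim$truth$ibd_tracts[j, ]
    in_tract <- in_tract + sum(
      sim$truth$varietal$chrom == tr$chrom &
        sim$truth$varietal$pos > tr$start & sim$truth$varietal$pos <= tr$end &
        sim$truth$varietal$vtype == "SNP"
    )
  }
  lam_tract <- cfg$ibd_rate / 1000 * tract_bp
  expect_lt(in_tract, lam_tract + 4 * sqrt(lam_tract) + 1)
})

test_that("zero somatic rates give zero polymorphic sites among clones", {
  cfg <- sim_config(seed = 2, chrom_lengths = c(cA = 2e5),
                    somatic_rates = rep(0, 8), low_qd_fraction = 0,
                    missing_rate = 0, dropout_mean = 0, n_genes = 2,
                    te_counts_by_sharing = setNames(c(2, 1, 1, 1, 1, 1, 1, 1), 1:8))
  sim <- simulate_population(cfg)
  poly <- polymorphic_sites(sim$variants, samples = sim$clones)
  expect_equal(nrow(poly), 0)
  expect_equal(nrow(sim$truth$somatic), 0)
})

test_that("loss-of-heterozygosity option plants 0/1 -> 1/1 divergence", {
  cfg <- sim_config(seed = 12, chrom_lengths = c(cA = 2e5),
                    loh_fraction = 1, low_qd_fraction = 0,
                    missing_rate = 0, dropout_mean = 0, n_genes = 2,
                    te_counts_by_sharing = setNames(c(2, 1, 1, 1, 1, 1, 1, 1), 1:8))
  sim <- simulate_population(cfg)
  loh <- sim$truth$somatic[sim$truth$somatic$mechanism == "loh", ]
  expect_gt(nrow(loh), 0)
  gm <- gt_matrix(sim$variants, sim$clones)
  key <- paste(sim$variants$chrom, sim$variants$pos)
  for (i in head(seq_len(nrow(loh)), 20)) {
    g <- gm[match(paste(loh$chrom[i], loh$pos[i]), key), ]
    expect_equal(unname(g[loh$clone[i]]), 2L)
    expect_true(all(g[setdiff(sim$clones, loh$clone[i])] == 1L))
  }
})

test_that("VCF writing follows the conventions and round-trips", {
  x <- make_variants("c1", pos = c(20, 10), gt = matrix(c(1L, 0L, NA, 2L), 2, 2))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(x, p, chrom_lengths = c(c1 = 100))
  lines <- readLines(p)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  expect_match(body[1], "^c1\t10\t")      # sorted before writing
  expect_match(body[1], "0/0:20\t1/1:20$")
  expect_match(body[2], "0/1:20\t")
  expect_match(body[2], "\\./\\.:20$")    # missing genotype convention
  back <- read_vcf(p)
  expect_equal(as.data.frame(back), as.data.frame(dplyr::arrange(x, chrom, pos)))
})

test_that("simulated artifacts round-trip through their on-disk formats", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  v <- read_vcf(file.path(dir, "variants.vcf"))
  expect_equal(as.data.frame(v), as.data.frame(sim$variants))
  g <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_equal(
    as.data.frame(dplyr::arrange(g, gene_id, start)),
    as.data.frame(dplyr::arrange(sim$genes, gene_id, start))
  )
  m <- read_coverage_masks(file.path(dir, "masks"))
  expect_equal(
    as.data.frame(dplyr::arrange(m, sample, chrom, start)),
    as.data.frame(dplyr::arrange(sim$masks, sample, chrom, start))
  )
  te <- read_te_tables(file.path(dir, "te"))
  expect_equal(
    as.data.frame(dplyr::arrange(te[names(sim$te)], method, chrom, pos, clone)),
    as.data.frame(dplyr::arrange(sim$te, method, chrom, pos, clone))
  )
})

test_that("TE tables keep shared events within the merge radius and write headers when empty", {
  sim <- small_sim()
  ev_truth <- sim$truth$te_events
  for (i in sample(seq_len(nrow(ev_truth)), 20)) {
    members <- sim$te[sim$te$method == ev_truth$method[i] &
                        sim$te$chrom == ev_truth$chrom[i] &
                        sim$te$family == ev_truth$family[i] &
                        abs(sim$te$pos - ev_truth$center[i]) <= 2000, ]
    expect_gte(nrow(members), ev_truth$k[i])
    expect_lt(max(members$pos) - min(members$pos), 10000)
  }
  dir <- withr::local_tempdir()
  empty <- sim$te[0, ]
  write_te_tables(empty, dir, methods = "m1")
  tab <- readr::read_tsv(file.path(dir, "te_m1.tsv"), show_col_types = FALSE)
  expect_equal(nrow(tab), 0)
  expect_equal(names(tab), c("chrom", "pos", "family", "te_class", "clone", "method"))
})
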