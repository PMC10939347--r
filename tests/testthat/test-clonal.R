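test_that("polymorphic and clone-unique classification follow the genotype rules", {
  gt <- rbind(
    rep(1L, 8),                      # all het: varietal, not polymorphic
    c(1L, rep(2L, 7)),               # one clone 0/1 vs seven 1/1: unique
    c(1L, 1L, rep(2L, 6)),           # two divergent clones: shared
    c(1L, 0L, rep(2L, 6)),           # two distinct minorities: not unique
    c(NA, rep(1L, 7))                # missing call: excluded (complete-case)
  )
  x <- make_variants("c1", pos = 1:5, gt = gt)
  poly <- polymorphic_sites(x)
  expect_equal(poly$pos, 2:4)
  poly_all <- polymorphic_sites(x, require_complete = FALSE)
  expect_equal(poly_all$pos, 2:4)    # row 5 has a single distinct call
  uniq <- clone_unique_variants(poly)
  expect_equal(uniq$pos, 2L)
  expect_equal(uniq$clone, "s1")
})

test_that("unique and shared partition the polymorphic set on simulated data", {
  sim <- small_sim()
  f <- suppressWarnings(filter_cascade(sim$variants, samples = sim$clones))
  poly <- polymorphic_sites(f, samples = sim$clones)
  uniq <- clone_unique_variants(poly, samples = sim$clones)
  expect_lte(nrow(uniq), nrow(poly))
  expect_false(any(duplicated(paste(uniq$chrom, uniq$pos))))
  ## every clone-unique site recovered is a planted somatic site of that clone
  truth_key <- paste(sim$truth$somatic$clone, sim$truth$somatic$chrom,
                     sim$truth$somatic$pos)
  expect_true(all(paste(uniq$clone, uniq$chrom, uniq$pos) %in% truth_key))
  ## and classification recovers every analyzable somatic site
  analyzable <- semi_join(poly, sim$truth$somatic, by = c("chrom", "pos"))
  expect_equal(nrow(uniq), nrow(analyzable))
})

test_that("sharing spectra are exact and sum to the site count", {
  gt <- rbind(
    rep(1L, 4),
    c(0L, 0L, 0L, 2L),
    c(NA, 1L, 1L, 1L),
    c(NA, NA, 0L, 0L)
  )
  x <- make_variants("c1", pos = 1:4, gt = gt)
  sp <- sharing_spectra(x)
  valid <- dplyr::filter(sp, spectrum == "valid_genotypes")
  expect_equal(sum(valid$n_sites), 4)
  expect_equal(valid$n_sites[valid$k == 4], 2L)
  expect_equal(valid$n_sites[valid$k == 3], 1L)
  expect_equal(valid$n_sites[valid$k == 2], 1L)
  carriers <- dplyr::filter(sp, spectrum == "nonref_carriers")
  expect_equal(carriers$n_sites[carriers$k == 4], 1L)
  expect_equal(carriers$n_sites[carriers$k == 1], 1L)
  expect_equal(carriers$n_sites[carriers$k == 0], 1L)
  expect_equal(carriers$n_sites[carriers$k == 3], 1L)
})

test_that("complete-case fraction under random missingness matches the binomial closed form", {
  withr::with_seed(13, {
    gt <- random_gt(20000, 8, p_missing = 0.1)
    x <- make_variants("c1", pos = seq_len(20000), gt = gt)
    sp <- sharing_spectra(x)
    complete <- dplyr::filter(sp, spectrum == "valid_genotypes", k == 8)
    expect_equal(complete$n_sites / 20000, 0.9^8, tolerance = 0.05)
  })
})

test_that("per-window unique density recounts match a manual tally", {
  u <- tibble(
    clone = c("a", "a", "a", "b"),
    chrom = c("c1", "c1", "c1", "c1"),
    pos = c(10L, 999990L, 1000001L, 50L)
  )
  d <- unique_variant_density(u, c(c1 = 2e6), window = 1e6)
  a1 <- dplyr::filter(d, clone == "a", start == 0)
  expect_equal(a1$n_unique, 2L)
  expect_equal(a1$per_mbp, 2)
  a2 <- dplyr::filter(d, clone == "a", start == 1e6)
  expect_equal(a2$n_unique, 1L)
  b2 <- dplyr::filter(d, clone == "b", start == 1e6)
  expect_equal(b2$n_unique, 0L)     # zero-count windows are materialized
  ## uniform 282 unique on one 1 Mbp chromosome: single window holds all
  u282 <- tibble(clone = "a", chrom = "c2",
                 pos = as.integer(seq(1000, 999000, length.out = 282)))
  d282 <- unique_variant_density(u282, c(c2 = 1e6), window = 1e6)
  expect_equal(d282$n_unique, 282L)
  expect_equal(d282$per_mbp, 282)
})
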