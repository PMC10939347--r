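te_row <- function(pos, clone, chrom = "c1", family = "LTR_fam1",
                   te_class = "LTR", method = "m1") {
  tibble(chrom = chrom, pos = as.integer(pos), family = family,
         te_class = te_class, clone = clone, method = method)
}

test_that("the 10 kbp merge boundary is exclusive", {
  close_pair <- dplyr::bind_rows(te_row(5000, "a"), te_row(14999, "b"))
  ev <- cluster_tei(close_pair)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$k, 2L)
  far_pair <- dplyr::bind_rows(te_row(5000, "a"), te_row(15000, "b"))
  expect_equal(nrow(cluster_tei(far_pair)), 2)
})

test_that("duplicate detections of one clone count once and are flagged", {
  te <- dplyr::bind_rows(te_row(5000, "a"), te_row(5600, "a"),
                         te_row(6000, "b"))
  ev <- cluster_tei(te)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$k, 2L)
  expect_equal(ev$n_duplicate, 1L)
})

test_that("families are never merged by proximity alone unless asked", {
  te <- dplyr::bind_rows(te_row(5000, "a"),
                         te_row(5100, "b", family = "TIR_fam1",
                                te_class = "TIR"))
  expect_equal(nrow(cluster_tei(te)), 2)
  expect_equal(nrow(cluster_tei(te, require_family = FALSE)), 1)
})

test_that("single-linkage clustering matches the transitive-closure oracle", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      n <- 40
      te <- te_row(sample(1:100000, n),
                   clone = sample(paste0("cl", 1:8), n, replace = TRUE),
                   chrom = sample(c("c1", "c2"), n, replace = TRUE),
                   family = sample(c("LTR_f1", "TIR_f1"), n, replace = TRUE))
      te$te_class <- sub("_f1", "", te$family)
      ev <- cluster_tei(te)
      comp <- oracle_te_clusters(te)
      expect_equal(nrow(ev), length(unique(comp)))
      ## cluster signatures (chrom, family, span, size) must agree exactly
      oracle_sig <- vapply(
        split(seq_len(nrow(te)), comp),
        function(i) sprintf("%s|%s|%d|%d|%d", te$chrom[i][1], te$family[i][1],
                            min(te$pos[i]), max(te$pos[i]), length(i)),
        character(1)
      )
      got_sig <- sprintf("%s|%s|%d|%d|%d", ev$chrom, ev$family,
                         ev$pos_min, ev$pos_max, ev$n_members)
      expect_equal(sort(got_sig), sort(unname(oracle_sig)))
    }
  })
})

test_that("clustering is idempotent, conserves members, and radius is monotone", {
  sim <- small_sim()
  ev <- cluster_tei(sim$te)
  expect_equal(sum(ev$n_members), nrow(sim$te))
  ## re-clustering the event pinpoints changes nothing
  ev2 <- cluster_tei(
    tibble(chrom = ev$chrom, pos = ev$pos, family = ev$family,
           te_class = ev$te_class, clone = "x", method = ev$method)
  )
  expect_equal(nrow(ev2), nrow(ev))
  for (r in c(2000, 10000, 50000)) {
    expect_lte(nrow(cluster_tei(sim$te, radius = 50000)),
               nrow(cluster_tei(sim$te, radius = r)))
  }
})

test_that("the planted sharing spectrum is recovered exactly", {
  sim <- small_sim()
  ev <- cluster_tei(sim$te)
  spec <- tei_sharing_spectrum(ev, n_clones = 8)
  planted <- sim$config$te_counts_by_sharing
  for (m in sim$config$te_methods) {
    got <- dplyr::filter(spec, method == m)
    expect_equal(got$n_events, unname(as.integer(planted)))
  }
})

test_that("spectrum percentages and class counts come out as printed", {
  ev <- tibble(method = "m1", k = c(rep(1L, 7), rep(2L, 2), 3L),
               te_class = c(rep("LTR", 6), rep("TIR", 4)))
  spec <- tei_sharing_spectrum(ev, n_clones = 4)
  expect_equal(spec$percent[spec$k == 1], 70)
  expect_equal(sum(spec$n_events), 10L)
  cls <- tei_class_counts(ev)
  expect_equal(cls$te_class, c("LTR", "TIR"))
  expect_equal(cls$n_events, c(6L, 4L))
})

test_that("Spearman correlation handles monotone extremes and matches exact enumeration", {
  x <- c(8, 6, 4, 2, 1.5, 1, 0.5, 0.1)
  expect_equal(tei_snp_correlation(x, rev(x))$rho, -1)
  expect_equal(tei_snp_correlation(x, x)$rho, 1)
  withr::with_seed(14, {
    a <- rnorm(8)
    b <- rnorm(8)
    res <- tei_snp_correlation(a, b)
    expect_true(res$exact)
    ## against R's asymptotic-free statistic on the same ranks
    expect_equal(res$rho, cor(a, b, method = "spearman"))
    ## exact p equals full-enumeration proportion by construction; check a
    ## perfectly anti-monotone case has the smallest possible exact p
    res_min <- tei_snp_correlation(x, rev(x))
    expect_equal(res_min$p_value, 2 / factorial(8))
  })
})
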