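test_that("site quality filter masks low-DP genotypes and drops low-QD sites", {
  x <- make_variants("c1", pos = c(100, 200, 300), qd = c(30, 19.9, 25),
                     gt = matrix(1L, 3, 2))
  x$dp_s1 <- c(4L, 20L, 20L)
  out <- filter_site_quality(x)
  expect_equal(out$pos, c(100L, 300L))           # QD 19.9 removed
  expect_true(is.na(out$gt_s1[out$pos == 100]))  # DP 4 genotype masked
  expect_equal(out$gt_s2[out$pos == 100], 1L)    # site itself kept
})

test_that("missing QD annotation rejects the record with a warning", {
  x <- make_variants("c1", pos = c(100, 200), qd = c(NA, 30))
  expect_warning(out <- filter_site_quality(x), "missing QD")
  expect_equal(out$pos, 200L)
})

test_that("only biallelic records survive", {
  x <- make_variants("c1", pos = 1:7,
                     alt = c("A", "A,T", "T", "G", "C,G", "A", "T"))
  expect_equal(filter_biallelic(x)$pos, c(1L, 3L, 4L, 6L, 7L))
})

test_that("SNP-near-INDEL boundary is inclusive at 15 bp", {
  x <- make_variants("c1", pos = c(1000, 1015, 3000, 3016),
                     ref = c("A", "AT", "A", "AT"),
                     alt = c("T", "A", "T", "A"))
  out <- filter_snp_near_indel(x)
  expect_false(1000 %in% out$pos)  # 15 bp from an INDEL: removed
  expect_true(3000 %in% out$pos)   # 16 bp away: kept
  expect_true(all(c(1015, 3016) %in% out$pos))  # INDELs untouched
})

test_that("SNP-near-INDEL filtering matches the all-pairs oracle", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 60
      x <- make_variants(
        sample(c("c1", "c2"), n, replace = TRUE),
        pos = sample(1:2000, n),
        ref = ifelse(runif(n) < 0.3, "AT", "A"),
        alt = "A"
      )
      x$alt[x$ref == "A"] <- "T"
      x <- dplyr::arrange(x, chrom, pos)
      out <- filter_snp_near_indel(x)
      keep_oracle <- x[!oracle_snp_near_indel_drop(x), ]
      expect_equal(out$pos, keep_oracle$pos)
      expect_equal(out$chrom, keep_oracle$chrom)
    }
  })
})

test_that("INDEL length and spacing rules hit their boundaries", {
  long_del <- paste0(c("A", rep("T", 120)), collapse = "")
  x <- make_variants("c1", pos = c(100, 500, 549, 3000, 3050),
                     ref = c(long_del, "AT", "AT", "AT", "AT"),
                     alt = "A")
  out <- filter_indel_rules(x)
  expect_false(100 %in% out$pos)                  # 120 bp: discarded
  expect_false(any(c(500, 549) %in% out$pos))     # 49 bp apart: both removed
  expect_true(all(c(3000, 3050) %in% out$pos))    # exactly 50 bp: kept
})

test_that("INDEL spacing matches the pairwise oracle on clustered toys", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      n <- 40
      x <- make_variants("c1", pos = sort(sample(1:1500, n)),
                         ref = "AT", alt = "A")
      out <- filter_indel_rules(x)
      keep_oracle <- x[!oracle_indel_spacing_drop(x), ]
      expect_equal(out$pos, keep_oracle$pos)
    }
  })
})

test_that("missingness rule keeps 4-of-8 missing but drops 5-of-8", {
  gt <- rbind(
    c(rep(NA_integer_, 5), 1L, 1L, 1L),
    c(rep(NA_integer_, 4), 1L, 1L, 1L, 1L),
    rep(1L, 8)
  )
  x <- make_variants("c1", pos = 1:3, gt = gt)
  out <- filter_missingness(x)
  expect_equal(out$pos, c(2L, 3L))
})

test_that("cascade conserves counts and is idempotent", {
  sim <- small_sim()
  f1 <- suppressWarnings(filter_cascade(sim$variants, samples = sim$clones))
  rep1 <- filter_report(f1)
  n <- setNames(rep1$n, rep1$stage)
  expect_equal(
    n[["input"]],
    n[["retained"]] + sum(n[setdiff(names(n), c("input", "retained"))])
  )
  f2 <- filter_cascade(f1, samples = sim$clones)
  strip <- function(x) {
    attr(x, "filter_report") <- NULL
    as.data.frame(x)
  }
  expect_equal(strip(f2), strip(f1))
  removed <- filter_report(f2)
  expect_equal(removed$n[removed$stage == "retained"], nrow(f1))
  expect_true(all(removed$n[!removed$stage %in% c("input", "retained")] == 0))
})
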