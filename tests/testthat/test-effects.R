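# A hand-built two-exon gene on each strand (see build_toy_gene in the
# helpers) plus randomized planting against the re-translation oracle.

test_that("codon-level SNP calls are correct on the plus strand", {
  toy <- build_toy_gene("+")
  ## TGG -> TGA at codon position 3 is a stop gain: find a TGG codon first
  cds <- clonescan:::prepare_gene(toy$genes, toy$reference)$cds
  ## destroy the initiator ATG (genomic 101..103 holds A,T,G)
  out <- classify1(toy, 101L, toy$chars[101], setdiff(c("C", "G", "T"), toy$chars[101])[1])
  expect_equal(out$effect, "start_lost")
  expect_equal(out$impact, "HIGH")
  ## destroy the terminal stop TAA (last codon, genomic 248..250)
  out <- classify1(toy, 248L, "T", "C")
  expect_equal(out$effect, "stop_lost")
  ## any base change inside the initiator codon destroys it
  out <- classify1(toy, 102L, "T", "C")
  expect_equal(out$effect, "start_lost")
  ## an interior codon where neither ref nor alt is a stop stays non-HIGH:
  ## the second codon starts at genomic 104; C at its first base can only
  ## give CNN codons, never a stop
  out <- classify1(toy, 104L, toy$chars[104], "C")
  expect_equal(out$impact, "other")
})

test_that("frameshift and in-frame INDELs are separated by length mod 3", {
  toy <- build_toy_gene("+")
  ref2 <- paste0(toy$chars[110:112], collapse = "")
  out <- classify1(toy, 110L, ref2, substr(ref2, 1, 1))  # 2 bp deletion
  expect_equal(out$effect, "frameshift_variant")
  ref3 <- paste0(toy$chars[110:113], collapse = "")
  out <- classify1(toy, 110L, ref3, substr(ref3, 1, 1))  # 3 bp deletion
  expect_equal(out$effect, "none")
  expect_equal(out$impact, "other")
  ins <- paste0(toy$chars[110], "TTTT")
  out <- classify1(toy, 110L, toy$chars[110], ins)       # 4 bp insertion
  expect_equal(out$effect, "frameshift_variant")
})

test_that("splice-site calls fire within 2 bp of internal boundaries only", {
  toy <- build_toy_gene("+")
  ## intron is [130, 190) 0-based; donor side 0-based 130,131 = pos 131,132
  expect_equal(classify1(toy, 131L, "A", "T")$effect, "splice_site_variant")
  expect_equal(classify1(toy, 132L, "A", "T")$effect, "splice_site_variant")
  expect_equal(classify1(toy, 133L, "A", "T")$effect, "none")
  ## acceptor side 0-based 188,189 = pos 189,190
  expect_equal(classify1(toy, 189L, "A", "T")$effect, "splice_site_variant")
  expect_equal(classify1(toy, 188L, "A", "T")$effect, "none")
  ## a deletion straddling the exon edge is a flagged conservative call
  ref_span <- paste0(toy$chars[128:133], collapse = "")
  out <- classify1(toy, 128L, ref_span, substr(ref_span, 1, 1))
  expect_equal(out$effect, "splice_site_variant")
  expect_equal(out$flag, "partial_cds_overlap")
})

test_that("strand symmetry: minus-strand genes give codon-consistent calls", {
  toy <- build_toy_gene("-")
  ## initiator ATG sits at the high end of exon 2: genomic 248..250 is CAT
  out <- classify1(toy, 250L, toy$chars[250], "G")  # destroys the initiator
  expect_equal(out$effect, "start_lost")
  ## terminal stop at the genomic start of exon 1 (101..103 = TTA revcomp TAA)
  out <- classify1(toy, 103L, toy$chars[103], "G")
  expect_equal(out$effect, "stop_lost")
})

test_that("classifier agrees with the re-translation oracle on planted variants", {
  n_target <- 1000
  checked <- 0
  mism <- list()
  withr::with_seed(606, {
    for (strand in c("+", "-")) {
      toy <- build_toy_gene(strand, seed = if (strand == "+") 11 else 22)
      seg <- toy$genes
      cds_pos0 <- c(100:129, 190:249)
      while (checked < n_target / 2 * (1 + (strand == "-"))) {
        if (runif(1) < 0.6) {  # SNP anywhere in CDS
          p0 <- sample(cds_pos0, 1)
          ref <- toy$chars[p0 + 1]
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
          pos <- p0 + 1L
        } else {               # INDEL fully inside, away from first/last codon
          len <- sample(1:6, 1)
          if (runif(1) < 0.5) {
            p0 <- sample(c(104:(128 - len), 193:(245 - len)), 1)
            ref <- paste0(toy$chars[(p0 + 1):(p0 + 1 + len)], collapse = "")
            alt <- toy$chars[p0 + 1]
          } else {
            p0 <- sample(c(104:127, 193:244), 1)
            ref <- toy$chars[p0 + 1]
            alt <- paste0(c(ref, sample(c("A", "C", "G", "T"), len, TRUE)),
                          collapse = "")
          }
          pos <- p0 + 1L
        }
        got <- classify1(toy, pos, ref, alt)
        want <- oracle_effect(toy$chars, seg, pos, ref, alt)
        if (!identical(got$effect, want)) {
          mism[[length(mism) + 1]] <- list(strand, pos, ref, alt,
                                           got = got$effect, want = want)
        }
        checked <- checked + 1
      }
    }
  })
  expect_equal(checked, n_target)
  expect_length(mism, 0)
})

test_that("HIGH-impact summaries reproduce count-and-percent arithmetic", {
  calls <- tibble(
    chrom = "c1", pos = 1:5, ref = "A", alt = "T",
    vtype = c("SNP", "SNP", "INDEL", "INDEL", "INDEL"),
    gene_id = "g", effect = c("stop_gained", "none", "frameshift_variant",
                              "frameshift_variant", "none"),
    impact = c("HIGH", "other", "HIGH", "HIGH", "other"),
    flag = NA_character_
  )
  s <- summarize_high_impact(calls, c(SNP = 1000, INDEL = 200))
  expect_equal(s$by_type$n_high, c(1L, 2L))
  expect_equal(s$by_type$percent, c(0.1, 1))
  expect_equal(s$by_effect$percent, c(100, 100))
  s0 <- summarize_high_impact(calls[calls$impact == "none", ],
                              c(SNP = 10, INDEL = 10))
  expect_equal(s0$by_type$percent, c(0, 0))
})

test_that("planted stop-gains on simulated genes are recovered exactly", {
  sim <- small_sim()
  ## plant a TGG->TGA stop gain in each gene that has a TGG codon
  planted <- list()
  for (gid in unique(sim$genes$gene_id)) {
    g <- clonescan:::prepare_gene(sim$genes[sim$genes$gene_id == gid, ],
                                  sim$reference)
    codons <- substring(g$cds, seq(1, nchar(g$cds) - 2, 3),
                        seq(3, nchar(g$cds), 3))
    tgg <- which(codons == "TGG")
    tgg <- tgg[tgg > 1 & tgg < length(codons)]
    if (length(tgg) == 0) next
    cc <- (tgg[1] - 1) * 3 + 2         # 0-based coding coord of the G -> A
    seg <- g$seg
    if (g$strand == "+") {
      off <- cc
      for (i in seq_len(nrow(seg))) {
        w <- seg$end[i] - seg$start[i]
        if (off < w) { p0 <- seg$start[i] + off; break }
        off <- off - w
      }
      ref <- "G"; alt <- "A"
    } else {
      off <- cc
      for (i in rev(seq_len(nrow(seg)))) {
        w <- seg$end[i] - seg$start[i]
        if (off < w) { p0 <- seg$end[i] - 1 - off; break }
        off <- off - w
      }
      ref <- "C"; alt <- "T"
    }
    planted[[gid]] <- tibble(chrom = seg$chrom[1], pos = p0 + 1L,
                             ref = ref, alt = alt, gene = gid)
  }
  planted <- dplyr::bind_rows(planted)
  expect_gt(nrow(planted), 0)
  x <- make_variants(planted$chrom, planted$pos, ref = planted$ref,
                     alt = planted$alt, gt = matrix(1L, nrow(planted), 1))
  out <- classify_variant_effects(x, sim$genes, sim$reference)
  out <- out[out$gene_id %in% planted$gene, ]
  hit <- out[paste(out$chrom, out$pos) %in% paste(planted$chrom, planted$pos), ]
  expect_equal(nrow(hit), nrow(planted))
  expect_true(all(hit$effect == "stop_gained"))
})
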