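---
title: "Methods: quantifying clonal variability in a resequenced clone panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying clonal variability in a resequenced clone panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescan)
```

## The problem

Vegetatively propagated crops — pear, apple, grapevine — exist as panels of
*clones*: individuals descended from a single ancestral plant without sexual
reproduction. Two kinds of variation coexist in such a panel when it is
resequenced against a reference genome:

* **varietal variation** — variants shared by all clones relative to the
  reference, dominated by the ancestral tree's heterozygosity (such species
  are strongly outcrossing and their genomes are highly heterozygous);
* **intra-varietal (clonal) variation** — sites where at least one clone's
  genotype differs from the rest, the footprint of somatic mutations
  accumulated over decades to centuries of propagation. A *clone-unique*
  variant is the sharpest case: one clone's genotype differs from the
  identical genotype of all the others (e.g. `0/1` against seven `1/1`).

`clonescan` implements the full analysis chain for such panels — filtering a
joint multi-sample call set, classifying varietal vs clonal variation,
windowed diversity statistics, relatedness, mutation-density regions,
sequence sets for motif enrichment, simplified HIGH-impact effect
annotation, and transposable-element-insertion (TEI) sharing — plus a
synthetic population generator so every stage can be exercised and validated
against a known truth set without any data download.

## The filter cascade

The cascade reproduces a standard post-calling filter chain
(GATK-VariantFiltration-style site filters followed by bcftools/vcftools
rules) in a fixed order, with each removed record attributed to the first
stage that fails it:

1. **Site quality.** A sample's genotype becomes missing when its depth
   `DP < 5`; a site is dropped when its summed depth is below 5 or its
   quality-by-depth `QD < 20`. Treating low `DP` as a per-genotype mask
   reproduces both the depth filter and the "covered bases where every
   clone has at least 5x" accounting with one mechanism. Sites with no QD
   annotation cannot be evaluated and are rejected with a warning.
2. **Biallelic only** (exactly one ALT allele).
3. **SNP-near-INDEL.** A SNP within 15 bp of any INDEL in the set *as
   given* (the pre-INDEL-filter set, which is what a chained bcftools call
   sees) is removed. Whether the published 15 bp is measured to the INDEL's
   POS or its full span is not stated; we use POS-to-POS, boundary
   inclusive.
4. **INDEL rules.** INDELs longer than 100 bp are discarded; then both
   members of any INDEL pair closer than 50 bp are removed (clustered-indel
   semantics; a pair exactly 50 bp apart survives).
5. **Missingness.** A record with missing genotypes in strictly more than
   half of the clones is removed: with eight clones, four missing calls are
   tolerated, five are not.

The cascade is idempotent, and its report always satisfies
`input = retained + sum(removed)`.

## Clonal classification

All genotypes are unphased diploid calls, handled as alt-allele dosages
(`0/1` and `1/0` are the same call). *Polymorphic* sites have at least two
distinct non-missing genotypes among the clones; the main classification
runs on the complete-case subset (no missing call in any clone) so that
downstream statistics see a constant sample size. A polymorphic site is
assigned to a clone as *clone-unique* only when that clone differs from all
others **and** the others are mutually identical; sites with two or more
distinct minority genotypes stay polymorphic-but-shared. Unique and shared
sites therefore partition the polymorphic set.

Per-clone unique-variant densities are reported in tumbling windows (1 Mbp
by default, 1 kbp for the motif sets). The published description of these
windows ("1 Mbp sliding windows" with densities quoted per Mbp) is
ambiguous between tumbling and sliding; tumbling is the default and a
`stride` argument exposes sliding.

## Diversity statistics

With `n` clones the panel carries `2n` haplotypes; because pi, Watterson's
theta and Tajima's D depend only on per-site allele frequencies, unphased
dosages suffice. For a biallelic site with `c` alt alleles among `m`
haplotypes the per-site diversity is the unbiased pairwise mismatch rate

$$\hat\pi = \frac{2c(m-c)}{m(m-1)},$$

summed over sites per 50-kbp non-overlapping window. Watterson's estimator
is `S / a1` with `a1` the harmonic number of `m - 1`, and Tajima's D uses
the standard 1989 normalization. D is undefined (`NA`) when `S = 0` or the
variance term vanishes. Chromosome-level values aggregate the windows' `S`
and pi sums and recompute theta and D from the totals. Statistics are
computed on the complete-case polymorphic SNPs so `m` is constant.

Covered bases — bases where *every* clone is covered, from the per-sample
masks — are carried per window. Because the printed unit of per-bp
diversity in tables of this kind is ambiguous, both the raw per-window sums
and per-covered-bp values scaled by 10^3 ("per-kbp equivalents") are
emitted; the choice of denominator (covered bases, not window width) is
explicit in the column names.

A clone panel is genealogically star-like: most polymorphic sites are
somatic singletons, so the site-frequency spectrum is strongly skewed
toward rare variants and Tajima's D is expected to be markedly negative
genome-wide — more negative than in a sexual population sample. The tests
assert exactly this sign structure rather than any particular magnitude.

## Relatedness

Kinship uses the KING-robust within-pair estimator

$$\varphi = \frac{N_{het,het} - 2\,N_{opp}}{N_{het}(i) + N_{het}(j)},$$

chosen over the homogeneous-population estimator because the panel mixes
near-identical clones with an unrelated accession — exactly the situation
the within-pair denominator is robust to. Published KING analyses do not
always state which estimator was used; the choice is fixed here and
validated analytically: an identical pair with any het site gives exactly
0.5 ("selfing"), Mendelian gene-dropping gives 0.25 for parent-offspring
pairs, and independent Hardy-Weinberg samples center on 0.

The PCA operates on the samples-by-sites dosage matrix of complete-case
polymorphic sites, mean-centered; `1/sqrt(2p(1-p))` scaling is available
behind a flag but off by default (plain covariance PCA of dosages, matching
common practice for panels like this where near-monomorphic somatic sites
would otherwise be up-weighted). Explained-variance fractions come from the
full singular spectrum.

`ibd_gene_drop()` drops uniquely labelled founder alleles through a fixed
three-founder pedigree at independent loci and reports the mean fraction of
alleles shared identical-by-descent (a locus sharing one allele scores 1/2).
This is the classical "fraction of genome shared": 25% for half-siblings,
50% for parent-offspring and full siblings.

## Mutation-density regions

Windows (50 kbp by default, matching the diversity windows — the published
window size for this classification is not stated, and one windowing
convention across the package keeps regions comparable) are classified by
rate thresholds: `LOW` at 1 SNP/kbp or rarer, `HIGH` at 1 SNP per 50 bp
(20/kbp) or more; INDEL tracks use < 0.2 and > 2 per kbp. Rates are
computed over jointly covered bases, and — deliberately — only variants
*inside* the jointly covered territory enter the numerator; otherwise
partially covered windows get arbitrarily inflated rates. Windows with zero
covered bases stay unclassified and break region merging. Adjacent
same-class windows merge into maximal regions (idempotently). Only sites
actually carried by the clone panel count: records where every clone is
hom-ref (outgroup-only variants) are not panel variation.

The companion independence check correlates the per-window *rate* (not the
raw count, which is trivially tied to callable territory) with the amount
of low-coverage sequence, using Spearman's rank correlation and a
permutation p-value.

## Motif sequence sets

Three FASTA sets feed external STREME-style motif discovery:

* **CONTROL** — each chromosome is tiled into non-overlapping 10-kbp
  windows (trailing partial windows skipped); windows with *no* mutation
  for any clone contribute their middle portion, window-relative offsets
  4250–5750. The published coordinates are treated as 0-based half-open
  offsets — a 1500 bp fragment, which is the only reading consistent with
  the stated fragment length.
* **HIGH / VERY_HIGH** — 1-kbp tumbling windows where a single clone
  accumulated strictly more than 5 (resp. 10) mutations, extended by
  250 bp flanks to 1500 bp; fragments running off a chromosome end are
  skipped. VERY_HIGH is a subset of HIGH by construction.

"Mutations" means clone-unique variants, since these sets follow the
unique-variant analysis; any position table can be passed to use a
different definition.

## Simplified effect annotation

The effect classifier is a deliberate reduction of a SnpEff-class annotator
to the HIGH categories analyzed downstream; everything else is lumped as
`other`. For SNPs inside a CDS the affected codon is re-translated on the
coding strand: `stop_gained`, `stop_lost` (terminal or internal reference
stop destroyed), `start_lost` (initiator ATG destroyed). INDELs fully
inside the CDS are `frameshift_variant` when their length is not divisible
by 3 and non-HIGH otherwise. Variants within 2 bp of an internal CDS/intron
boundary on the intron side are `splice_site_variant`, and an INDEL
partially overlapping a CDS edge gets the same call conservatively, with a
flag. GFF3 coordinates (1-based inclusive) are converted to 0-based
half-open internally.

The classifier is validated against an independent oracle that performs the
sequence surgery literally — mutates the chromosome, shifts the CDS
coordinates, re-extracts and re-translates the whole CDS, and diffs the
protein products — with 100% agreement required on randomly planted
variants on both strands. Known limitation: an in-frame INDEL whose
junction codon happens to spell a stop is still classified non-HIGH; the
category set is minimal by design, and the published HIGH sets likewise
leave their residual categories unenumerated.

## TEI sharing

Non-reference TE insertions are 1-bp pinpoints, so per-clone detections of
one event scatter around the true insertion point. Detections of the same
family on the same chromosome (and the same caller method — methods are
never merged) are clustered by single linkage: sorted by position,
consecutive pinpoints strictly closer than 10 kbp are linked. The published
rule is pairwise; applying it transitively means a chained cluster can span
more than 10 kbp, which is documented rather than hidden. Whether family
identity was required for merging is slightly ambiguous in the original
description ("the same TE"); it is required by default and relaxable by
flag. A clone detected twice in one cluster counts once and is flagged.

Sharing spectra report events by the number of distinct carrier clones;
the unique-TEI vs unique-SNP correlation uses Spearman with mid-ranks and
an exact permutation p-value (full enumeration of the 8! rankings for
panels of up to eight clones, Monte-Carlo above).

## The synthetic generator

`simulate_population()` draws a single diploid "variety" against a random
reference at population loci (per-locus allele frequency uniform on
[0.05, 0.95], Hardy-Weinberg genotypes), calibrated so the realized
variety-vs-reference SNP rate is 7.3/kbp (0.79 INDELs/kbp) — the rates
observed for such a panel. Every clone inherits the variety genotype;
clone-specific somatic het mutations are then planted at Poisson counts
around per-clone rates, by default one strongly divergent clone at 282
SNPs/Mbp and the rest uniform in 10–28 SNPs/Mbp. An optional unrelated
outgroup is an independent Hardy-Weinberg draw at the same loci — this, not
a fixed genotype, is what makes clone-vs-outgroup kinship center on zero.

Further structure, with the reasoning behind each default:

* **IBD-like tracts** (10% of the genome, one tract per chromosome,
  boundaries on a 50-kbp grid) are modelled as regions of depressed
  *population* polymorphism — such low-variability regions recur across
  accessions and even related species — rather than as variety-only
  hom-ref stretches, which would manufacture opposite homozygotes against
  the outgroup and bias kinship negative. The realized tract rate defaults
  to 0.2 SNP/kbp: tract variability is "almost null", and the value keeps
  tract windows safely below the 1 SNP/kbp LOW threshold even after the
  somatic background lands on top.
* **Somatic hotspots**: 30% of each clone's somatic SNPs are packed into
  ~8-mutation 1-kbp windows, the rest scattered uniformly. Clonal panels
  accumulate much of their variability in very narrow kbp-scale locations
  that differ between clones; a purely uniform model would never populate
  the >5/>10-mutations-per-kbp sequence sets at all.
* **Depth and quality**: per-genotype depth is Poisson(16) (the panel's
  mean filtered depth); true sites carry QD 25 while a configurable
  fraction of *artifact* sites (random genotypes, QD < 20) gives the
  quality filter real work without perturbing the truth set.
* **INDEL lengths** are a mixture of geometric(0.5) and 2% uniform
  50–120 bp draws, capped at 120 bp — a pure geometric draw would never
  reach the 100 bp length filter.
* **Missingness** (3% per genotype) and per-sample coverage dropout
  intervals (about one 10–60 kbp interval per sample per chromosome)
  generate realistic missingness spectra and a non-trivial covered-bases
  accounting; genotypes inside a sample's dropout are missing.
* **TE events** are planted on a 15-kbp slot grid with per-clone pinpoint
  jitter uniform in ±2 kbp, so members of one event always stay within the
  10-kbp merge radius while distinct same-family events never touch; the
  default sharing spectrum is dominated by clone-exclusive events (about
  47% exclusive, about 1% shared by all) scaled to 250 events per method.
* **Somatic genotype model**: het gain at a new site, matching the
  genotype-level divergence the clone-unique definition is built on
  (`0/1` against identical others). Loss-of-heterozygosity events
  (`0/1 -> 1/1` at an existing varietal het site) are available through
  `loh_fraction` and default to off, since the published material shows
  the genotype pattern but not the mechanism mix.

What the generator does **not** emulate: read-level errors (there is no
genotype-error model, so recovery of planted truth on analyzable sites is
exact), linkage disequilibrium between loci, mutational signatures or
sequence-context effects, shared somatic variants between clones (all
polymorphic simulated sites are clone-unique by construction), and
reference/assembly artifacts. Passing tests therefore demonstrate that the
estimators and classifiers are correct on data satisfying their model
assumptions — not that real data meet those assumptions.

## Numerical choices and problem sizes

Determinism is absolute: the same seed and configuration give byte-identical
artifacts, and every source of randomness in the pipeline (including
permutation p-values) is seeded. Window tiling is 0-based half-open
everywhere; VCF positions are 1-based; BED and GFF3 follow their own
conventions on disk and are converted at the boundary. Poisson-consistency
tests use 3–4 sigma bands; the stochastic IBD anchor uses 100,000 loci for
a standard error of about 0.07 percentage points against a ±1 point band.
The test suite exercises the full default study conditions (eight clones
plus outgroup, three 2-Mbp chromosomes, about 58,000 sites) once, and
smaller 0.4–0.9 Mbp panels elsewhere; these sizes were chosen so the whole
suite completes in about a minute and a half while every stage still sees
thousands of sites.

## Known limitations

* The effect classifier's category set is minimal (five HIGH effects); see
  above for the in-frame-junction caveat.
* Chained TEI clusters can exceed the pairwise merge radius (single
  linkage), and the representative event position is the median pinpoint.
* Spearman permutation p-values are exact only up to eight samples.
* Chromosome-level Tajima's D recomputed from aggregated window sums
  assumes the same haplotype count in every window (guaranteed by the
  complete-case design).
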