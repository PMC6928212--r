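---
title: "Mapping a high-protein trait: genome scans, bulked segregants and pedigree retention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a high-protein trait: genome scans, bulked segregants and pedigree retention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protmap)
```

## The problem

Seed protein content in soybean is a quantitative trait controlled by several
loci of very unequal effect. A breeding program that has introgressed
high-protein alleles from a donor cultivar into adapted germplasm leaves three
complementary kinds of evidence about where those alleles sit:

1. a biparental RIL population segregating for the trait, which supports a
   genome scan for QTLs;
2. several further RIL populations too small or too expensive to genotype
   fully, which support bulked-segregant analysis (BSA) on their phenotypic
   extremes; and
3. the pedigree itself — a donor cultivar and a set of derived high-protein
   cultivars bred through repeated cycles of selection — which supports a
   genome-wide search for donor alleles that are rare in the general
   germplasm but were retained by every (or nearly every) descendant.

protmap implements all three tracks plus a simulation module that generates
data under the same genetic model the analyses assume, so each stage can be
validated against known truth.

## The genetic model behind the simulator

**RIL populations.** Lines are produced by strict single-seed descent from
the F1 of two fully homozygous parents. Each meiosis places a
Poisson(L/100) number of crossovers uniformly on a chromosome of length L cM
— the Haldane model, no interference. An F_k-derived line retains residual
heterozygosity (1/2)^(k-1) (6.25% for the default F5), and the genotype
codes are A (parent-1 homozygote), H, B. We chose Haldane both for the
generator and for the scanner's genotype probabilities so that the two sides
of every simulation study share one self-consistent model; no mapping
function is implied by the data themselves at these marker densities.

**Phenotypes.** The trait is percent seed protein:

\[
y_{it} = \mu + \textstyle\sum_j a_j x_{ij} + \sum_{jk} w_{jk} x_{ij} x_{ik}
        + t_t + e_{it},
\]

with dosage \(x \in \{-1, 0, +1\}\), balanced trials \(t = 1..T\) and
within-trial residual \(e\). Defaults: \(\mu = 44\) (midway between
high-protein parents near 48% and low-protein parents near 40%), T = 3
trials, residual SD 2.4 percentage points, trial-effect SD 0.8. Under
balanced trials the arithmetic line mean equals the least-squares mean, and
the common trial effect cancels from the between-line variance, so the
line-mean residual variance is \(\sigma_e^2 / T\). When a `qtl_model`
carries target variance fractions, `simulate_phenotypes()` solves for the
effects against the *empirical* dosage variances of the simulated
population, so each locus's marginal share of the line-mean variance matches
its target in expectation. By default the trait-increasing alleles come from
parent 1 (code A), matching a high x low cross with the high parent written
first.

**The five-locus architecture.** The published per-locus variance
contributions for this germplasm are 60, 23, 14, 13 and 1 percent
(chromosomes 20, 15, 1, 16 and an epistatic chromosome 5 x 20 pair), while
the jointly explained total is 70 percent. For unlinked loci, marginal
fractions add, so the five printed marginals (sum 111%) and the printed
joint total cannot both hold in one population; they evidently reflect
overlapping single-locus fits in the original data. Where the two collide we
treat the joint total as binding: `variance_recovery_study("five")`
allocates per-locus shares proportional to 60:23:14:13:1 and scales them so
the joint five-term model explains 70% of the line-mean variance
(38/15/9/8/0.6%). The single- and two-locus studies use the printed 60% and
60/23% directly, which are feasible as stated. This choice is a modeling
decision, made once; its consequence is that the chromosome-1 and -16
marginals in the five-locus study are ~9 and ~8 rather than 14 and 13.

**Diversity panel and pedigree descent.** `simulate_panel()` draws an
inbred SNP panel (background minor-allele frequencies uniform on 0.05–0.5,
1% residual heterozygosity) and injects donor-rare SNPs at a chosen panel
frequency; a configurable subset of them is placed in tight physical
clusters (default 4 clusters spanning 1 Mb), because a donor's rare alleles
really arrive as haplotype blocks, and block-shaped truth is what the
retention scan must recover. `simulate_descent()` then builds each
derivative cultivar as a donor/recurrent-parent mosaic: SNPs inside the
retained blocks are always donor (modeling selection), and outside them the
genome is partitioned into independently segregating 10-Mb segments that
are donor with a configurable retention probability (default 0.25, a
plausible expectation for a backcross-derived program after further cycles).
What this deliberately does *not* emulate: linkage drag around the forced
blocks, genotyping error, and any correlation between panel structure and
the trait — so passing the end-to-end test shows the filters recover
block-shaped retained haplotypes under clean inheritance, not that they are
robust to assay artefacts.

## The genome scan

The test statistic is a likelihood-ratio-type quantity from Haley–Knott
regression of line means on expected dosage,

\[ \mathrm{TS} = n \,\ln(\mathrm{RSS}_0/\mathrm{RSS}_1), \]

evaluated on a 1-cM grid (marker positions always included). Expected
dosages come from exact conditional genotype probabilities: for each grid
point the joint distribution of (left flank, grid point, right flank) is
computed by iterating the full single-seed-descent diplotype distribution
through k−1 selfings and conditioning on the nearest informative flanking
observations; missing flanks are handled by walking outward, a fully
missing line falls back to the generation prior ((1−h)/2, h, (1−h)/2).
The statistic's scale is immaterial because the genome-wide threshold is the
empirical (1−α) quantile of the per-permutation maximum TS (default 10,000
permutations, α = 0.05 — the 9,500th order statistic). Heterozygote dosage
is 0: an additive-only model, reasonable for RILs with ~6% residual
heterozygosity; dominance is out of scope.

`sCIM` adds background cofactor markers (by default the most associated
marker per ~30 cM, excluded within ±20 cM of the tested position) to both
the null and full models; with an empty cofactor set it reduces to SIM
exactly, which the tests assert point by point. Peak calling reports one
peak per chromosome unless the profile dips below the threshold between
maxima, or a shoulder is separated by a dip of at least 25% of the lower
maximum. `anchored_scan()` holds the major QTL's dosage in the model and
reports separate statistics for an added additive term and an added
anchor x test interaction, excluding the anchor's ±20 cM neighborhood; this
is how a locus with ~no marginal effect but an epistatic interaction with
the major QTL is found.

Numerical details that matter: collinear cofactors are dropped once,
globally, with a warning; a constant phenotype yields an all-zero profile
with a warning rather than an error; RSS values are floored at 1e-12 before
the log; permutation thresholds with fewer than 20 lines warn that the
threshold is unstable; `alpha = 1` degenerates to the minimum null maximum,
so every point is declared.

## Bulked-segregant analysis

Bulks are the top and bottom `tail_fraction` (default 0.1, at least 8
lines) of the line means; boundary ties break by line-name order so bulk
membership is deterministic. Bulk genotyping is modeled by pooling the
member lines' calls into allele counts (a heterozygote contributes one
allele of each kind) rather than by a pooled-DNA intensity model — the
published design genotyped DNA pools, but gives no intensity model, and at
these bulk sizes the information content is equivalent. A marker is
`positive` when the high-parent allele-frequency contrast Δf = f_high −
f_low is at least `delta_threshold` (default 0.4) *and* Fisher's exact test
on the 2x2 allele-count table gives p ≤ 0.05; `fixed_high` when both bulks
carry the high parent's allele at ≥ 0.95 — fixation is consistent with a
locus being required for high protein, so `cross_population_summary()`
counts positives *plus* fixed-high populations as support. A high x high
cross cannot show a contrast at loci where both parents carry the high
allele, so such populations are excluded from locus discovery and only
report their allele status at loci the other populations found. The
positive-call criterion in the original study is not quantified anywhere;
these defaults are decisions, exposed in the configuration, not
reconstructions.

## The retention scan

Four filters, in order, each a separate function so intermediate sets are
inspectable:

1. `rare_allele_scan()` — SNPs where the focal line is homozygous for an
   allele with panel frequency ≤ `max_panel_frequency` (default 0.02;
   retained rare-allele frequencies of 0.05–1.1% have been reported for
   this kind of screen). Heterozygous or missing focal calls are skipped.
   The focal line itself counts toward the frequency; its known descendants
   should be passed via `exclude`, since their carrier status is exactly
   what the later filter measures.
2. `contrast_filter()` — the recurrent parent must be homozygous for the
   other allele; absence from further low-protein lines is a hard filter by
   default but can be demoted to an annotation (`require_low_absent =
   FALSE`), since the original description is ambiguous on this point.
   Missing comparator calls keep the SNP, flagged.
3. `retention_filter()` — retention ratio ρ = carriers / informative
   derivatives, carrier meaning homozygous for the focal allele (hets count
   as neither carrier nor informative by default; `het_as_carrier` flips
   this), keep when ρ ≥ `min_ratio` (0.66 broad screen, 1.0 strict screen)
   with at least `min_informative` = 4 informative derivatives. Whether the
   published 66% ratio counted missing genotypes in its denominator is
   unstated; the informative-only denominator is our decision.
4. `build_blocks()` — single-linkage clustering along each chromosome with
   `max_gap_bp` = 500 kb and `min_snps` = 2 (how the published blocks were
   delimited is not stated; these defaults reproduce block sizes from
   ~100 kb to ~10 Mb on realistic densities). Coordinates are 1-based
   inclusive internally and 0-based half-open in BED output. Sub-threshold
   clusters are kept as a singleton list so that every surviving SNP
   appears exactly once.

`annotate_blocks()` links blocks to anchor markers and known regions
(QTL/BSA loci, consensus Meta-QTL tables) within `link_distance_bp` of the
block edges; unannotated blocks are labeled novel. The pipeline's strict
(ρ = 1) report can exclude blocks already present in the broad report
(`novel_only_strict`), mirroring the convention of reporting only the new
strict-screen blocks.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- read_config(system.file("extdata", "demo_config.yaml",
                               package = "protmap"))
res <- run_pipeline(cfg, out_dir = tempfile("protmap_demo"))
attr(res$scan, "peaks")
res$retention_blocks
```

## Validation studies and problem sizes

The package's quantitative validation is parameter recovery on simulated
data, run by `variance_recovery_study()` and the test suite at these sizes
(chosen so a study represents the published design faithfully while staying
a desk-scale computation):

* 200 replicate F5-derived populations of 100 lines on the ~640-marker,
  20-chromosome framework-map skeleton per architecture (single, two-locus,
  five-locus), scanned on a 1-cM grid; mean recovered variance explained is
  compared with the simulated truth within ±5 percentage points.
* Permutation calibration: 1,000 null genomes on a 5-chromosome map, each
  thresholded by its own 1,000 permutations at α = 0.05; the genome-wide
  false-positive rate must be 0.05 ± 0.02 (the procedure's exact nominal
  level is 51/1001 ≈ 0.051).
* Retention end-to-end: a 300-line panel with ~20,000 SNPs and 8 injected
  donor clusters; the strict screen must recover every injected block with
  ≥90% span overlap and ≤10% false blocks.

The tests also check the machinery against independent oracles: the exact
genotype-probability recursion against a Monte-Carlo single-seed-descent
simulator that recombines per interval instead of placing crossovers; the
interval statistic against plain single-marker regression at marker
positions; recombination between simulated marker pairs against
R = 2r/(1+2r); and the clustering, nesting and monotonicity properties of
the BSA and retention filters against brute-force implementations.

## Known limitations

* The map skeleton places markers at the per-chromosome mean spacing;
  real maps have long gaps (up to ~64 cM) that locally weaken interval
  mapping. Recovery results are therefore mildly optimistic about position
  accuracy in sparse regions.
* No dominance, no genotype-by-environment interaction, no selective
  genotyping corrections; BSA is in-silico pooling, not pooled-DNA signal.
* The retention scan assumes biallelic SNPs and an essentially inbred
  panel; no imputation, phasing or LD-based haplotype inference is
  attempted, and gene-level annotation is out of scope.
* Published headline counts that depend on the original (undeposited)
  genotype datasets — e.g. the number of SNPs surviving each filter on the
  real panel — are covered only by direction-of-effect and truth-recovery
  checks on synthetic data.
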