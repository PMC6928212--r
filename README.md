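# protmap

Tools for dissecting a high seed-protein trait in soybean breeding
germplasm, for geneticists and breeders who have three kinds of evidence and
want them analyzed coherently:

* a biparental **RIL population** → genome scan (simple / simplified
  composite interval mapping) with permutation-based genome-wide thresholds
  and an anchored re-scan for additive and epistatic effects;
* additional populations genotyped only at their phenotypic extremes →
  **bulked-segregant analysis** with positive / fixed-allele marker
  classification and cross-population locus support;
* a pedigree of a donor cultivar and its selected descendants plus a
  diversity SNP panel → **rare-allele retention scan** that finds donor
  alleles rare in the panel, absent from the recurrent parent, retained
  across the derivatives, and assembles them into physical genomic blocks.

A simulation module (`simulate_ril_population()`, `simulate_phenotypes()`,
`simulate_panel()`, `simulate_descent()`) generates all of these data types
with known truth, so every stage is testable without external data.

## The model in brief

RILs are simulated by strict single-seed descent under the Haldane model
(crossovers Poisson(L/100), positions uniform); an F5-derived line keeps
(1/2)^4 = 6.25% residual heterozygosity. The trait is

    y_it = mu + sum_j a_j x_ij + sum_jk w_jk x_ij x_ik + t_t + e_it

with dosage x in {-1, 0, +1} over balanced trials. The scan statistic is a
likelihood-ratio-type quantity from Haley–Knott regression of line means on
the expected dosage,

    TS(pos) = n · ln(RSS0 / RSS1),

computed on a 1-cM grid from exact F_k single-seed-descent genotype
probabilities, with the genome-wide critical value taken as the empirical
(1 − alpha) quantile of per-permutation maximum TS (10,000 permutations,
alpha = 0.05 by default). Retention ratio rho = carriers / informative
derivatives, with the broad screen at rho ≥ 0.66 and the strict screen at
rho = 1.0; surviving SNPs ≤ 500 kb apart join one block.

## Worked example

```r
library(protmap)
cfg <- read_config(system.file("extdata", "demo_config.yaml",
                               package = "protmap"))
res <- run_pipeline(cfg, out_dir = "demo_out")
res$scan
```

```
QTL scan (SIM): 3892 grid points on 20 chromosome(s)
  genome-wide threshold: 15.475
  declared peaks:
 chrom pos_cM nearest_marker       ts        r2
  Gm15   74.0   Gm15_dart_24 22.26093 0.1995725
  Gm20   61.2   Gm20_dseq_18 44.96233 0.3621316
```

The demo simulates a 100-line F5-derived RIL population carrying the
five-locus architecture (chromosome 20 major QTL, chromosome 15 secondary
QTL, minor loci on 1 and 16, an epistatic 5 x 20 pair) and declares the two
QTLs that clear the 300-permutation threshold: the chromosome-20 peak
explains ~36% of the line-mean variance here and the chromosome-15 peak
~20%, close to the simulated per-locus shares. The retention stage recovers
the donor haplotype blocks injected into the synthetic 60-line panel:

```r
res$retention_blocks
```

```
Retention blocks: 4 block(s); 1 singleton cluster(s)
 chrom    start      end n_snps mean_rho span_kb
  Gm02 51474721 52380223      5        1   905.5
  Gm10 23299999 23783436      5        1   483.4
  Gm16 15572056 16107454      5        1   535.4
  Gm16 36458582 37064389      5        1   605.8
```

Every output is also written as plain text (scan profile and peaks, BSA
calls and merged loci, blocks as TSV and BED, provenance with config digest
and seed registry) under `out_dir`. A thin command-line wrapper with
`simulate` / `scan` / `bsa` / `retain` / `run` subcommands is installed at
`inst/cli/protmap.R`.

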