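Package: protmap
Title: QTL Scans, Bulked-Segregant Analysis and Pedigree Rare-Allele
    Retention for High-Protein Soybean Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dissecting a quantitative seed-composition trait in
    biparental and pedigree-derived soybean germplasm. Implements simple and
    simplified composite interval mapping on recombinant inbred line (RIL)
    populations with permutation-based genome-wide thresholds and an anchored
    additive/epistatic re-scan; in-silico bulked-segregant analysis with
    positive/fixed-allele marker classification across multiple populations;
    and a genome-wide pedigree rare-allele retention scan that delimits
    physically clustered donor haplotype blocks and annotates them against
    marker and consensus-QTL tables. A simulation module generates diversity
    panels, backcross pedigrees with retained donor segments, single-seed
    descent RIL populations and multi-trial phenotypes with additive and
    epistatic locus effects calibrated to target variance fractions, so every
    stage can be validated on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
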