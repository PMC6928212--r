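# Independent oracles used across the test files. These deliberately take a
# different computational route from the package: genotypes are generated by
# per-interval Bernoulli recombination at marker positions (not by Poisson
# crossover placement), and clustering is done by brute force.

# Monte-Carlo single-seed-descent oracle: n lines, loci separated by
# per-meiosis recombination fractions r_vec, advanced to generation k.
# Returns an n x m matrix of genotype codes 1 = A, 2 = H, 3 = B.
oracle_ssd <- function(n, r_vec, k) {
  m <- length(r_vec) + 1L
  gamete <- function(H1, H2) {
    src <- matrix(0L, n, m)
    src[, 1] <- stats::rbinom(n, 1L, 0.5)
    for (j in seq_along(r_vec)) {
      sw <- stats::rbinom(n, 1L, r_vec[j])
      src[, j + 1] <- (src[, j] + sw) %% 2L
    }
    H1 * (1L - src) + H2 * src
  }
  H1 <- matrix(0L, n, m)
  H2 <- matrix(1L, n, m)
  for (g in seq_len(k - 1L)) {
    G1 <- gamete(H1, H2)
    G2 <- gamete(H1, H2)
    H1 <- G1; H2 <- G2
  }
  H1 + H2 + 1L
}

# Brute-force single-linkage clustering of positions with a gap threshold.
oracle_cluster <- function(pos, gap) {
  pos <- sort(pos)
  grp <- cumsum(c(TRUE, diff(pos) > gap))
  unname(split(pos, grp))
}

# Small multi-chromosome test map: n_chr chromosomes, markers every
# `by` cM up to `len` cM.
test_map <- function(n_chr = 5, len = 60, by = 10) {
  pos <- seq(0, len, by = by)
  chrs <- sprintf("C%02d", seq_len(n_chr))
  genetic_map(marker = as.vector(outer(seq_along(pos), chrs,
                                       function(i, c) paste0(c, "_m", i))),
              chrom = rep(chrs, each = length(pos)),
              pos_cM = rep(pos, n_chr),
              bp = rep(pos * 4e5 + 1, n_chr))
}

# Simulated population + phenotype with one QTL at the middle marker of the
# first chromosome.
sim_one_qtl <- function(map = test_map(), n = 100, frac = 0.6, seed = 1,
                        chrom = "C01", pos = 30) {
  rg <- simulate_ril_population(map, n, 5, seed = seed)
  m <- qtl_model(data.frame(chrom = chrom, pos_cM = pos),
                 target_variance_fractions = frac)
  ph <- simulate_phenotypes(rg, m, seed = seed + 1000)
  list(geno = rg, phen = ph, y = line_means(ph))
}

# Synthetic pedigree panel with injected donor haplotype blocks: a diversity
# panel, a donor whose rare SNPs partly cluster, and 7 derivatives built by
# descent with the clusters as retained blocks. Truth = the cluster spans.
retention_fixture <- function(seed = 61, n_lines = 80, snp_density = 250,
                              n_rare = 60, p_out = 0.25,
                              map = test_map(4, len = 100, by = 10),
                              n_clusters = 4, cluster_span_bp = 8e5,
                              snps_per_cluster = 5) {
  pan <- simulate_panel(n_lines, map, snp_density,
                        donor_rare_config = list(
                          n_rare = n_rare, rare_frequency = 1 / n_lines,
                          n_clusters = n_clusters,
                          cluster_span_bp = cluster_span_bp,
                          snps_per_cluster = snps_per_cluster),
                        seed = seed)
  derivs <- sprintf("D%02d", 1:7)
  ped <- pedigree(nodes = c("Donor", "V002", "V003", "V004", derivs),
                  parents = stats::setNames(
                    rep(list(c("Donor", "V002")), 7), derivs),
                  donor = "Donor", recurrent_parent = "V002",
                  derivatives = derivs, low_lines = c("V003", "V004"))
  clus <- attr(pan, "rare_clusters")
  truth <- do.call(rbind, lapply(clus, function(ids) {
    i <- match(ids, pan$snp_info$id)
    data.frame(chrom = pan$snp_info$chrom[i[1]],
               start = min(pan$snp_info$bp[i]),
               end = max(pan$snp_info$bp[i]))
  }))
  pan <- simulate_descent(pan, ped, truth, p_out, seed = seed + 1)
  list(panel = pan, ped = ped, truth = truth, derivs = derivs)
}
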