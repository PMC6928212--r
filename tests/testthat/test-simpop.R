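test_that("single-seed descent matches F_k heterozygosity and degenerate cases", {
  gm <- genetic_map(paste0("M", 1:4), "C01", c(0, 10, 10, 40))
  rg <- simulate_ril_population(gm, 3000, 5, seed = 42)
  expect_equal(dim(rg), c(3000, 4))
  expect_true(all(unclass(rg) %in% c("A", "H", "B")))
  # markers 2 and 3 are 0 cM apart: identical columns
  expect_identical(unclass(rg)[, 2], unclass(rg)[, 3])
  # heterozygosity (1/2)^(k-1) within 3 binomial SEs at every marker
  h <- colMeans(unclass(rg) == "H")
  se <- sqrt(0.0625 * 0.9375 / 3000)
  expect_true(all(abs(h - 0.0625) <= 3 * se))
  # and for another generation
  rg2 <- simulate_ril_population(gm, 3000, 3, seed = 43)
  h2 <- mean(unclass(rg2) == "H")
  expect_lt(abs(h2 - 0.25), 3 * sqrt(0.25 * 0.75 / 3000))
  expect_error(simulate_ril_population(gm, 1, 5), "n_lines")
  expect_error(simulate_ril_population(gm, 10, 11), "derived_generation")
})

test_that("simulators are reproducible by seed and differ across seeds", {
  gm <- test_map(2)
  a <- simulate_ril_population(gm, 30, 5, seed = 7)
  b <- simulate_ril_population(gm, 30, 5, seed = 7)
  c <- simulate_ril_population(gm, 30, 5, seed = 8)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(c)))
  p1 <- simulate_panel(20, gm, snp_density = 50, seed = 5)
  p2 <- simulate_panel(20, gm, snp_density = 50, seed = 5)
  expect_identical(p1$calls, p2$calls)
})

test_that("pairwise recombination follows the RIL expectation and an independent oracle", {
  # near-complete inbreeding: observed R ~ 2r/(1+2r)
  for (d in c(1, 5, 10, 20, 50)) {
    gm <- genetic_map(c("L", "R"), "C01", c(0, d))
    rg <- simulate_ril_population(gm, 3000, 10, seed = 100 + d)
    C <- matrix(match(unclass(rg), c("A", "H", "B")), 3000)
    hom <- C[, 1] != 2 & C[, 2] != 2
    Rhat <- mean(C[hom, 1] != C[hom, 2])
    r <- 0.5 * (1 - exp(-2 * d / 100))
    Rexp <- 2 * r / (1 + 2 * r)
    se <- sqrt(Rexp * (1 - Rexp) / sum(hom))
    expect_lt(abs(Rhat - Rexp), 4 * se + 0.005)
  }
  # residually heterozygous F5: compare against the Monte-Carlo SSD oracle,
  # which recombines per interval rather than by crossover placement
  d <- 20
  gm <- genetic_map(c("L", "R"), "C01", c(0, d))
  rg <- simulate_ril_population(gm, 6000, 5, seed = 21)
  C <- matrix(match(unclass(rg), c("A", "H", "B")), 6000)
  hom <- C[, 1] != 2 & C[, 2] != 2
  Rhat <- mean(C[hom, 1] != C[hom, 2])
  set.seed(22)
  O <- oracle_ssd(6000, 0.5 * (1 - exp(-2 * d / 100)), 5)
  ohom <- O[, 1] != 2 & O[, 2] != 2
  Rora <- mean(O[ohom, 1] != O[ohom, 2])
  se <- sqrt(2 * Rora * (1 - Rora) / sum(ohom))
  expect_lt(abs(Rhat - Rora), 4 * se)
})

test_that("panel injection realizes the requested rare-allele frequency", {
  gm <- test_map(3)
  pan <- simulate_panel(300, gm, snp_density = 100,
                        donor_rare_config = list(n_rare = 100,
                                                 rare_frequency = 1 / 300),
                        seed = 31)
  expect_equal(dim(pan$calls), c(300, 3 * 100 + 100))
  rare <- attr(pan, "rare_snps")
  expect_length(rare, 100)
  j <- match(rare, pan$snp_info$id)
  # at f = 1/300 the donor is the sole carrier at every injected SNP
  expect_true(all(pan$calls["Donor", j] == 2L))
  expect_true(all(colSums(pan$calls[-1, j] > 0, na.rm = TRUE) == 0))
  # at f = 5/300, carrier count is 1 (donor) + Binomial(299, q); check the
  # mean against the closed-form expectation within 4 SEs
  pan5 <- simulate_panel(300, gm, snp_density = 50,
                         donor_rare_config = list(n_rare = 200,
                                                  rare_frequency = 5 / 300),
                         seed = 32)
  j5 <- match(attr(pan5, "rare_snps"), pan5$snp_info$id)
  carriers <- colSums(pan5$calls[, j5] == 2L, na.rm = TRUE)
  q <- (5 - 1) / 299
  se <- sqrt(299 * q * (1 - q) / 200)
  expect_lt(abs(mean(carriers) - 5), 4 * se)
  # validation
  expect_error(simulate_panel(5, gm), "n_lines")
  expect_error(
    simulate_panel(100, gm,
                   donor_rare_config = list(n_rare = 5,
                                            rare_frequency = 1 / 300)),
    "less than one line")
  p0 <- simulate_panel(20, gm, snp_density = 30,
                       donor_rare_config = list(n_rare = 0), seed = 3)
  expect_length(attr(p0, "rare_snps"), 0)
  expect_equal(ncol(p0$calls), 90)
})

test_that("pedigree descent forces retained blocks and is neutral elsewhere", {
  gm <- test_map(3)
  pan <- simulate_panel(60, gm, snp_density = 150,
                        donor_rare_config = list(n_rare = 40,
                                                 rare_frequency = 1 / 60),
                        seed = 41)
  derivs <- sprintf("D%02d", 1:7)
  ped <- pedigree(nodes = c("Donor", "V002", derivs),
                  parents = stats::setNames(
                    rep(list(c("Donor", "V002")), 7), derivs),
                  donor = "Donor", recurrent_parent = "V002",
                  derivatives = derivs)
  blocks <- data.frame(chrom = "C01", start = 1, end = 5e6)
  out <- simulate_descent(pan, ped, blocks, 0.3, seed = 42)
  expect_equal(nrow(out$calls), 60 + 7)
  expect_setequal(out$roles$derivatives, derivs)
  inb <- out$snp_info$chrom == "C01" & out$snp_info$bp <= 5e6
  for (d in derivs)
    expect_identical(out$calls[d, inb], out$calls["Donor", inb])
  # original panel genotypes (and hence panel allele frequencies) untouched
  expect_identical(out$calls[rownames(pan$calls), ], pan$calls)
  # whole-genome retention: derivatives identical to the donor
  whole <- data.frame(chrom = attr(gm, "chromosomes"), start = 1, end = 1e9)
  all_don <- simulate_descent(pan, ped, whole, 0, seed = 43)
  for (d in derivs)
    expect_identical(all_don$calls[d, ], all_don$calls["Donor", ])
  expect_error(simulate_descent(pan, ped,
                                data.frame(chrom = "C99", start = 1, end = 2)),
               "unknown chromosome")
  # retention probability 0.5: mean donor-origin fraction outside blocks
  many <- sprintf("E%03d", 1:300)
  ped2 <- pedigree(nodes = c("Donor", "V002", many),
                   parents = stats::setNames(
                     rep(list(c("Donor", "V002")), 300), many),
                   donor = "Donor", recurrent_parent = "V002",
                   derivatives = many)
  out2 <- simulate_descent(pan, ped2, NULL, 0.5, seed = 44)
  # score donor origin at SNPs where donor and recurrent parent differ
  diffsnp <- which(pan$calls["Donor", ] != pan$calls["V002", ])
  frac <- mean(out2$calls[many, diffsnp] ==
                 matrix(pan$calls["Donor", diffsnp], 300, length(diffsnp),
                        byrow = TRUE))
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("phenotype simulator realizes target variance fractions", {
  gm <- test_map(2, len = 80, by = 10)
  rg <- simulate_ril_population(gm, 2000, 5, seed = 51)
  m <- qtl_model(data.frame(chrom = "C01", pos_cM = 40),
                 target_variance_fractions = 0.5)
  ph <- simulate_phenotypes(rg, m, seed = 52)
  y <- line_means(ph)
  x <- protmap:::marker_dosage(rg, "C01", 40)
  r2 <- cor(x, y)^2
  expect_lt(abs(r2 - 0.5), 0.04)
  # closed form: R2 = a^2 var(x) / (a^2 var(x) + sigma_m^2)
  a <- attr(ph, "effects")$additive
  expect_equal(unname(a^2 * var(x) / (a^2 * var(x) + m$residual_sd^2 / 3)),
               0.5, tolerance = 1e-10)
  # null model: line-mean variance is the residual line-mean variance only
  m0 <- qtl_model(data.frame(chrom = character(), pos_cM = numeric()))
  ph0 <- simulate_phenotypes(rg, m0, seed = 53)
  v0 <- var(line_means(ph0))
  expect_lt(abs(v0 - m0$residual_sd^2 / 3), 0.15 * m0$residual_sd^2 / 3)
  # infeasible fractions are rejected
  expect_error(qtl_model(data.frame(chrom = c("C01", "C02"),
                                    pos_cM = c(0, 0)),
                         target_variance_fractions = c(0.7, 0.6)),
               "> 1")
  # protein means sit on the percent scale around the population mean
  expect_lt(abs(mean(y) - 44), 1)
  expect_true(all(ph$protein > 0 & ph$protein < 100))
})
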