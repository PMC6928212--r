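test_that("genotype probabilities give point masses, priors and coherent vectors", {
  gm <- genetic_map(c("L", "M", "R"), "C01", c(0, 10, 30))
  rg <- simulate_ril_population(gm, 40, 5, seed = 1)
  gp <- genotype_probabilities(rg, step_cM = 5)
  # observed marker positions are point masses
  i10 <- which(gp$grid$pos_cM == 10)
  codes <- match(unclass(rg)[, "M"], c("A", "H", "B"))
  for (l in 1:40)
    expect_equal(gp$probs[l, i10, ], as.numeric(1:3 == codes[l]))
  # all probability vectors sum to 1
  expect_equal(rowSums(gp$probs[, 5, ]), rep(1, 40))
  # a fully missing line falls back to the generation prior
  gmiss <- unclass(rg)
  gmiss[3, ] <- NA
  rg2 <- ril_geno(gmiss, gm, 5)
  gp2 <- genotype_probabilities(rg2, step_cM = 5)
  h <- 0.5^4
  expect_equal(gp2$probs[3, i10, ], c((1 - h) / 2, h, (1 - h) / 2))
  expect_equal(gp2$dosage[3, i10], 0)
  expect_error(genotype_probabilities(rg, step_cM = 0), "step_cM")
})

test_that("midpoint conditional probabilities match the Monte-Carlo SSD oracle", {
  # 20 cM interval, grid point in the middle, F5: the package computes the
  # conditional exactly; the oracle estimates it from 150k simulated lines
  r10 <- 0.5 * (1 - exp(-2 * 10 / 100))
  set.seed(99)
  O <- oracle_ssd(150000, c(r10, r10), 5)
  tab <- protmap:::cond_table(10, 10, 5)
  for (a in c(1, 3)) for (b in c(1, 3)) {
    sel <- O[, 1] == a & O[, 3] == b
    emp <- tabulate(O[sel, 2], 3) / sum(sel)
    expect_lt(max(abs(tab[a, b, ] - emp)), 0.015)
  }
  # one-sided table against the oracle too
  tab1 <- protmap:::cond_table(10, NA, 5)
  sel <- O[, 1] == 1
  emp <- tabulate(O[sel, 2], 3) / sum(sel)
  expect_lt(max(abs(tab1[1, ] - emp)), 0.01)
})

test_that("TS at informative markers reduces to single-marker regression", {
  d <- sim_one_qtl(seed = 3)
  sc <- qtl_scan(d$geno, d$y, step_cM = 1)
  map <- attr(d$geno, "map")
  n <- length(d$y)
  for (mk in c("C01_m4", "C03_m2")) {
    i <- which(map$marker == mk)
    x <- match(unclass(d$geno)[, i], c("A", "H", "B")) - 2
    fit <- lm(d$y ~ x)
    ts_lm <- n * log(sum((d$y - mean(d$y))^2) / sum(residuals(fit)^2))
    j <- which(sc$chrom == map$chrom[i] & sc$pos_cM == map$pos_cM[i])
    expect_equal(sc$ts[j], ts_lm, tolerance = 1e-8)
  }
})

test_that("scan is affine-invariant, sCIM with no cofactors equals SIM, and degenerate input warns", {
  d <- sim_one_qtl(seed = 4)
  s1 <- qtl_scan(d$geno, d$y)
  s2 <- qtl_scan(d$geno, 3.7 * d$y + 11)
  expect_equal(s1$ts, s2$ts, tolerance = 1e-10)
  s3 <- qtl_scan(d$geno, d$y, mode = "sCIM", cofactors = character(0))
  expect_equal(s1$ts, s3$ts)
  # sCIM with cofactors runs and suppresses the cofactor's own neighborhood
  s4 <- qtl_scan(d$geno, d$y, mode = "sCIM", cofactors = "auto")
  expect_equal(nrow(s4), nrow(s1))
  expect_true(all(s4$ts >= 0))
  yc <- rep(5, length(d$y))
  names(yc) <- names(d$y)
  expect_warning(s0 <- qtl_scan(d$geno, yc), "constant")
  expect_true(all(s0$ts == 0))
})

test_that("permutation threshold is the documented order statistic and is monotone in alpha", {
  d <- sim_one_qtl(n = 60, seed = 5)
  t05 <- permutation_threshold(d$geno, d$y, n_permutations = 200,
                               alpha = 0.05, seed = 9)
  null_max <- attr(t05, "null_max")
  expect_equal(as.numeric(t05), sort(null_max)[ceiling(0.95 * 200)])
  t01 <- permutation_threshold(d$geno, d$y, n_permutations = 200,
                               alpha = 0.01, seed = 9)
  expect_identical(attr(t01, "null_max"), null_max)  # same draws
  expect_gte(as.numeric(t01), as.numeric(t05))
  t1 <- permutation_threshold(d$geno, d$y, n_permutations = 200,
                              alpha = 1, seed = 9)
  expect_equal(as.numeric(t1), min(null_max))
  expect_error(permutation_threshold(d$geno, d$y, n_permutations = 50),
               "n_permutations")
  small <- d$geno[1:15, ]
  expect_warning(permutation_threshold(small, d$y[1:15],
                                       n_permutations = 100, seed = 1),
                 "unstable")
})

test_that("a major QTL is declared on the right chromosome and R2 matches its truth", {
  d <- sim_one_qtl(frac = 0.6, seed = 6)
  thr <- permutation_threshold(d$geno, d$y, n_permutations = 500, seed = 7)
  sc <- qtl_scan(d$geno, d$y, threshold = as.numeric(thr))
  pk <- attr(sc, "peaks")
  expect_gte(nrow(pk), 1)
  expect_equal(pk$chrom[which.max(pk$ts)], "C01")
  expect_lt(abs(pk$r2[which.max(pk$ts)] - 0.6), 0.2)
  # R2 equals the squared correlation with the dosage (algebraic identity)
  x <- protmap:::marker_dosage(d$geno, "C01", 30)
  expect_equal(variance_explained(d$geno, d$y, "C01", 30),
               unname(cor(x, d$y)^2), tolerance = 1e-10)
  # orthogonal noise explains ~nothing
  set.seed(8)
  ynoise <- stats::setNames(rnorm(length(d$y)), names(d$y))
  expect_lt(variance_explained(d$geno, ynoise, "C01", 30), 0.1)
})

test_that("anchored re-scan separates additive from epistatic signal", {
  map <- test_map(4, len = 80, by = 10)
  rg <- simulate_ril_population(map, 200, 5, seed = 11)
  # pure interaction between C02 and the anchor QTL on C01
  m <- qtl_model(data.frame(chrom = c("C01", "C02"), pos_cM = c(40, 40)),
                 epistatic_pairs = data.frame(locus_i = 2, locus_j = 1,
                                              target_variance_fraction = 0.12),
                 target_variance_fractions = c(0.5, 0))
  ph <- simulate_phenotypes(rg, m, seed = 12)
  y <- line_means(ph)
  an <- anchored_scan(rg, y, list(chrom = "C01", pos_cM = 40))
  expect_true(all(is.na(an$ts_add[an$chrom == "C01" &
                                    abs(an$pos_cM - 40) <= 20])))
  ipk <- which.max(an$ts_int)
  expect_equal(an$chrom[ipk], "C02")
  expect_lt(abs(an$pos_cM[ipk] - 40), 15)
  # no epistasis in truth: the interaction profile stays well below the
  # epistatic signal
  m0 <- qtl_model(data.frame(chrom = c("C01", "C02"), pos_cM = c(40, 40)),
                  target_variance_fractions = c(0.5, 0.1))
  ph0 <- simulate_phenotypes(rg, m0, seed = 13)
  an0 <- anchored_scan(rg, line_means(ph0), list(chrom = "C01", pos_cM = 40))
  expect_lt(max(an0$ts_int, na.rm = TRUE), an$ts_int[ipk] / 2)
  # additive TS at an unlinked second QTL ~ its unanchored TS; with small
  # orthogonal effects the two statistics approach each other (conditioning
  # on a strong anchor would legitimately sharpen the anchored one)
  msm <- qtl_model(data.frame(chrom = c("C01", "C02"), pos_cM = c(40, 40)),
                   target_variance_fractions = c(0.15, 0.15))
  phs <- simulate_phenotypes(rg, msm, seed = 14)
  ys <- line_means(phs)
  ans <- anchored_scan(rg, ys, list(chrom = "C01", pos_cM = 40))
  scs <- qtl_scan(rg, ys)
  i2 <- which(ans$chrom == "C02")
  j <- i2[which.max(ans$ts_add[i2])]
  k <- which(scs$chrom == "C02" & scs$pos_cM == ans$pos_cM[j])
  expect_lt(abs(ans$ts_add[j] - scs$ts[k]) / scs$ts[k], 0.35)
  expect_equal(scs$chrom[which.max(scs$ts)], "C01")
  # constant anchor dosage is rejected
  gmono <- unclass(rg)
  gmono[, ] <- "A"
  expect_error(anchored_scan(ril_geno(gmono, map, 5), y,
                             list(chrom = "C01", pos_cM = 40)),
               "constant")
})

test_that("peak position recovery is accurate for a major QTL", {
  map <- test_map(5, len = 100, by = 10)
  err <- vapply(1:60, function(r) {
    d <- sim_one_qtl(map, n = 100, frac = 0.6, seed = 500 + r,
                     chrom = "C01", pos = 50)
    sc <- qtl_scan(d$geno, d$y, step_cM = 2)
    i <- which.max(sc$ts)
    if (sc$chrom[i] != "C01") return(Inf)
    abs(sc$pos_cM[i] - 50)
  }, numeric(1))
  expect_lte(median(err), 5)
})
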