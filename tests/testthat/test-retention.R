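test_that("rare-allele scan returns the injected SNPs and respects focal zygosity", {
  fx <- retention_fixture()
  pan <- fx$panel
  cand <- rare_allele_scan(pan, "Donor", 0.02, exclude = fx$derivs)
  expect_setequal(cand$id, attr(pan, "rare_snps"))
  expect_true(all(cand$panel_freq <= 0.02))
  # an impossible threshold returns nothing (the focal line itself counts)
  expect_equal(nrow(rare_allele_scan(pan, "Donor", 0)), 0)
  # a heterozygous focal call is skipped regardless of frequency
  pan2 <- pan
  j <- match(cand$id[1], pan2$snp_info$id)
  pan2$calls["Donor", j] <- 1L
  cand2 <- rare_allele_scan(pan2, "Donor", 0.02, exclude = fx$derivs)
  expect_false(cand$id[1] %in% cand2$id)
  expect_error(rare_allele_scan(pan, "NoSuchLine"), "not in panel")
})

test_that("contrast filter drops recurrent-parent carriers and flags missing", {
  fx <- retention_fixture()
  pan <- fx$panel
  cand <- rare_allele_scan(pan, "Donor", 0.02, exclude = fx$derivs)
  filt <- contrast_filter(cand, pan, "V002", c("V003", "V004"))
  # sole-carrier injection: the recurrent parent never carries the allele
  expect_setequal(filt$id, cand$id)
  # force the recurrent parent to carry one SNP: it must drop
  pan3 <- pan
  j <- match(cand$id[1], pan3$snp_info$id)
  pan3$calls["V002", j] <- 2L
  f3 <- contrast_filter(cand, pan3, "V002")
  expect_false(cand$id[1] %in% f3$id)
  # a missing recurrent call keeps the SNP but flags it non-informative
  pan4 <- pan
  pan4$calls["V002", j] <- NA
  f4 <- contrast_filter(cand, pan4, "V002")
  expect_true(cand$id[1] %in% f4$id)
  expect_false(f4$recurrent_informative[f4$id == cand$id[1]])
})

test_that("retention ratio arithmetic, informative denominator and nesting", {
  gm <- genetic_map(paste0("M", 1:3), "C01", c(0, 1, 2), bp = c(1e5, 2e5, 3e5))
  # 1 donor + 1 recurrent + 7 derivatives; 3 SNPs with 5, 4, 7 carriers
  calls <- matrix(0L, 9, 3,
                  dimnames = list(c("Donor", "Rec", sprintf("D%d", 1:7)),
                                  NULL))
  calls["Donor", ] <- 2L
  calls[sprintf("D%d", 1:5), 1] <- 2L
  calls[sprintf("D%d", 1:4), 2] <- 2L
  calls[sprintf("D%d", 1:7), 3] <- 2L
  info <- data.frame(id = paste0("S", 1:3), chrom = "C01",
                     bp = c(1e5, 2e5, 3e5), ref = "A", alt = "T")
  pan <- panel_geno(calls, info)
  cand <- rare_allele_scan(pan, "Donor", 0.5, exclude = sprintf("D%d", 1:7))
  rec <- retention_filter(cand, pan, sprintf("D%d", 1:7), min_ratio = 0.66)
  expect_setequal(rec$id, c("S1", "S3"))           # 5/7 = 0.714 and 7/7
  expect_equal(rec$rho[rec$id == "S1"], 5 / 7)
  strict <- retention_filter(cand, pan, sprintf("D%d", 1:7), min_ratio = 1)
  expect_equal(strict$id, "S3")                     # 4/7 = 0.571 dropped
  expect_true(all(strict$id %in% rec$id))
  # heterozygous derivatives are not carriers and not informative by default
  calls2 <- calls
  calls2["D6", 1] <- 1L
  pan2 <- panel_geno(calls2, info)
  r2 <- retention_filter(rare_allele_scan(pan2, "Donor", 0.5,
                                          exclude = sprintf("D%d", 1:7)),
                         pan2, sprintf("D%d", 1:7), min_ratio = 0.66)
  expect_equal(r2$informative[r2$id == "S1"], 6)
  expect_equal(r2$rho[r2$id == "S1"], 5 / 6)
  # nesting on random panels: strict results are a subset of broad results
  for (s in 1:5) {
    fx <- retention_fixture(seed = 200 + s, n_lines = 40, snp_density = 80,
                            n_rare = 30)
    cand <- rare_allele_scan(fx$panel, "Donor", 0.02, exclude = fx$derivs)
    b <- retention_filter(cand, fx$panel, fx$derivs, 0.66)
    st <- retention_filter(cand, fx$panel, fx$derivs, 1)
    expect_true(all(st$id %in% b$id))
  }
  expect_error(retention_filter(cand, pan, sprintf("D%d", 1:7), 0), "min_ratio")
})

test_that("blocks assemble by physical gap and partition every SNP", {
  rec <- data.frame(id = c("a", "b", "c"), chrom = "C01",
                    bp = c(1e5, 2e5, 5e6), focal_allele = "alt",
                    panel_freq = 0, rho = 1)
  blk <- build_blocks(rec, max_gap_bp = 1e6, min_snps = 2)
  expect_equal(nrow(blk), 1)
  expect_equal(c(blk$start, blk$end), c(1e5, 2e5))
  sing <- attr(blk, "singletons")
  expect_equal(sing$start, 5e6)
  # random partition property vs the brute-force clustering oracle
  set.seed(33)
  for (rep in 1:5) {
    bp <- sort(sample.int(2e7, 40))
    rec <- data.frame(id = paste0("s", seq_along(bp)), chrom = "C01",
                      bp = bp, focal_allele = "alt", panel_freq = 0, rho = 1)
    blk <- build_blocks(rec, max_gap_bp = 5e5, min_snps = 2)
    clus <- oracle_cluster(bp, 5e5)
    expect_equal(nrow(blk) + nrow(attr(blk, "singletons")), length(clus))
    n_in <- sum(blk$n_snps) + sum(attr(blk, "singletons")$n_snps)
    expect_equal(n_in, length(bp))
  }
})

test_that("annotation links anchors within distance and is monotone in it", {
  blk <- data.frame(chrom = "Gm01", start = 49056999, end = 49869514,
                    n_snps = 5, mean_rho = 1, snp_ids = "x")
  anchors <- data.frame(name = c("Satt077", "SattFar"),
                        chrom = "Gm01", bp = c(49500000, 60000000))
  known <- data.frame(name = "protein-QTL", chrom = "Gm01",
                      start = 48000000, end = 50000000)
  a <- annotate_blocks(blk, anchors, known, link_distance_bp = 5e5)
  expect_equal(a$anchors, "Satt077")
  expect_equal(a$known, "protein-QTL")
  expect_false(a$novel)
  a0 <- annotate_blocks(blk, NULL, NULL)
  expect_true(a0$novel)
  hits <- vapply(c(0, 5e5, 2e7), function(ld)
    nchar(annotate_blocks(blk, anchors, NULL, ld)$anchors), numeric(1))
  expect_true(all(diff(hits) >= 0))
})

test_that("the full retention scan recovers injected blocks end to end", {
  fx <- retention_fixture(seed = 77, n_lines = 120, snp_density = 400,
                          n_rare = 80)
  pan <- fx$panel
  cand <- rare_allele_scan(pan, "Donor", 0.02, exclude = fx$derivs)
  filt <- contrast_filter(cand, pan, "V002", c("V003", "V004"))
  rec <- retention_filter(filt, pan, fx$derivs, min_ratio = 1)
  blk <- build_blocks(rec, max_gap_bp = 5e5, min_snps = 2)
  # every injected block recovered with >= 90% span overlap
  for (i in seq_len(nrow(fx$truth))) {
    tb <- fx$truth[i, ]
    ov <- blk$chrom == tb$chrom & blk$start <= tb$end & blk$end >= tb$start
    expect_true(any(ov))
    cover <- sum(pmin(blk$end[ov], tb$end) - pmax(blk$start[ov], tb$start)) /
      (tb$end - tb$start)
    expect_gte(cover, 0.9)
  }
  # false-discovery proportion among reported blocks <= 0.1
  is_false <- vapply(seq_len(nrow(blk)), function(i)
    !any(fx$truth$chrom == blk$chrom[i] & fx$truth$start <= blk$end[i] &
           fx$truth$end >= blk$start[i]), logical(1))
  expect_lte(mean(is_false), 0.1)
})
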