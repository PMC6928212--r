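# Replicate simulation studies for parameter recovery: simulate RIL
# populations at the published per-locus variance contributions, scan them
# and measure how well the variance explained is recovered.

# Middle marker of a chromosome (causal loci sit at markers).
.mid_marker <- function(map, chrom) {
  mi <- which(map$chrom == chrom)
  mi[ceiling(length(mi) / 2)]
}

#' Variance-explained recovery study
#'
#' Simulates replicate F5-derived RIL populations (default n = 100 lines on
#' the 20-chromosome framework map) under one of three QTL architectures and
#' records, per replicate, the variance explained recovered by the genome
#' scan:
#'
#' * `"single"` — one chromosome-20 locus at a 60% variance fraction; records
#'   the R^2 at the genome-wide peak (`r2_peak`).
#' * `"two"` — chromosome-20 and -15 loci at 60% and 23%; records the peak
#'   R^2 and the R^2 at the chromosome-15 maximum (`r2_gm15`).
#' * `"five"` — the five-locus architecture (chromosomes 20, 15, 1, 16 plus
#'   a chromosome 5 x 20 epistatic pair) with per-locus shares proportional
#'   to 60:23:14:13:1 and jointly scaled so the full model explains 70% of
#'   the line-mean variance; records marginal R^2 at the causal markers
#'   (`r2_gm20`, `r2_gm15`, `r2_gm01`, `r2_gm16`) and the joint R^2 of
#'   the five causal dosages including the interaction (`r2_joint`).
#'
#' @param design `"single"`, `"two"` or `"five"`.
#' @param n_reps number of replicate populations (default 200).
#' @param n_lines lines per population (default 100).
#' @param seed integer seed; replicate seeds are derived from it.
#' @param map genetic map (default [x4050_map_skeleton()]).
#' @param step_cM scan grid step (default 1).
#' @return A data frame with one row per replicate and the columns listed
#'   above, plus attribute `truth` (the simulated variance fractions).
#' @export
variance_recovery_study <- function(design = c("single", "two", "five"),
                                    n_reps = 200, n_lines = 100, seed = 1,
                                    map = x4050_map_skeleton(),
                                    step_cM = 1) {
  design <- match.arg(design)
  chr5 <- c("Gm20", "Gm15", "Gm01", "Gm16", "Gm05")
  mid <- vapply(chr5, function(cc) .mid_marker(map, cc), integer(1))
  pos <- map$pos_cM[mid]
  names(pos) <- chr5
  if (design == "single") {
    loci <- data.frame(chrom = "Gm20", pos_cM = pos[["Gm20"]])
    tv <- 0.60
    ep <- NULL
    truth <- c(Gm20 = 0.60)
  } else if (design == "two") {
    loci <- data.frame(chrom = c("Gm20", "Gm15"),
                       pos_cM = pos[c("Gm20", "Gm15")])
    tv <- c(0.60, 0.23)
    ep <- NULL
    truth <- c(Gm20 = 0.60, Gm15 = 0.23)
  } else {
    shares <- 0.70 * c(60, 23, 14, 13, 1) / sum(c(60, 23, 14, 13, 1))
    loci <- data.frame(chrom = chr5, pos_cM = pos)
    tv <- c(shares[1:4], 0)
    ep <- data.frame(locus_i = 5, locus_j = 1,
                     target_variance_fraction = shares[5])
    truth <- c(Gm20 = shares[1], Gm15 = shares[2], Gm01 = shares[3],
               Gm16 = shares[4], Gm05xGm20 = shares[5], joint = 0.70)
  }
  model <- qtl_model(loci, epistatic_pairs = ep,
                     target_variance_fractions = tv)
  seeds <- derive_seeds(seed, 2 * n_reps)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rg <- simulate_ril_population(map, n_lines, 5, seed = seeds[2 * r - 1])
    ph <- simulate_phenotypes(rg, model, seed = seeds[2 * r])
    y <- line_means(ph)
    sc <- qtl_scan(rg, y, step_cM = step_cM)
    ipk <- which.max(sc$ts)
    out <- list(peak_chrom = sc$chrom[ipk], peak_pos = sc$pos_cM[ipk],
                r2_peak = variance_explained(rg, y, sc$chrom[ipk],
                                             sc$pos_cM[ipk]))
    if (design == "two") {
      i15 <- which(sc$chrom == "Gm15")
      j <- i15[which.max(sc$ts[i15])]
      out$r2_gm15 <- variance_explained(rg, y, "Gm15", sc$pos_cM[j])
    }
    if (design == "five") {
      X <- vapply(chr5, function(cc)
        marker_dosage(rg, cc, pos[[cc]]), numeric(n_lines))
      for (cc in c("Gm20", "Gm15", "Gm01", "Gm16"))
        out[[paste0("r2_", tolower(cc))]] <-
          unname(stats::cor(X[, cc], y)^2)
      fit <- stats::lm(y ~ X[, "Gm20"] + X[, "Gm15"] + X[, "Gm01"] +
                         X[, "Gm16"] + X[, "Gm05"] +
                         X[, "Gm05"]:X[, "Gm20"])
      out$r2_joint <- summary(fit)$r.squared
    }
    rows[[r]] <- as.data.frame(out, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  structure(res, truth = truth, design = design)
}
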