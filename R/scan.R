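# Genome scan for trait loci on RIL line means.
#
# The test statistic is a likelihood-ratio-type quantity from Haley-Knott
# regression of line means on expected genotype dosage:
#     TS(position) = n * ln(RSS0 / RSS1),
# where RSS1 comes from the model with the tested dosage (plus any cofactor
# dosages) and RSS0 from the same model without it. Its scale is immaterial
# for QTL declaration because the genome-wide threshold is obtained by
# permutation of the same statistic.

.align_pheno <- function(genotypes, phenotypes) {
  y <- if (is.data.frame(phenotypes)) line_means(phenotypes) else phenotypes
  if (is.null(names(y))) {
    if (length(y) != nrow(genotypes))
      stop_protmap("unnamed phenotypes must match genotype lines")
    names(y) <- rownames(genotypes)
  }
  miss <- setdiff(names(y), rownames(genotypes))
  if (length(miss))
    stop_protmap("phenotype lines absent from genotypes: ",
                 paste(utils::head(miss, 5), collapse = ", "))
  y[rownames(genotypes)[rownames(genotypes) %in% names(y)]]
}

.ts_profile_sim <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  Syy <- sum(yc^2)
  if (Syy <= 0) return(rep(0, ncol(X)))
  Xc <- sweep(X, 2, colMeans(X))
  Sxx <- colSums(Xc^2)
  Sxy <- as.vector(crossprod(Xc, yc))
  rss1 <- Syy - ifelse(Sxx > 1e-12, Sxy^2 / Sxx, 0)
  n * log(Syy / pmax(rss1, 1e-12))
}

# Automatic sCIM cofactor choice: the strongest marginally associated marker
# in each ~window_cM span of the map.
.auto_cofactors <- function(genotypes, y, window_cM = 30) {
  map <- attr(genotypes, "map")
  C <- code_to_int(unclass(genotypes)) - 2
  r2 <- apply(C, 2, function(x) {
    ok <- !is.na(x)
    if (stats::sd(x[ok]) == 0) return(0)
    stats::cor(x[ok], y[ok])^2
  })
  picks <- character(0)
  for (cc in attr(map, "chromosomes")) {
    mi <- which(map$chrom == cc)
    bins <- floor(map$pos_cM[mi] / window_cM)
    for (b in unique(bins)) {
      j <- mi[bins == b]
      picks <- c(picks, map$marker[j[which.max(r2[j])]])
    }
  }
  picks
}

#' Genome scan (simple / simplified composite interval mapping)
#'
#' Scans a cM grid for association between line means and expected genotype
#' dosage. `mode = "SIM"` tests each position alone; `mode = "sCIM"` adds
#' background cofactor markers to both the null and the full model, dropping
#' cofactors within `cofactor_window_cM` of the tested position. With an
#' empty cofactor set, sCIM reduces to SIM point by point.
#'
#' @param genotypes a [ril_geno()].
#' @param phenotypes line means (named numeric) or a `phenotype_records`
#'   data frame (aggregated by [line_means()]).
#' @param mode `"SIM"` or `"sCIM"`.
#' @param cofactors for sCIM: character vector of marker names, `"auto"`
#'   (one per ~30 cM chosen by strongest marginal association), or `NULL`.
#' @param step_cM grid step (default 1).
#' @param threshold optional genome-wide threshold (from
#'   [permutation_threshold()]); peaks are declared above it.
#' @param cofactor_window_cM half-width of the cofactor exclusion window
#'   around the tested position (default 20).
#' @return A `qtl_scan` object: data frame `grid` (chrom, pos_cM, ts) with
#'   attributes `threshold`, `peaks` (position, nearest marker, TS, R2),
#'   `mode`, `alpha`, `n_perm`.
#' @examples
#' gm <- genetic_map(paste0("M", 1:6), "Gm01", seq(0, 100, 20))
#' rg <- simulate_ril_population(gm, 60, seed = 1)
#' m <- qtl_model(data.frame(chrom = "Gm01", pos_cM = 40),
#'                target_variance_fractions = 0.5)
#' ph <- simulate_phenotypes(rg, m, seed = 2)
#' sc <- qtl_scan(rg, ph)
#' @export
qtl_scan <- function(genotypes, phenotypes, mode = c("SIM", "sCIM"),
                     cofactors = NULL, step_cM = 1, threshold = NULL,
                     cofactor_window_cM = 20) {
  mode <- match.arg(mode)
  y <- .align_pheno(genotypes, phenotypes)
  genotypes <- genotypes[names(y), ]
  core <- .genoprob_core(genotypes, step_cM)
  X <- core$dosage
  grid <- core$grid
  map <- attr(genotypes, "map")
  if (stats::sd(y) == 0) {
    warning("constant phenotype: all test statistics are zero")
    ts <- rep(0, nrow(grid))
  } else if (mode == "SIM" || is.null(cofactors) || !length(cofactors)) {
    ts <- .ts_profile_sim(X, y)
  } else {
    if (identical(cofactors, "auto"))
      cofactors <- .auto_cofactors(genotypes, y)
    bad <- setdiff(cofactors, map$marker)
    if (length(bad)) stop_protmap("unknown cofactor marker(s): ",
                                  paste(bad, collapse = ", "))
    ci <- match(cofactors, map$marker)
    Z_all <- code_to_int(unclass(genotypes))[, ci, drop = FALSE] - 2
    Z_all[is.na(Z_all)] <- 0
    # drop collinear cofactors once, globally
    qz <- qr(cbind(1, Z_all))
    if (qz$rank < ncol(Z_all) + 1) {
      keep <- (qz$pivot[seq_len(qz$rank)] - 1)[-1]
      keep <- keep[keep > 0]
      warning("dropping ", ncol(Z_all) - length(keep),
              " collinear cofactor(s)")
      ci <- ci[keep]
      Z_all <- Z_all[, keep, drop = FALSE]
    }
    ts <- vapply(seq_len(nrow(grid)), function(i) {
      use <- !(map$chrom[ci] == grid$chrom[i] &
                 abs(map$pos_cM[ci] - grid$pos_cM[i]) <= cofactor_window_cM)
      Z0 <- cbind(rep(1, length(y)), Z_all[, use, drop = FALSE])
      r0 <- stats::lm.fit(Z0, y)$residuals
      r1 <- stats::lm.fit(cbind(Z0, X[, i]), y)$residuals
      rss0 <- sum(r0^2); rss1 <- sum(r1^2)
      length(y) * log(max(rss0, 1e-12) / max(rss1, 1e-12))
    }, numeric(1))
  }
  ts <- pmax(ts, 0)
  res <- data.frame(chrom = grid$chrom, pos_cM = grid$pos_cM, ts = ts)
  peaks <- if (!is.null(threshold))
    find_peaks(res, threshold, genotypes, y) else NULL
  structure(res, threshold = threshold, peaks = peaks, mode = mode,
            class = c("qtl_scan", "data.frame"))
}

# Peak calling: one peak per chromosome unless the profile dips below the
# threshold between local maxima, or a shoulder is separated by a dip of at
# least `dip` (25%) of the lower of the two maxima.
find_peaks <- function(res, threshold, genotypes = NULL, y = NULL,
                       dip = 0.25) {
  out <- list()
  for (cc in unique(res$chrom)) {
    ts <- res$ts[res$chrom == cc]
    pos <- res$pos_cM[res$chrom == cc]
    n <- length(ts)
    if (max(ts) < threshold) next
    lmax <- which(diff(c(-Inf, ts)) >= 0 & diff(c(ts, -Inf)) <= 0 &
                    ts >= threshold)
    # prune maxima pairwise by the dip rule
    repeat {
      if (length(lmax) <= 1) break
      drop <- integer(0)
      for (j in seq_len(length(lmax) - 1)) {
        a <- lmax[j]; b <- lmax[j + 1]
        valley <- min(ts[a:b])
        if (valley < threshold) next
        if (valley <= (1 - dip) * min(ts[a], ts[b])) next
        drop <- c(drop, if (ts[a] <= ts[b]) j else j + 1)
      }
      if (!length(drop)) break
      lmax <- lmax[-unique(drop)[1]]
    }
    for (i in lmax) {
      r2 <- if (!is.null(genotypes))
        variance_explained(genotypes, y, cc, pos[i]) else NA_real_
      map <- if (!is.null(genotypes)) attr(genotypes, "map") else NULL
      nearest <- if (!is.null(map)) {
        mi <- which(map$chrom == cc)
        map$marker[mi[which.min(abs(map$pos_cM[mi] - pos[i]))]]
      } else NA_character_
      out[[length(out) + 1]] <- data.frame(
        chrom = cc, pos_cM = pos[i], nearest_marker = nearest,
        ts = ts[i], r2 = r2, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos_cM = numeric(),
                      nearest_marker = character(), ts = numeric(),
                      r2 = numeric()))
  }
  do.call(rbind, out)
}

#' Permutation-based genome-wide threshold
#'
#' Permutes line means against genotype rows, records the genome-wide
#' maximum test statistic of each permutation and returns its empirical
#' (1 - alpha) quantile: with 10,000 permutations at alpha = 0.05 this is
#' the 9,500th order statistic of the null maxima.
#'
#' @inheritParams qtl_scan
#' @param n_permutations number of permutations (>= 100; default 10000).
#' @param alpha genome-wide type-I error (default 0.05).
#' @param seed integer seed.
#' @return Numeric critical value with the sorted null maxima in
#'   `attr(, "null_max")`.
#' @export
permutation_threshold <- function(genotypes, phenotypes, mode = "SIM",
                                  n_permutations = 10000, alpha = 0.05,
                                  step_cM = 1, cofactors = NULL, seed = NULL) {
  if (n_permutations < 100) stop_protmap("n_permutations must be >= 100")
  y <- .align_pheno(genotypes, phenotypes)
  if (length(y) < 20)
    warning("fewer than 20 lines: permutation threshold is unstable")
  genotypes <- genotypes[names(y), ]
  with_seed(seed, {
    if (mode == "SIM") {
      core <- .genoprob_core(genotypes, step_cM)
      X <- core$dosage
      n <- length(y)
      Xc <- sweep(X, 2, colMeans(X))
      Sxx <- pmax(colSums(Xc^2), 1e-12)
      maxts <- numeric(n_permutations)
      chunk <- 500L
      done <- 0L
      while (done < n_permutations) {
        m <- min(chunk, n_permutations - done)
        Yp <- vapply(seq_len(m), function(i) sample(y), numeric(n))
        Yp <- sweep(Yp, 2, colMeans(Yp))
        Syy <- colSums(Yp^2)
        S <- crossprod(Xc, Yp)                 # grid x perms
        rss1 <- pmax(sweep(-(S^2) / Sxx, 2, Syy, "+"), 1e-12)
        ts <- n * log(sweep(1 / rss1, 2, Syy, "*"))
        maxts[done + seq_len(m)] <- apply(ts, 2, max)
        done <- done + m
      }
    } else {
      maxts <- vapply(seq_len(n_permutations), function(i) {
        yp <- stats::setNames(sample(y), names(y))
        max(qtl_scan(genotypes, yp, mode = "sCIM", cofactors = cofactors,
                     step_cM = step_cM)$ts)
      }, numeric(1))
    }
    srt <- sort(maxts)
    kth <- max(1L, ceiling((1 - alpha) * n_permutations))
    structure(srt[kth], null_max = srt, alpha = alpha,
              n_permutations = n_permutations)
  })
}

#' Fraction of line-mean variance explained at a map position
#'
#' R-squared of the regression of line means on the expected genotype dosage
#' at the given position (equal to the squared Pearson correlation).
#'
#' @inheritParams qtl_scan
#' @param chrom chromosome identifier.
#' @param pos_cM map position.
#' @return Fraction in `[0, 1]`.
#' @export
variance_explained <- function(genotypes, phenotypes, chrom, pos_cM) {
  y <- .align_pheno(genotypes, phenotypes)
  genotypes <- genotypes[names(y), ]
  x <- .dosage_at(genotypes, chrom, pos_cM)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  unname(stats::cor(x, y)^2)
}

# Expected dosage at an arbitrary map position (marker or off-marker).
.dosage_at <- function(genotypes, chrom, pos_cM) {
  map <- attr(genotypes, "map")
  k <- attr(genotypes, "generation")
  C <- code_to_int(unclass(genotypes))
  ci <- which(map$chrom == chrom)
  if (!length(ci)) stop_protmap("unknown chromosome ", chrom)
  mi <- ci[abs(map$pos_cM[ci] - pos_cM) <= 1e-8]
  if (length(mi) && !anyNA(C[, mi[1]])) return(C[, mi[1]] - 2)
  vapply(seq_len(nrow(C)), function(l) {
    pr <- .line_probs_slow(C[l, ci], map$pos_cM[ci], pos_cM, k)
    pr[3] - pr[1]
  }, numeric(1))
}

#' Anchored re-scan for additive and epistatic effects
#'
#' Holds the dosage of an anchor locus (typically the major declared QTL) in
#' the model and re-scans the genome: at each grid point it fits
#' `mean + anchor + test + anchor:test` and reports separate test statistics
#' for the added additive term (`ts_add`) and for the interaction term
#' (`ts_int`). Grid points within `window_cM` of the anchor are excluded.
#'
#' @inheritParams qtl_scan
#' @param anchor list or vector with `chrom` and `pos_cM` of the anchor.
#' @param window_cM exclusion half-width around the anchor (default 20).
#' @return A `qtl_scan`-like data frame with columns `chrom`, `pos_cM`,
#'   `ts_add`, `ts_int` (NA inside the exclusion window); `mode` attribute
#'   is `"anchored"`.
#' @export
anchored_scan <- function(genotypes, phenotypes, anchor, step_cM = 1,
                          window_cM = 20) {
  y <- .align_pheno(genotypes, phenotypes)
  genotypes <- genotypes[names(y), ]
  z <- .dosage_at(genotypes, anchor$chrom %||% anchor[["chrom"]],
                  as.numeric(anchor$pos_cM %||% anchor[["pos_cM"]]))
  if (stats::sd(z) == 0) stop_protmap("anchor dosage is constant")
  core <- .genoprob_core(genotypes, step_cM)
  X <- core$dosage
  grid <- core$grid
  n <- length(y)
  one <- rep(1, n)
  rss_z <- sum(stats::lm.fit(cbind(one, z), y)$residuals^2)
  ts_add <- ts_int <- rep(NA_real_, nrow(grid))
  excl <- grid$chrom == (anchor$chrom %||% anchor[["chrom"]]) &
    abs(grid$pos_cM - as.numeric(anchor$pos_cM %||% anchor[["pos_cM"]])) <=
      window_cM
  for (i in which(!excl)) {
    x <- X[, i]
    r1 <- sum(stats::lm.fit(cbind(one, z, x), y)$residuals^2)
    r2 <- sum(stats::lm.fit(cbind(one, z, x, z * x), y)$residuals^2)
    ts_add[i] <- n * log(max(rss_z, 1e-12) / max(r1, 1e-12))
    ts_int[i] <- n * log(max(r1, 1e-12) / max(r2, 1e-12))
  }
  res <- data.frame(chrom = grid$chrom, pos_cM = grid$pos_cM,
                    ts_add = pmax(ts_add, 0), ts_int = pmax(ts_int, 0))
  structure(res, mode = "anchored", anchor = anchor,
            class = c("qtl_scan", "data.frame"))
}

#' @export
print.qtl_scan <- function(x, ...) {
  md <- attr(x, "mode")
  cat("QTL scan (", md, "): ", nrow(x), " grid points on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  th <- attr(x, "threshold")
  if (!is.null(th)) cat("  genome-wide threshold:", round(th, 3), "\n")
  pk <- attr(x, "peaks")
  if (!is.null(pk) && nrow(pk)) {
    cat("  declared peaks:\n")
    print(pk, row.names = FALSE)
  } else if (!is.null(th)) cat("  no peaks above threshold\n")
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, ...) {
  md <- attr(object, "mode")
  if (identical(md, "anchored")) {
    data.frame(statistic = c("ts_add", "ts_int"),
               max = c(max(object$ts_add, na.rm = TRUE),
                       max(object$ts_int, na.rm = TRUE)))
  } else {
    agg <- do.call(rbind, lapply(split(object, object$chrom), function(d)
      data.frame(chrom = d$chrom[1], max_ts = max(d$ts),
                 pos_at_max = d$pos_cM[which.max(d$ts)])))
    rownames(agg) <- NULL
    agg[order(match(agg$chrom, unique(object$chrom))), ]
  }
}

#' @export
plot.qtl_scan <- function(x, ...) {
  chrs <- unique(x$chrom)
  off <- 0
  xs <- numeric(nrow(x))
  mids <- numeric(length(chrs))
  for (j in seq_along(chrs)) {
    i <- x$chrom == chrs[j]
    xs[i] <- x$pos_cM[i] - min(x$pos_cM[i]) + off
    mids[j] <- off + (max(x$pos_cM[i]) - min(x$pos_cM[i])) / 2
    off <- max(xs[i]) + 5
  }
  yv <- if (!is.null(x$ts)) x$ts else x$ts_add
  graphics::plot(xs, yv, type = "l", xaxt = "n", xlab = "chromosome",
                 ylab = "test statistic", ...)
  graphics::axis(1, at = mids, labels = chrs, las = 2, cex.axis = 0.7)
  th <- attr(x, "threshold")
  if (!is.null(th)) graphics::abline(h = th, lty = 2)
  if (!is.null(x$ts_int)) graphics::lines(xs, x$ts_int, col = 2)
  invisible(x)
}
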