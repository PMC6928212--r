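# Conditional genotype probabilities on a cM grid for F_k-derived RILs.
#
# The implementation is exact: for a set of 2-3 linked loci it iterates the
# single-seed-descent diplotype distribution (all ordered haplotype pairs)
# from the F1 through k-1 rounds of selfing, with per-meiosis recombination
# fractions from the Haldane map function and no interference, then
# conditions the middle-locus genotype on the observed flanking genotypes.
# Tables depend only on (distances, k) and are cached per session.

.protmap_cache <- new.env(parent = emptyenv())

cache_get <- function(key) .protmap_cache[[key]]
cache_set <- function(key, val) assign(key, val, envir = .protmap_cache)

#' @keywords internal
clear_protmap_cache <- function() {
  rm(list = ls(.protmap_cache), envir = .protmap_cache)
}

# Joint genotype distribution at m = length(r)+1 loci for an F_k SSD plant.
# r: per-meiosis recombination fractions between adjacent loci.
# Returns an array of dim rep(3, m): P(genotype codes 1=A,2=H,3=B).
ssd_joint <- function(r, k) {
  m <- length(r) + 1L
  nh <- 2L^m
  hb <- t(vapply(0:(nh - 1L), function(h) as.integer(intToBits(h))[1:m],
                 integer(m)))                      # haplotype bit matrix
  # source patterns for one meiosis and their probabilities
  S <- as.matrix(expand.grid(rep(list(0:1), m)))
  pr_s <- apply(S, 1, function(s) {
    p <- 0.5
    for (j in seq_len(m - 1L))
      p <- p * if (s[j] == s[j + 1L]) 1 - r[j] else r[j]
    p
  })
  pow2 <- 2L^(seq_len(m) - 1L)
  # gamete index per (diplotype, pattern)
  h1 <- rep(0:(nh - 1L), each = nh)
  h2 <- rep(0:(nh - 1L), nh)
  nd <- nh * nh
  gidx <- matrix(0L, nd, nrow(S))
  for (s in seq_len(nrow(S))) {
    sel <- S[s, ]
    bits <- hb[h1 + 1L, , drop = FALSE] * rep(1L - sel, each = nd) +
      hb[h2 + 1L, , drop = FALSE] * rep(sel, each = nd)
    gidx[, s] <- as.integer(bits %*% pow2)
  }
  M <- matrix(0, nd, nh)                           # P(gamete | diplotype)
  for (s in seq_len(nrow(S)))
    M[cbind(seq_len(nd), gidx[, s] + 1L)] <- M[cbind(seq_len(nd),
                                                     gidx[, s] + 1L)] + pr_s[s]
  # F1 diplotype: one haplotype all parent-1 (0), one all parent-2 (2^m - 1)
  p <- numeric(nd)
  p[(0L) * nh + (nh - 1L) + 1L] <- 1
  for (gen in seq_len(k - 1L)) {
    PP <- crossprod(M, p * M)                      # P(g1, g2)
    p <- as.vector(t(PP))                          # index h1*nh + h2 + 1
  }
  geno <- hb[h1 + 1L, , drop = FALSE] + hb[h2 + 1L, , drop = FALSE]  # 0/1/2
  J <- array(0, rep(3L, m))
  idx <- geno %*% (3L^(seq_len(m) - 1L)) + 1L      # linear index
  for (d in seq_len(nd)) J[idx[d]] <- J[idx[d]] + p[d]
  J
}

# Conditional table P(G | L, R) for a grid point dL/dR cM from its informative
# flanks; dR = NA gives the one-flank table, both NA the unconditional prior.
cond_table <- function(dL, dR, k) {
  key <- sprintf("ct_%d_%.6f_%.6f", k,
                 if (is.na(dL)) -1 else dL, if (is.na(dR)) -1 else dR)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  out <- if (is.na(dL) && is.na(dR)) {
    h <- 0.5^(k - 1)
    matrix(c((1 - h) / 2, h, (1 - h) / 2), 1, 3)   # prior, single row
  } else if (is.na(dR) || is.na(dL)) {
    d <- if (is.na(dR)) dL else dR
    J <- ssd_joint(haldane_r(d), k)                # loci: flank, grid point
    tab <- J / pmax(rowSums(J), 1e-300)            # P(G | flank = a), 3 x 3
    tab
  } else {
    J <- ssd_joint(haldane_r(c(dL, dR)), k)        # loci: L, G, R
    tab <- array(0, c(3, 3, 3))                    # [a, b, g] = P(G=g|L=a,R=b)
    for (a in 1:3) for (b in 1:3) {
      w <- J[a, , b]
      tab[a, b, ] <- if (sum(w) > 0) w / sum(w) else c(0, 1, 0)
    }
    tab
  }
  cache_set(key, out)
  out
}

# Grid layout and per-point tables for a map; cached per (map, k, step).
grid_spec <- function(map, k, step_cM) {
  key <- sprintf("grid_%d_%s_%s", k, format(step_cM),
                 paste(format(c(nrow(map), sum(map$pos_cM),
                                sum(map$pos_cM^2))), collapse = "_"))
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  chrs <- attr(map, "chromosomes")
  midx <- split(seq_len(nrow(map)), factor(map$chrom, chrs))
  pts <- list()
  for (cc in chrs) {
    mi <- midx[[cc]]
    mp <- map$pos_cM[mi]
    gp <- sort(unique(c(mp, seq(min(mp), max(mp), by = step_cM))))
    at <- match(round(gp, 8), round(mp, 8))
    iL <- findInterval(gp, mp)
    iR <- length(mp) - findInterval(-gp, rev(-mp)) + 1L
    pts[[cc]] <- data.frame(chrom = cc, pos_cM = gp, at_marker = mi[at],
                            iL = mi[iL], iR = mi[iR])
  }
  grid <- do.call(rbind, pts)
  rownames(grid) <- NULL
  # precompute dosage/probability tables for off-marker points
  tabs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (!is.na(grid$at_marker[i])) next
    dL <- grid$pos_cM[i] - map$pos_cM[grid$iL[i]]
    dR <- map$pos_cM[grid$iR[i]] - grid$pos_cM[i]
    tabs[[i]] <- cond_table(dL, dR, k)
  }
  out <- list(grid = grid, tabs = tabs)
  cache_set(key, out)
  out
}

# Per-line conditional probability at one grid point, walking outward to the
# nearest informative markers (used when flanking calls are missing).
.line_probs_slow <- function(codes, mpos, gpos, k) {
  inf <- which(!is.na(codes))
  lft <- inf[mpos[inf] <= gpos]
  rgt <- inf[mpos[inf] >= gpos]
  iL <- if (length(lft)) lft[which.max(mpos[lft])] else NA_integer_
  iR <- if (length(rgt)) rgt[which.min(mpos[rgt])] else NA_integer_
  if (!is.na(iL) && !is.na(iR) && iL == iR)
    return(diag(3)[codes[iL], ])
  dL <- if (is.na(iL)) NA_real_ else gpos - mpos[iL]
  dR <- if (is.na(iR)) NA_real_ else mpos[iR] - gpos
  tab <- cond_table(dL, dR, k)
  if (is.na(iL) && is.na(iR)) return(tab[1, ])
  if (is.na(iR)) return(tab[codes[iL], ])
  if (is.na(iL)) return(tab[codes[iR], ])
  tab[codes[iL], codes[iR], ]
}

# Core engine: expected dosage matrix (lines x grid points) and, optionally,
# the full probability array.
.genoprob_core <- function(genotypes, step_cM, full = FALSE) {
  map <- attr(genotypes, "map")
  k <- attr(genotypes, "generation")
  gs <- grid_spec(map, k, step_cM)
  grid <- gs$grid
  C <- code_to_int(unclass(genotypes))
  n <- nrow(C)
  G <- nrow(grid)
  X <- matrix(NA_real_, n, G)
  P <- if (full) array(NA_real_, c(n, G, 3)) else NULL
  mpos <- map$pos_cM
  for (i in seq_len(G)) {
    am <- grid$at_marker[i]
    if (!is.na(am)) {
      cl <- C[, am]
      x <- as.numeric(cl) - 2
      miss <- is.na(cl)
      if (full) {
        pv <- matrix(0, n, 3)
        pv[cbind(which(!miss), cl[!miss])] <- 1
        P[, i, ] <- pv
      }
      if (any(miss)) {
        ci <- which(map$chrom == grid$chrom[i])
        for (l in which(miss)) {
          pr <- .line_probs_slow(C[l, ci], mpos[ci], grid$pos_cM[i], k)
          x[l] <- pr[3] - pr[1]
          if (full) P[l, i, ] <- pr
        }
      }
      X[, i] <- x
    } else {
      tab <- gs$tabs[[i]]
      cl <- C[, grid$iL[i]]
      cr <- C[, grid$iR[i]]
      ok <- !is.na(cl) & !is.na(cr)
      if (any(ok)) {
        pv <- tab[cbind(rep(cl[ok], 3), rep(cr[ok], 3),
                        rep(1:3, each = sum(ok)))]
        pv <- matrix(pv, sum(ok), 3)
        X[ok, i] <- pv[, 3] - pv[, 1]
        if (full) P[ok, i, ] <- pv
      }
      if (any(!ok)) {
        ci <- which(map$chrom == grid$chrom[i])
        for (l in which(!ok)) {
          pr <- .line_probs_slow(C[l, ci], mpos[ci], grid$pos_cM[i], k)
          X[l, i] <- pr[3] - pr[1]
          if (full) P[l, i, ] <- pr
        }
      }
    }
  }
  list(grid = grid[c("chrom", "pos_cM")], dosage = X, probs = P)
}

#' Conditional genotype probabilities on a cM grid
#'
#' For every line and every grid point, computes the probability vector over
#' genotype codes (A, H, B) given the nearest informative flanking markers,
#' under the exact F_k single-seed-descent transition model with Haldane
#' recombination and no interference. At a non-missing marker the vector is
#' a point mass; for a fully missing line it is the unconditional RIL
#' expectation ((1-h)/2, h, (1-h)/2) with h = (1/2)^(k-1).
#'
#' @param genotypes a [ril_geno()].
#' @param step_cM grid step in cM (> 0); marker positions are always
#'   included in the grid.
#' @return A `genoprob` object: list with `grid` (chrom, pos_cM), `probs`
#'   (lines x grid x 3 array) and `dosage` (lines x grid expected dosage,
#'   P(B) - P(A) in [-1, 1]).
#' @export
genotype_probabilities <- function(genotypes, step_cM = 1) {
  if (step_cM <= 0) stop_protmap("step_cM must be > 0")
  out <- .genoprob_core(genotypes, step_cM, full = TRUE)
  structure(out, class = "genoprob")
}

#' @export
print.genoprob <- function(x, ...) {
  cat("Genotype probabilities:", dim(x$probs)[1], "lines x",
      nrow(x$grid), "grid points\n")
  invisible(x)
}
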