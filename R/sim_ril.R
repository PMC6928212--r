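#' RIL genotype container
#'
#' @param geno character matrix (lines x markers) with codes `"A"` (parent-1
#'   homozygote), `"H"`, `"B"` (parent-2 homozygote) or `NA`.
#' @param map the [genetic_map()] the columns refer to.
#' @param generation derived generation k (an F_k-derived line).
#' @return A `ril_geno` object: the coded matrix with the map, generation and
#'   per-marker missing fraction attached as attributes.
#' @export
ril_geno <- function(geno, map, generation) {
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map))
    stop_protmap("genotype columns (", ncol(geno),
                 ") do not match map markers (", nrow(map), ")")
  bad <- !(geno %in% c(genotype_codes, NA))
  if (any(bad)) stop_protmap("unknown genotype code(s): ",
                             paste(unique(geno[bad]), collapse = ", "))
  colnames(geno) <- map$marker
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf(sprintf("RIL%%0%dd", max(3L, nchar(nrow(geno)))),
                              seq_len(nrow(geno)))
  structure(geno, map = map, generation = as.integer(generation),
            missing_fraction = colMeans(is.na(geno)),
            class = c("ril_geno", "matrix", "array"))
}

#' @export
`[.ril_geno` <- function(x, i, j, drop = FALSE) {
  map <- attr(x, "map")
  gen <- attr(x, "generation")
  out <- unclass(x)[i, j, drop = FALSE]
  if (!missing(j)) {
    keep <- seq_len(nrow(map))[j]
    map <- genetic_map(map$marker[keep], map$chrom[keep], map$pos_cM[keep],
                       map$marker_class[keep], map$bp[keep])
  }
  ril_geno(out, map, gen)
}

#' @export
print.ril_geno <- function(x, ...) {
  cat("RIL genotypes: ", nrow(x), " lines x ", ncol(x), " markers (F",
      attr(x, "generation"), "-derived)\n", sep = "")
  tab <- table(factor(x, genotype_codes))
  cat("  code frequencies:",
      paste(names(tab), sprintf("%.3f", tab / sum(tab)), sep = "=",
            collapse = ", "),
      sprintf("; missing %.3f", mean(is.na(unclass(x)))), "\n")
  invisible(x)
}

# One round of meioses at marker resolution for all lines of a chromosome.
# H1/H2 are n x m integer haplotype matrices (0 = parent-1 origin, 1 =
# parent-2), pos the marker cM positions. Per meiosis the crossover count is
# Poisson(L/100) with positions uniform on [0, L] (Haldane model, no
# interference).
.gametes <- function(H1, H2, pos) {
  n <- nrow(H1)
  m <- length(pos)
  L <- pos[m] - pos[1]
  ph0 <- stats::rbinom(n, 1L, 0.5)
  out <- H1
  nc <- if (L > 0) stats::rpois(n, L / 100) else integer(n)
  plain <- nc == 0L & ph0 == 1L
  out[plain, ] <- H2[plain, , drop = FALSE]
  for (i in which(nc > 0L)) {
    xpos <- pos[1] + sort(stats::runif(nc[i], 0, L))
    phase <- (ph0[i] + findInterval(pos, xpos)) %% 2L
    oi <- H1[i, ]
    sw <- phase == 1L
    oi[sw] <- H2[i, sw]
    out[i, ] <- oi
  }
  out
}

#' Simulate an F_k-derived RIL population by single-seed descent
#'
#' Starting from the F1 of two fully homozygous parents, each line is
#' advanced by strict single-seed descent to generation `derived_generation`:
#' every generation one plant is selfed via two independently simulated
#' meioses per chromosome. Residual heterozygosity is retained, so an
#' F5-derived line is heterozygous at a fraction (1/2)^4 = 6.25% of loci in
#' expectation.
#'
#' @param map a [genetic_map()].
#' @param n_lines number of lines (>= 2).
#' @param derived_generation k in 2..10 (e.g. 5 for an F5-derived RIL).
#' @param missing_rate per-call probability of a missing genotype (default 0).
#' @param seed integer seed; results are reproducible given the seed.
#' @return A [ril_geno()] matrix of `"A"`/`"H"`/`"B"` codes.
#' @examples
#' gm <- genetic_map(paste0("M", 1:5), "Gm01", c(0, 10, 20, 30, 60))
#' rg <- simulate_ril_population(gm, n_lines = 20, seed = 1)
#' @export
simulate_ril_population <- function(map, n_lines, derived_generation = 5,
                                    missing_rate = 0, seed = NULL) {
  if (n_lines < 2) stop_protmap("n_lines must be >= 2")
  if (!derived_generation %in% 2:10)
    stop_protmap("derived_generation must be in 2..10")
  chrs <- attr(map, "chromosomes")
  pos_by_chr <- split(map$pos_cM, factor(map$chrom, chrs))
  with_seed(seed, {
    cols <- lapply(chrs, function(cc) {
      pos <- pos_by_chr[[cc]]
      m <- length(pos)
      H1 <- matrix(0L, n_lines, m)   # F1: one haplotype from each parent
      H2 <- matrix(1L, n_lines, m)
      for (g in seq_len(derived_generation - 1L)) {
        G1 <- .gametes(H1, H2, pos)
        G2 <- .gametes(H1, H2, pos)
        H1 <- G1; H2 <- G2
      }
      H1 + H2
    })
    geno <- do.call(cbind, cols)
    codes <- matrix(genotype_codes[geno + 1L], n_lines, nrow(map))
    if (missing_rate > 0)
      codes[stats::runif(length(codes)) < missing_rate] <- NA
    rownames(codes) <- sprintf(sprintf("RIL%%0%dd", max(3L, nchar(n_lines))),
                               seq_len(n_lines))
    ril_geno(codes, map, derived_generation)
  })
}
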