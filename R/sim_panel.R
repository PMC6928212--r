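#' Diversity-panel genotype container
#'
#' Biallelic SNP genotypes for a panel of (largely inbred) varieties, with
#' physical coordinates. Calls are coded `0` (homozygous reference), `1`
#' (heterozygous), `2` (homozygous alternate) or `NA`.
#'
#' @param calls integer matrix, lines x SNPs.
#' @param snp_info data frame with columns `id`, `chrom`, `bp` (strictly
#'   increasing within a chromosome), `ref`, `alt`.
#' @param roles optional named list of special lines (`donor`,
#'   `recurrent_parent`, `derivatives`, `low_lines`).
#' @return A `panel_geno` object (list with `calls` and `snp_info`).
#' @export
panel_geno <- function(calls, snp_info, roles = NULL) {
  calls <- as.matrix(calls)
  snp_info <- as.data.frame(snp_info)
  need <- c("id", "chrom", "bp", "ref", "alt")
  if (!all(need %in% names(snp_info)))
    stop_protmap("snp_info needs columns ", paste(need, collapse = ", "))
  if (ncol(calls) != nrow(snp_info))
    stop_protmap("calls columns do not match snp_info rows")
  if (!all(calls %in% c(0L, 1L, 2L, NA)))
    stop_protmap("calls must be coded 0/1/2/NA")
  for (cc in unique(snp_info$chrom)) {
    b <- snp_info$bp[snp_info$chrom == cc]
    if (any(diff(b) <= 0)) {
      i <- which(diff(b) <= 0)[1]
      stop_protmap("physical positions not strictly increasing on ", cc,
                   " at SNP ", snp_info$id[snp_info$chrom == cc][i + 1])
    }
  }
  colnames(calls) <- snp_info$id
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("V%03d", seq_len(nrow(calls)))
  structure(list(calls = calls, snp_info = snp_info, roles = roles),
            class = "panel_geno")
}

#' @export
print.panel_geno <- function(x, ...) {
  cat("SNP panel: ", nrow(x$calls), " lines x ", ncol(x$calls),
      " SNPs on ", length(unique(x$snp_info$chrom)), " chromosome(s)\n",
      sep = "")
  if (!is.null(x$roles$donor)) cat("  donor line:", x$roles$donor, "\n")
  if (length(x$roles$derivatives))
    cat("  derivatives:", paste(x$roles$derivatives, collapse = ", "), "\n")
  invisible(x)
}

# Alternate-allele frequency per SNP over non-missing calls (hets count 1/2),
# restricted to `lines` when given.
alt_freq <- function(panel, lines = NULL) {
  m <- panel$calls
  if (!is.null(lines)) m <- m[lines, , drop = FALSE]
  colMeans(m, na.rm = TRUE) / 2
}

#' Simulate a diversity panel with injected donor-rare alleles
#'
#' Generates an inbred SNP panel on the chromosomes of `map`. Most SNPs draw
#' their alternate-allele frequency from `maf_distribution`; in addition,
#' `donor_rare_config` injects SNPs at which a designated donor line (the
#' first line, named `"Donor"`) is homozygous for a minor allele whose panel
#' frequency equals `rare_frequency` in expectation. A subset of the injected
#' SNPs is placed in tight physical clusters, emulating donor haplotype
#' blocks; the remainder is scattered.
#'
#' @param n_lines panel size (>= 10).
#' @param map a [genetic_map()]; chromosome physical lengths are taken from
#'   its `bp` column when present, else 1 cM ~ 400 kb.
#' @param snp_density background SNPs per chromosome.
#' @param maf_distribution function(n) returning n minor-allele frequencies
#'   (default uniform on 0.05..0.5).
#' @param donor_rare_config list with `n_rare` (count), `rare_frequency`
#'   (panel frequency of the donor allele, < 0.05), and optionally
#'   `n_clusters` and `cluster_span_bp` controlling how many of the injected
#'   SNPs form physical clusters (defaults 4 clusters spanning 1 Mb, 5 SNPs
#'   each).
#' @param het_rate,missing_rate per-call heterozygosity and missingness of
#'   the background panel (defaults 0.01 and 0).
#' @param seed integer seed.
#' @return A [panel_geno()]; the injected SNP ids are in
#'   `attr(, "rare_snps")` and the clustered subsets in `attr(, "rare_clusters")`.
#' @export
simulate_panel <- function(n_lines, map, snp_density = 500,
                           maf_distribution = function(n) stats::runif(n, 0.05, 0.5),
                           donor_rare_config = list(n_rare = 0,
                                                    rare_frequency = 1 / n_lines),
                           het_rate = 0.01, missing_rate = 0, seed = NULL) {
  if (n_lines < 10) stop_protmap("n_lines must be >= 10")
  n_rare <- donor_rare_config$n_rare %||% 0
  f_rare <- donor_rare_config$rare_frequency %||% (1 / n_lines)
  n_clusters <- donor_rare_config$n_clusters %||% (if (n_rare >= 20) 4 else 0)
  span <- donor_rare_config$cluster_span_bp %||% 1e6
  per_cluster <- donor_rare_config$snps_per_cluster %||% 5
  if (n_rare > 0) {
    if (f_rare >= 0.05) stop_protmap("rare_frequency must be < 0.05")
    if (f_rare * n_lines < 1)
      stop_protmap("rare_frequency x n_lines < 1: the rare allele cannot ",
                   "exist in less than one line")
  }
  chrs <- attr(map, "chromosomes")
  chr_len <- if (!is.null(map$bp)) {
    vapply(split(map$bp, factor(map$chrom, chrs)), max, numeric(1))
  } else {
    chrom_lengths(map) * 4e5 + 1
  }
  with_seed(seed, {
    # background SNP coordinates
    pos <- lapply(chrs, function(cc)
      sort(sample.int(chr_len[[cc]], snp_density)))
    snp <- data.frame(chrom = rep(chrs, each = snp_density),
                      bp = unlist(pos), rare = FALSE)
    # injected donor-rare SNP coordinates: clustered + scattered
    if (n_rare > 0) {
      n_clu <- min(n_clusters, n_rare %/% max(per_cluster, 1))
      clu_id <- integer(0); rb <- numeric(0); rc <- character(0)
      if (n_clu > 0) {
        cc <- sample(chrs, n_clu, replace = TRUE)
        start <- vapply(cc, function(ch)
          stats::runif(1, 1, chr_len[[ch]] - span), numeric(1))
        for (j in seq_len(n_clu)) {
          rb <- c(rb, sort(round(stats::runif(per_cluster, start[j],
                                              start[j] + span))))
          rc <- c(rc, rep(cc[j], per_cluster))
          clu_id <- c(clu_id, rep(j, per_cluster))
        }
      }
      n_scatter <- n_rare - length(rb)
      if (n_scatter > 0) {
        cc <- sample(chrs, n_scatter, replace = TRUE)
        rb <- c(rb, vapply(cc, function(ch)
          stats::runif(1, 1, chr_len[[ch]]), numeric(1)))
        rc <- c(rc, cc)
        clu_id <- c(clu_id, rep(0L, n_scatter))
      }
      snp <- rbind(snp, data.frame(chrom = rc, bp = round(rb), rare = TRUE))
      snp$cluster <- c(rep(0L, snp_density * length(chrs)), clu_id)
    } else snp$cluster <- 0L
    snp <- snp[order(match(snp$chrom, chrs), snp$bp), , drop = FALSE]
    # de-duplicate coincident coordinates
    dup <- duplicated(snp[c("chrom", "bp")])
    while (any(dup)) {
      snp$bp[dup] <- snp$bp[dup] + 1
      snp <- snp[order(match(snp$chrom, chrs), snp$bp), , drop = FALSE]
      dup <- duplicated(snp[c("chrom", "bp")])
    }
    n_snp <- nrow(snp)
    p_alt <- numeric(n_snp)
    p_alt[!snp$rare] <- maf_distribution(sum(!snp$rare))
    calls <- matrix(0L, n_lines, n_snp)
    # inbred background: small het rate, homozygote frequency tuned so the
    # expected alt frequency equals p_alt
    bg <- which(!snp$rare)
    for (j in bg) {
      p_hom <- min(max((p_alt[j] - het_rate / 2) / (1 - het_rate), 0), 1)
      g <- stats::rbinom(n_lines, 1L, p_hom) * 2L
      g[stats::runif(n_lines) < het_rate] <- 1L
      calls[, j] <- g
    }
    # donor-rare SNPs: donor homozygous alt; other lines carry the alt allele
    # so that the expected panel frequency equals f_rare
    if (n_rare > 0) {
      q <- max((f_rare * n_lines - 1) / (n_lines - 1), 0)
      for (j in which(snp$rare)) {
        g <- c(2L, stats::rbinom(n_lines - 1L, 1L, q) * 2L)
        calls[, j] <- g
      }
      p_alt[snp$rare] <- f_rare
    }
    if (missing_rate > 0)
      calls[stats::runif(length(calls)) < missing_rate] <- NA
    info <- data.frame(id = sprintf("S_%s_%09d", snp$chrom, snp$bp),
                       chrom = snp$chrom, bp = snp$bp,
                       ref = "A", alt = "T", stringsAsFactors = FALSE)
    rownames(calls) <- c("Donor", sprintf("V%03d", seq_len(n_lines - 1L) + 1L))
    pan <- panel_geno(calls, info, roles = list(donor = "Donor"))
    attr(pan, "rare_snps") <- info$id[snp$rare]
    attr(pan, "rare_clusters") <- split(info$id[snp$rare & snp$cluster > 0],
                                        snp$cluster[snp$rare & snp$cluster > 0])
    pan
  })
}

#' Append pedigree-derived lines carrying retained donor segments
#'
#' Each derivative named in `pedigree$derivatives` is built as a mosaic of
#' the donor and the recurrent parent: inside `retained_blocks` (physical
#' intervals under selection) the derivative always carries the donor
#' genotype; outside, chromosomes are partitioned into independently
#' segregating physical segments (`segment_bp`) that carry the donor
#' genotype with probability `retention_probability_outside` each.
#'
#' @param panel a [panel_geno()] containing the donor and recurrent parent.
#' @param pedigree a [pedigree()]; its `derivatives` are appended.
#' @param retained_blocks data frame `chrom`, `start`, `end` (1-based bp,
#'   inclusive) of intervals forced to donor origin; may be empty.
#' @param retention_probability_outside per-segment donor retention
#'   probability outside the blocks.
#' @param segment_bp physical size of an independently segregating segment
#'   (default 10 Mb).
#' @param seed integer seed.
#' @return The panel with derivative rows appended and roles updated.
#' @export
simulate_descent <- function(panel, pedigree, retained_blocks = NULL,
                             retention_probability_outside = 0.25,
                             segment_bp = 1e7, seed = NULL) {
  calls <- panel$calls
  info <- panel$snp_info
  donor <- pedigree$donor
  recur <- pedigree$recurrent_parent
  if (!all(c(donor, recur) %in% rownames(calls)))
    stop_protmap("donor and recurrent parent must be panel lines")
  if (!is.null(retained_blocks) && nrow(retained_blocks) > 0) {
    bad <- !retained_blocks$chrom %in% info$chrom
    if (any(bad))
      stop_protmap("retained block on unknown chromosome: ",
                   paste(unique(retained_blocks$chrom[bad]), collapse = ", "))
  }
  in_block <- rep(FALSE, nrow(info))
  if (!is.null(retained_blocks)) {
    for (i in seq_len(NROW(retained_blocks))) {
      in_block <- in_block |
        (info$chrom == retained_blocks$chrom[i] &
           info$bp >= retained_blocks$start[i] &
           info$bp <= retained_blocks$end[i])
    }
  }
  seg <- paste(info$chrom, info$bp %/% segment_bp)
  seg_f <- factor(seg, unique(seg))
  with_seed(seed, {
    new <- matrix(NA_integer_, length(pedigree$derivatives), ncol(calls))
    for (i in seq_along(pedigree$derivatives)) {
      keep <- stats::rbinom(nlevels(seg_f), 1L,
                            retention_probability_outside) == 1L
      donor_state <- in_block | keep[as.integer(seg_f)]
      new[i, ] <- ifelse(donor_state, calls[donor, ], calls[recur, ])
    }
    rownames(new) <- pedigree$derivatives
    out <- panel_geno(rbind(calls, new), info,
                      roles = list(donor = donor, recurrent_parent = recur,
                                   derivatives = pedigree$derivatives,
                                   low_lines = pedigree$low_lines))
    attr(out, "rare_snps") <- attr(panel, "rare_snps")
    attr(out, "rare_clusters") <- attr(panel, "rare_clusters")
    attr(out, "retained_blocks") <- retained_blocks
    out
  })
}
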