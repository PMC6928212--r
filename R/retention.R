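# Pedigree rare-allele retention scan: find the focal line's alleles that
# are rare in a diversity panel, contrast them against the recurrent parent
# and low-trait lines, keep those retained across the derivative cultivars,
# and assemble the survivors into physical genomic blocks.

# Focal line's homozygous allele per SNP: 0 (ref), 2 (alt) or NA when the
# focal call is heterozygous or missing.
.focal_allele <- function(panel, focal) {
  g <- panel$calls[focal, ]
  ifelse(is.na(g) | g == 1L, NA, g)
}

#' Scan a panel for the focal line's rare alleles
#'
#' Returns the SNPs at which the focal line is homozygous for an allele
#' whose panel frequency is at most `max_panel_frequency`. Frequencies are
#' computed over non-missing allele calls (the focal line included) with
#' heterozygotes counting one half; heterozygous or missing focal calls are
#' skipped. Lines in `exclude` — typically the focal line's own descendants,
#' whose carrier status is the object of the later retention filter — do not
#' enter the frequency denominator.
#'
#' @param panel a [panel_geno()].
#' @param focal focal line name (e.g. the donor cultivar).
#' @param max_panel_frequency rare-allele frequency ceiling (default 0.02;
#'   published pedigree screens of this kind report retained rare-allele
#'   frequencies in the 0.0005-0.011 range).
#' @param exclude additional line names excluded from the frequency
#'   computation.
#' @return A `retention_candidates` data frame: id, chrom, bp, focal_allele
#'   (`"ref"`/`"alt"`), panel_freq.
#' @export
rare_allele_scan <- function(panel, focal, max_panel_frequency = 0.02,
                             exclude = character()) {
  if (!focal %in% rownames(panel$calls))
    stop_protmap("focal line ", focal, " not in panel")
  fa <- .focal_allele(panel, focal)
  others <- setdiff(rownames(panel$calls), exclude)
  af <- alt_freq(panel, others)                # alt frequency, hets as half
  focal_freq <- ifelse(fa == 2L, af, 1 - af)
  keep <- which(!is.na(fa) & focal_freq <= max_panel_frequency)
  res <- data.frame(id = panel$snp_info$id[keep],
                    chrom = panel$snp_info$chrom[keep],
                    bp = panel$snp_info$bp[keep],
                    focal_allele = c("ref", "alt")[fa[keep] / 2 + 1],
                    panel_freq = unname(focal_freq[keep]),
                    stringsAsFactors = FALSE)
  structure(res, focal = focal,
            class = c("retention_candidates", "data.frame"))
}

#' Contrast candidate SNPs against the recurrent parent and low lines
#'
#' Keeps candidates at which the recurrent parent does not carry the focal
#' allele (is homozygous for the other allele). When `require_low_absent`
#' is `TRUE`, all `low_lines` must also lack it. Missing comparator calls
#' are non-informative: the SNP is kept and flagged.
#'
#' @param candidates a [rare_allele_scan()] result.
#' @param panel the [panel_geno()].
#' @param recurrent_parent line name.
#' @param low_lines character vector of low-trait contrast lines.
#' @param require_low_absent enforce absence from `low_lines` as a hard
#'   filter (default TRUE); with `FALSE` the low-line status is annotated
#'   only.
#' @return The filtered `retention_candidates` with logical columns
#'   `recurrent_informative` and `absent_from_low`.
#' @export
contrast_filter <- function(candidates, panel, recurrent_parent,
                            low_lines = character(),
                            require_low_absent = TRUE) {
  if (!recurrent_parent %in% rownames(panel$calls))
    stop_protmap("recurrent parent not in panel")
  idx <- match(candidates$id, panel$snp_info$id)
  fa <- ifelse(candidates$focal_allele == "alt", 2L, 0L)
  rp <- panel$calls[recurrent_parent, idx]
  rp_lacks <- !is.na(rp) & rp == 2L - fa      # hom for the other allele
  rp_inform <- !is.na(rp)
  low_absent <- rep(TRUE, nrow(candidates))
  if (length(low_lines)) {
    lg <- panel$calls[low_lines, idx, drop = FALSE]
    carries <- sweep(lg, 2, fa, function(g, a) !is.na(g) & (g == a | g == 1L))
    low_absent <- colSums(carries) == 0
  }
  keep <- (!rp_inform | rp_lacks) & (!require_low_absent | low_absent)
  res <- candidates[keep, , drop = FALSE]
  res$recurrent_informative <- rp_inform[keep]
  res$absent_from_low <- low_absent[keep]
  rownames(res) <- NULL
  structure(res, focal = attr(candidates, "focal"),
            class = c("retention_candidates", "data.frame"))
}

#' Filter SNPs by retention ratio across derivative lines
#'
#' For each SNP the retention ratio rho = carriers / informative derivatives,
#' where a carrier is a derivative homozygous for the focal allele and
#' informative means non-missing and non-heterozygous (configurable via
#' `het_as_carrier`). SNPs are kept when `rho >= min_ratio` and at least
#' `min_informative` derivatives are informative.
#'
#' @param candidates a (filtered) `retention_candidates` data frame.
#' @param panel the [panel_geno()].
#' @param derivatives character vector of derivative line names.
#' @param min_ratio minimum retention ratio (0.66 for the broad screen, 1.0
#'   for the strict screen).
#' @param min_informative minimum informative derivatives (default 4).
#' @param het_as_carrier count heterozygous derivatives as carriers
#'   (default FALSE: carrier status requires homozygosity).
#' @return A `retention_records` data frame adding `carriers`,
#'   `informative` and `rho`.
#' @export
retention_filter <- function(candidates, panel, derivatives, min_ratio = 0.66,
                             min_informative = 4, het_as_carrier = FALSE) {
  if (min_ratio <= 0 || min_ratio > 1)
    stop_protmap("min_ratio must be in (0, 1]")
  if (!all(derivatives %in% rownames(panel$calls)))
    stop_protmap("derivatives must be panel lines")
  idx <- match(candidates$id, panel$snp_info$id)
  fa <- ifelse(candidates$focal_allele == "alt", 2L, 0L)
  dg <- panel$calls[derivatives, idx, drop = FALSE]
  is_car <- sweep(dg, 2, fa, function(g, a)
    !is.na(g) & (g == a | (het_as_carrier & g == 1L)))
  inform <- !is.na(dg) & (het_as_carrier | dg != 1L)
  carriers <- colSums(is_car & inform)
  informative <- colSums(inform)
  rho <- ifelse(informative > 0, carriers / informative, NA)
  dropped <- sum(informative == 0)
  if (dropped > 0)
    message(dropped, " SNP(s) dropped: no informative derivative genotype")
  keep <- !is.na(rho) & rho >= min_ratio & informative >= min_informative
  res <- candidates[keep, , drop = FALSE]
  res$carriers <- carriers[keep]
  res$informative <- informative[keep]
  res$rho <- rho[keep]
  rownames(res) <- NULL
  structure(res, focal = attr(candidates, "focal"), min_ratio = min_ratio,
            class = c("retention_records", "data.frame"))
}

#' Assemble retained SNPs into physical genomic blocks
#'
#' Single-linkage clustering along each chromosome: consecutive retained
#' SNPs at most `max_gap_bp` apart join one block. Clusters with fewer than
#' `min_snps` members are reported separately as singletons. Block spans run
#' from the first to the last member SNP (1-based, inclusive).
#'
#' @param records a `retention_records` data frame.
#' @param max_gap_bp maximum within-block gap (default 500 kb).
#' @param min_snps minimum SNPs per block (default 2).
#' @return A `retention_blocks` data frame: chrom, start, end, n_snps,
#'   mean_rho, snp_ids (comma-separated); sub-threshold clusters in
#'   `attr(, "singletons")`.
#' @export
build_blocks <- function(records, max_gap_bp = 5e5, min_snps = 2) {
  if (!nrow(records)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      mean_rho = numeric(), snp_ids = character())
    return(structure(out, singletons = out,
                     class = c("retention_blocks", "data.frame")))
  }
  d <- records[order(records$chrom, records$bp), , drop = FALSE]
  grp <- cumsum(c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                    diff(d$bp) > max_gap_bp))
  blk <- lapply(split(d, grp), function(g)
    data.frame(chrom = g$chrom[1], start = min(g$bp), end = max(g$bp),
               n_snps = nrow(g),
               mean_rho = mean(g$rho %||% rep(NA_real_, nrow(g))),
               snp_ids = paste(g$id, collapse = ","),
               stringsAsFactors = FALSE))
  blk <- do.call(rbind, blk)
  rownames(blk) <- NULL
  main <- blk[blk$n_snps >= min_snps, , drop = FALSE]
  sing <- blk[blk$n_snps < min_snps, , drop = FALSE]
  rownames(main) <- rownames(sing) <- NULL
  structure(main, singletons = sing,
            class = c("retention_blocks", "data.frame"))
}

#' Annotate retention blocks with anchor markers and known regions
#'
#' Attaches to each block the anchor markers (e.g. SSR/DArT loci with
#' physical positions) and known regions (QTL, BSA loci, consensus
#' Meta-QTL) lying inside the block or within `link_distance_bp` of its
#' edges. Blocks with no annotation are labeled novel.
#'
#' @param blocks a [build_blocks()] result.
#' @param anchors data frame `name`, `chrom`, `bp`.
#' @param known_regions data frame `name`, `chrom`, `bp` (point) or
#'   `start`/`end` (interval), and optionally `type`.
#' @param link_distance_bp linking distance beyond block edges (default
#'   500 kb).
#' @return The blocks with added columns `anchors`, `known`, `novel`.
#' @export
annotate_blocks <- function(blocks, anchors = NULL, known_regions = NULL,
                            link_distance_bp = 5e5) {
  near <- function(chrom, lo, hi, tab) {
    if (is.null(tab) || !nrow(tab)) return(character(0))
    s <- tab$start %||% tab$bp
    e <- tab$end %||% tab$bp
    hit <- tab$chrom == chrom & e >= lo - link_distance_bp &
      s <= hi + link_distance_bp
    tab$name[hit]
  }
  blocks$anchors <- vapply(seq_len(nrow(blocks)), function(i)
    paste(near(blocks$chrom[i], blocks$start[i], blocks$end[i], anchors),
          collapse = ","), character(1))
  blocks$known <- vapply(seq_len(nrow(blocks)), function(i)
    paste(near(blocks$chrom[i], blocks$start[i], blocks$end[i],
               known_regions), collapse = ","), character(1))
  blocks$novel <- blocks$anchors == "" & blocks$known == ""
  blocks
}

#' @export
print.retention_blocks <- function(x, ...) {
  cat("Retention blocks:", nrow(x), "block(s)")
  sing <- attr(x, "singletons")
  if (!is.null(sing)) cat(";", nrow(sing), "singleton cluster(s)")
  cat("\n")
  if (nrow(x)) {
    show <- x
    show$snp_ids <- NULL
    show$span_kb <- round((show$end - show$start) / 1e3, 1)
    print(as.data.frame(show), row.names = FALSE)
  }
  invisible(x)
}

#' Write retention blocks as BED and TSV
#'
#' The BED file uses 0-based half-open coordinates (converted from the
#' internal 1-based inclusive spans); the TSV mirrors the block table.
#'
#' @param blocks a [build_blocks()] result.
#' @param bed,tsv output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_blocks <- function(blocks, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    bd <- data.frame(blocks$chrom, format(blocks$start - 1, scientific = FALSE, trim = TRUE),
                     format(blocks$end, scientific = FALSE, trim = TRUE),
                     sprintf("block%02d", seq_len(nrow(blocks))))
    utils::write.table(bd, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv))
    utils::write.table(as.data.frame(blocks), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(bed = bed, tsv = tsv))
}
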