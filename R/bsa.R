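# In-silico bulked segregant analysis: bulks are built from the phenotypic
# tails of a RIL population and genotyped by pooling the individual lines'
# marker calls (allele counts; a heterozygote contributes one allele of
# each kind).

#' Build high/low phenotype bulks
#'
#' Ranks line means and takes the top and bottom `tail_fraction` as the high
#' and low bulks. Ties at a bulk boundary are broken by line-name order, so
#' bulk membership is deterministic.
#'
#' @param phenotypes a `phenotype_records` data frame or named line means.
#' @param tail_fraction fraction of lines per bulk, in (0, 0.5].
#' @param min_bulk minimum lines per bulk (default 8); smaller tails are an
#'   error.
#' @param population optional population identifier stored in the result.
#' @return A `bulk_pair`: list with `high_lines`, `low_lines`, bulk mean
#'   phenotypes and the population id.
#' @export
make_bulks <- function(phenotypes, tail_fraction = 0.1, min_bulk = 8,
                       population = "pop") {
  if (tail_fraction <= 0 || tail_fraction > 0.5)
    stop_protmap("tail_fraction must be in (0, 0.5]")
  y <- if (is.data.frame(phenotypes)) line_means(phenotypes) else phenotypes
  n_tail <- floor(length(y) * tail_fraction)
  if (n_tail < min_bulk)
    stop_protmap("tail of ", n_tail, " lines is below min_bulk = ", min_bulk)
  ord <- order(-y, names(y))
  high <- names(y)[ord[seq_len(n_tail)]]
  low <- names(y)[rev(ord)[seq_len(n_tail)]]
  structure(list(population = population, high_lines = high, low_lines = low,
                 high_mean = mean(y[high]), low_mean = mean(y[low]),
                 n_lines = length(y)),
            class = "bulk_pair")
}

#' @export
print.bulk_pair <- function(x, ...) {
  cat("Bulk pair [", x$population, "]: ", length(x$high_lines),
      " high + ", length(x$low_lines), " low lines of ", x$n_lines,
      "; bulk means ", round(x$high_mean, 2), " / ", round(x$low_mean, 2),
      "\n", sep = "")
  invisible(x)
}

# Allele counts of the high-parent allele in a set of lines at all markers.
# high_parent "A" means parent 1 carries the trait-increasing alleles.
.bulk_counts <- function(genotypes, lines, high_parent) {
  C <- code_to_int(unclass(genotypes))[lines, , drop = FALSE]
  nA <- colSums((C == 1) * 2 + (C == 2), na.rm = TRUE)
  tot <- colSums(!is.na(C)) * 2
  hi <- if (high_parent == "A") nA else tot - nA
  list(high = hi, total = tot)
}

#' Classify markers from bulk allele frequencies
#'
#' For each marker, computes the frequency of the high-protein parent's
#' allele in the high bulk (`f_high`) and low bulk (`f_low`) and classifies:
#' `positive` when `f_high - f_low >= delta_threshold` and a two-proportion
#' exact test (Fisher) on the allele counts has p <= alpha; `fixed_high`
#' when both bulks carry the high parent's allele at frequency
#' `>= fixed_threshold`; `fixed_low` symmetrically; otherwise
#' `uninformative`. Markers monomorphic across the population are flagged
#' non-segregating.
#'
#' @param bulks a [make_bulks()] result.
#' @param genotypes a [ril_geno()] containing the bulk lines.
#' @param delta_threshold minimum bulk frequency contrast (default 0.4).
#' @param alpha exact-test significance level (default 0.05).
#' @param fixed_threshold frequency above which an allele counts as fixed in
#'   a bulk (default 0.95).
#' @param high_parent `"A"` (default) or `"B"`: which parental code carries
#'   the trait-increasing alleles.
#' @return A `bsa_calls` data frame: marker, chrom, pos_cM, f_high, f_low,
#'   delta_f, p_value, class, segregating.
#' @export
classify_markers <- function(bulks, genotypes, delta_threshold = 0.4,
                             alpha = 0.05, fixed_threshold = 0.95,
                             high_parent = c("A", "B")) {
  high_parent <- match.arg(high_parent)
  map <- attr(genotypes, "map")
  miss <- setdiff(c(bulks$high_lines, bulks$low_lines), rownames(genotypes))
  if (length(miss))
    stop_protmap("bulk lines absent from genotypes: ",
                 paste(utils::head(miss, 5), collapse = ", "))
  hi <- .bulk_counts(genotypes, bulks$high_lines, high_parent)
  lo <- .bulk_counts(genotypes, bulks$low_lines, high_parent)
  f_high <- ifelse(hi$total > 0, hi$high / hi$total, NA)
  f_low <- ifelse(lo$total > 0, lo$high / lo$total, NA)
  C <- code_to_int(unclass(genotypes))
  seg <- apply(C, 2, function(g) length(unique(g[!is.na(g)])) > 1)
  p <- vapply(seq_along(f_high), function(j) {
    if (is.na(f_high[j]) || is.na(f_low[j])) return(NA_real_)
    tab <- matrix(c(hi$high[j], hi$total[j] - hi$high[j],
                    lo$high[j], lo$total[j] - lo$high[j]), 2, byrow = TRUE)
    stats::fisher.test(round(tab))$p.value
  }, numeric(1))
  delta <- f_high - f_low
  cls <- rep("uninformative", length(delta))
  cls[!is.na(delta) & delta >= delta_threshold & !is.na(p) & p <= alpha] <-
    "positive"
  fx_hi <- !is.na(delta) & f_high >= fixed_threshold & f_low >= fixed_threshold
  fx_lo <- !is.na(delta) & f_high <= 1 - fixed_threshold &
    f_low <= 1 - fixed_threshold
  cls[cls == "uninformative" & fx_hi] <- "fixed_high"
  cls[cls == "uninformative" & fx_lo] <- "fixed_low"
  res <- data.frame(marker = map$marker, chrom = map$chrom,
                    pos_cM = map$pos_cM, f_high = f_high, f_low = f_low,
                    delta_f = delta, p_value = p, class = cls,
                    segregating = seg, stringsAsFactors = FALSE)
  structure(res, population = bulks$population,
            class = c("bsa_calls", "data.frame"))
}

#' @export
print.bsa_calls <- function(x, ...) {
  cat("BSA calls [", attr(x, "population"), "]: ", nrow(x), " markers; ",
      sum(x$class == "positive"), " positive, ",
      sum(x$class == "fixed_high"), " fixed-high, ",
      sum(x$class == "fixed_low"), " fixed-low\n", sep = "")
  invisible(x)
}

#' Merge BSA-positive calls across populations into loci
#'
#' Single-linkage merges positive calls lying within `merge_window_cM` of
#' each other on the same chromosome into loci, then reports per-locus
#' status in every population: `positive`, `fixed_high`, `negative`
#' (segregating but not positive) or `not_segregating`. The support count is
#' positives + fixed-high populations, reflecting that fixation of the high
#' parent's allele is consistent with the locus mattering. Populations named
#' in `exclude_from_discovery` (e.g. a high x high cross) contribute status
#' but never seed a locus.
#'
#' @param calls named list of `bsa_calls` (one per population).
#' @param map a [genetic_map()] (for locus coordinates).
#' @param merge_window_cM merge distance (default 10).
#' @param exclude_from_discovery population names whose positive calls do
#'   not seed loci.
#' @return A `bsa_summary` data frame: one row per locus with chrom,
#'   interval, representative marker, per-population status columns and
#'   `support`.
#' @export
cross_population_summary <- function(calls, map, merge_window_cM = 10,
                                     exclude_from_discovery = character()) {
  if (!length(calls)) stop_protmap("need at least one population")
  if (is.null(names(calls)))
    names(calls) <- vapply(calls, function(x)
      attr(x, "population") %||% "pop", character(1))
  disc <- setdiff(names(calls), exclude_from_discovery)
  pos <- do.call(rbind, lapply(disc, function(p) {
    d <- calls[[p]]
    d <- d[d$class == "positive", c("marker", "chrom", "pos_cM", "delta_f")]
    if (nrow(d)) d$population <- p
    d
  }))
  if (is.null(pos) || !nrow(pos)) {
    out <- data.frame(locus = character(), chrom = character(),
                      start_cM = numeric(), end_cM = numeric(),
                      marker = character(), support = integer())
    return(structure(out, class = c("bsa_summary", "data.frame")))
  }
  pos <- pos[order(match(pos$chrom, attr(map, "chromosomes")), pos$pos_cM), ]
  grp <- cumsum(c(TRUE, pos$chrom[-1] != pos$chrom[-nrow(pos)] |
                    diff(pos$pos_cM) > merge_window_cM))
  loci <- lapply(split(pos, grp), function(d) {
    rep_m <- d$marker[which.max(abs(d$delta_f))]
    data.frame(chrom = d$chrom[1], start_cM = min(d$pos_cM),
               end_cM = max(d$pos_cM), marker = rep_m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  out$locus <- sprintf("L%02d", seq_len(nrow(out)))
  status <- matrix("", nrow(out), length(calls),
                   dimnames = list(NULL, names(calls)))
  for (p in names(calls)) {
    d <- calls[[p]]
    for (i in seq_len(nrow(out))) {
      in_loc <- d$chrom == out$chrom[i] &
        d$pos_cM >= out$start_cM[i] - merge_window_cM / 2 &
        d$pos_cM <= out$end_cM[i] + merge_window_cM / 2
      cl <- d$class[in_loc]
      status[i, p] <- if (!any(in_loc)) "not_segregating"
        else if (any(cl == "positive")) "positive"
        else if (any(cl == "fixed_high")) "fixed_high"
        else if (!any(d$segregating[in_loc])) "not_segregating"
        else "negative"
    }
  }
  out <- cbind(out[c("locus", "chrom", "start_cM", "end_cM", "marker")],
               as.data.frame(status, stringsAsFactors = FALSE))
  out$support <- rowSums(status == "positive" | status == "fixed_high")
  rownames(out) <- NULL
  structure(out, class = c("bsa_summary", "data.frame"))
}

#' @export
print.bsa_summary <- function(x, ...) {
  cat("BSA cross-population summary:", nrow(x), "locus/loci\n")
  if (nrow(x)) print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
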