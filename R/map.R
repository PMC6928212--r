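#' Construct a genetic map
#'
#' A genetic map is an ordered table of markers with centimorgan positions,
#' one or more chromosomes, a marker technology class and (optionally) a
#' physical anchor position in base pairs.
#'
#' @param marker character vector of marker names, unique genome-wide.
#' @param chrom chromosome identifier per marker.
#' @param pos_cM non-negative map position per marker; must be non-decreasing
#'   within a chromosome.
#' @param marker_class marker technology, one of `"SSR"`, `"DArT"`,
#'   `"DArTseq"`, `"SNP"` (recycled).
#' @param bp optional physical position (bp) per marker.
#'
#' @return A `genetic_map`: a data frame with columns `marker`, `chrom`,
#'   `pos_cM`, `marker_class` and optionally `bp`, ordered by chromosome and
#'   position, with the chromosome order kept in `attr(, "chromosomes")`.
#' @examples
#' gm <- genetic_map(paste0("M", 1:4), rep("Gm01", 4), c(0, 10, 20, 40))
#' chrom_lengths(gm)
#' @export
genetic_map <- function(marker, chrom, pos_cM,
                        marker_class = "SNP", bp = NULL) {
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  pos_cM <- as.numeric(pos_cM)
  if (anyDuplicated(marker))
    stop_protmap("duplicate marker name(s): ",
                 paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(is.na(pos_cM)) || any(pos_cM < 0))
    stop_protmap("pos_cM must be non-negative and non-missing")
  bad <- !marker_class %in% c("SSR", "DArT", "DArTseq", "SNP")
  if (any(bad)) stop_protmap("unknown marker_class: ",
                             paste(unique(marker_class[bad]), collapse = ", "))
  df <- data.frame(marker = marker, chrom = chrom, pos_cM = pos_cM,
                   marker_class = rep_len(as.character(marker_class),
                                          length(marker)),
                   stringsAsFactors = FALSE)
  if (!is.null(bp)) df$bp <- as.numeric(bp)
  chrs <- unique(chrom)
  for (cc in chrs) {
    p <- df$pos_cM[df$chrom == cc]
    if (is.unsorted(p)) {
      i <- which(diff(p) < 0)[1]
      off <- df$marker[df$chrom == cc][i + 1]
      stop_protmap("map positions decrease on ", cc, " at marker ", off)
    }
  }
  df <- df[order(match(df$chrom, chrs), df$pos_cM), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, chromosomes = chrs,
            class = c("genetic_map", "data.frame"))
}

#' @export
print.genetic_map <- function(x, ...) {
  chrs <- attr(x, "chromosomes")
  cat("Genetic map: ", nrow(x), " markers on ", length(chrs),
      " chromosome(s), ", round(sum(chrom_lengths(x)), 1), " cM total\n",
      sep = "")
  tab <- table(x$marker_class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Chromosome lengths of a genetic map
#'
#' @param map a [genetic_map()].
#' @return Named numeric vector of spanned cM per chromosome.
#' @export
chrom_lengths <- function(map) {
  vapply(split(map$pos_cM, factor(map$chrom, attr(map, "chromosomes"))),
         function(p) max(p) - min(p), numeric(1))
}

# Per-chromosome statistics of the 644-marker X4050-style framework map:
# marker counts by technology and mean inter-marker spacing (cM).
.x4050_map_stats <- data.frame(
  chrom = sprintf("Gm%02d", 1:20),
  linkage_group = c("D1a", "D1b", "N", "C1", "A1", "C2", "M", "A2", "K", "O",
                    "B1", "H", "F", "B2", "E", "J", "D2", "G", "L", "I"),
  n_ssr     = c(13, 14, 11, 10, 10,  8, 11, 17, 21, 11, 15,  9, 16, 10, 20, 11, 15, 13, 17, 16),
  n_dart    = c( 6, 13,  1,  5,  0,  6, 12,  0,  6,  1,  3,  2,  2,  1,  6, 16,  0,  7,  1,  2),
  n_dartseq = c( 9,  5, 20,  9, 10,  9, 16,  4, 22, 12,  8, 15, 23, 12, 22, 21,  9, 19, 19, 17),
  avg_cM    = c(7.0, 6.3, 3.7, 6.8, 7.0, 10.2, 4.8, 9.1, 4.6, 7.5,
                6.3, 5.7, 5.1, 5.6, 3.2, 2.9, 7.9, 4.7, 6.2, 3.6),
  stringsAsFactors = FALSE
)

#' Framework map skeleton for a ~640-marker soybean RIL map
#'
#' Builds a 20-chromosome genetic map whose per-chromosome marker counts
#' (SSR/DArT/DArTseq) and mean inter-marker spacing reproduce the published
#' per-chromosome statistics of the X4050 RIL framework map (639 markers as
#' tabulated). Markers are placed at the mean spacing, so the skeleton has
#' the published size and density but idealized uniform spacing; physical
#' anchors are assigned at 1 cM ~ 400 kb.
#'
#' @param step_scale multiplier on the per-chromosome mean spacing (default 1).
#' @return A [genetic_map()] with 639 markers on chromosomes Gm01..Gm20.
#' @examples
#' gm <- x4050_map_skeleton()
#' nrow(gm)
#' @export
x4050_map_skeleton <- function(step_scale = 1) {
  st <- .x4050_map_stats
  rows <- lapply(seq_len(nrow(st)), function(i) {
    n <- st$n_ssr[i] + st$n_dart[i] + st$n_dartseq[i]
    cls <- rep(c("SSR", "DArT", "DArTseq"),
               c(st$n_ssr[i], st$n_dart[i], st$n_dartseq[i]))
    # interleave classes along the chromosome
    cls <- cls[order(seq_along(cls) %% 3, seq_along(cls))]
    pos <- (seq_len(n) - 1) * st$avg_cM[i] * step_scale
    data.frame(marker = sprintf("%s_%s_%02d", st$chrom[i],
                                c(SSR = "ssr", DArT = "dart",
                                  DArTseq = "dseq")[cls], seq_len(n)),
               chrom = st$chrom[i], pos_cM = pos, marker_class = cls,
               bp = round(pos * 4e5) + 1, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  genetic_map(df$marker, df$chrom, df$pos_cM, df$marker_class, df$bp)
}

#' Read / write a genetic map as CSV
#'
#' The CSV dialect is `marker,chrom,cM[,class][,bp]`. Validation errors name
#' the offending marker.
#'
#' @param path file path.
#' @param map a [genetic_map()].
#' @return `read_genetic_map()` returns a [genetic_map()];
#'   `write_genetic_map()` returns `path` invisibly.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "cM")
  if (!all(need %in% names(df)))
    stop_protmap("map CSV must have columns ", paste(need, collapse = ", "))
  genetic_map(df$marker, df$chrom, df$cM,
              marker_class = df$class %||% "SNP", bp = df$bp)
}

#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(map, path) {
  out <- data.frame(marker = map$marker, chrom = map$chrom, cM = map$pos_cM,
                    class = map$marker_class)
  if (!is.null(map$bp)) out$bp <- map$bp
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
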