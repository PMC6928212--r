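# Readers and writers for the package's plain-text interchange formats:
# map CSV, phenotype CSV, RIL genotype TSV, HapMap-style panel TSV and
# VCF v4.2. Validation failures name the offending record.

#' Write / read a panel as HapMap-style TSV
#'
#' Columns: `marker`, `chrom`, `pos`, `alleles` (`ref/alt`), then one
#' two-letter genotype column per line (`NN` = missing).
#'
#' @param panel a [panel_geno()].
#' @param path file path.
#' @return `read_hapmap()` returns a [panel_geno()].
#' @export
write_hapmap <- function(panel, path) {
  info <- panel$snp_info
  gmat <- apply(panel$calls, 1, function(g) {
    out <- rep("NN", length(g))
    out[!is.na(g) & g == 0L] <- paste0(info$ref, info$ref)[!is.na(g) & g == 0L]
    out[!is.na(g) & g == 1L] <- paste0(info$ref, info$alt)[!is.na(g) & g == 1L]
    out[!is.na(g) & g == 2L] <- paste0(info$alt, info$alt)[!is.na(g) & g == 2L]
    out
  })
  df <- data.frame(marker = info$id, chrom = info$chrom, pos = info$bp,
                   alleles = paste0(info$ref, "/", info$alt),
                   gmat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hapmap
#' @export
read_hapmap <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  need <- c("marker", "chrom", "pos", "alleles")
  if (!all(need %in% names(df)))
    stop_protmap("HapMap TSV must start with columns ",
                 paste(need, collapse = ", "))
  al <- strsplit(df$alleles, "/", fixed = TRUE)
  ref <- vapply(al, `[`, character(1), 1)
  alt <- vapply(al, `[`, character(1), 2)
  lines <- setdiff(names(df), need)
  calls <- matrix(NA_integer_, length(lines), nrow(df),
                  dimnames = list(lines, df$marker))
  for (i in seq_along(lines)) {
    g <- df[[lines[i]]]
    code <- rep(NA_integer_, length(g))
    code[g == paste0(ref, ref)] <- 0L
    code[g == paste0(ref, alt) | g == paste0(alt, ref)] <- 1L
    code[g == paste0(alt, alt)] <- 2L
    bad <- is.na(code) & g != "NN"
    if (any(bad))
      stop_protmap("unknown genotype code '", g[which(bad)[1]],
                   "' for line ", lines[i], " at SNP ", df$marker[which(bad)[1]])
    calls[i, ] <- code
  }
  panel_geno(calls, data.frame(id = df$marker, chrom = df$chrom,
                               bp = as.numeric(df$pos), ref = ref, alt = alt,
                               stringsAsFactors = FALSE))
}

#' Write / read a panel as VCF v4.2
#'
#' `write_vcf()` emits a minimal genotype-only VCF. `read_vcf()` parses it
#' via the vcfR package.
#'
#' @param panel a [panel_geno()].
#' @param path file path.
#' @return `read_vcf()` returns a [panel_geno()].
#' @export
write_vcf <- function(panel, path) {
  info <- panel$snp_info
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=protmap",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(panel$calls)),
                   collapse = "\t"), con)
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(info)), function(j) {
    g <- panel$calls[, j]
    gs <- ifelse(is.na(g), "./.", gt[as.character(g)])
    paste(c(info$chrom[j], format(info$bp[j], scientific = FALSE),
            info$id[j], info$ref[j], info$alt[j], ".", "PASS", ".", "GT",
            gs), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_protmap("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  panel_geno(t(code),
             data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                        bp = as.numeric(fix[, "POS"]), ref = fix[, "REF"],
                        alt = fix[, "ALT"], stringsAsFactors = FALSE))
}

#' Write / read RIL genotypes as TSV
#'
#' One row per line, one column per marker, codes `A`/`H`/`B`/`NA`.
#'
#' @param genotypes a [ril_geno()].
#' @param path file path.
#' @param map the [genetic_map()] for the markers (reading).
#' @param generation derived generation (reading).
#' @return `read_ril_tsv()` returns a [ril_geno()].
#' @export
write_ril_tsv <- function(genotypes, path) {
  df <- data.frame(line = rownames(genotypes),
                   unclass(genotypes), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ril_tsv
#' @export
read_ril_tsv <- function(path, map, generation = 5) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = "NA")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line
  if (!identical(colnames(m), map$marker)) {
    miss <- setdiff(map$marker, colnames(m))
    if (length(miss)) stop_protmap("TSV lacks marker(s): ",
                                   paste(utils::head(miss, 5), collapse = ", "))
    m <- m[, map$marker, drop = FALSE]
  }
  ril_geno(m, map, generation)
}

#' Write / read phenotype records as CSV
#'
#' Columns `line,trial,protein[,oil][,yield]`; protein and oil must lie in
#' 0..100.
#'
#' @param phenotypes a `phenotype_records` data frame.
#' @param path file path.
#' @return `read_phenotypes()` returns a `phenotype_records` data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(as.data.frame(phenotypes), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("line", "trial", "protein") %in% names(df)))
    stop_protmap("phenotype CSV needs columns line, trial, protein")
  for (tr in intersect(c("protein", "oil"), names(df))) {
    bad <- !is.na(df[[tr]]) & (df[[tr]] < 0 | df[[tr]] > 100)
    if (any(bad))
      stop_protmap(tr, " out of [0,100] for line ", df$line[which(bad)[1]],
                   " trial ", df$trial[which(bad)[1]])
  }
  structure(df, aggregation = "mean",
            class = c("phenotype_records", "data.frame"))
}

#' Read an anchors / known-regions table
#'
#' CSV with columns `name,chrom,bp[,type]` or `name,chrom,start,end[,type]`.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_anchors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "chrom") %in% names(df)) ||
      !any(c("bp", "start") %in% names(df)))
    stop_protmap("anchors CSV needs name, chrom and bp (or start/end)")
  df
}

#' Load a typed dataset from file
#'
#' Dispatches on `kind`: `"panel"` (HapMap TSV or VCF by extension),
#' `"ril"` (TSV; needs `map`), `"map"` (CSV), `"phenotype"` (CSV),
#' `"anchors"` (CSV). All type invariants are validated on load.
#'
#' @param path file path.
#' @param kind dataset kind.
#' @param ... passed to the specific reader (e.g. `map`, `generation`).
#' @return The typed object.
#' @export
load_dataset <- function(path, kind = c("panel", "ril", "map", "phenotype",
                                        "anchors"), ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_protmap("file not found: ", path)
  switch(kind,
         panel = if (grepl("\\.vcf(\\.gz)?$", path)) read_vcf(path)
                 else read_hapmap(path),
         ril = read_ril_tsv(path, ...),
         map = read_genetic_map(path),
         phenotype = read_phenotypes(path),
         anchors = read_anchors(path))
}
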