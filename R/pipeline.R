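# End-to-end orchestration: simulate -> scan -> bsa -> retain, driven by a
# flat configuration list (YAML on disk), with deterministic outputs and a
# provenance stamp.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every parameter at its default.
#' Values supplied by the user (or a YAML file) are merged over these.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @return Named list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    stages = c("simulate", "scan", "bsa", "retain"),
    # simulation
    n_lines = 100, derived_generation = 5, n_trials = 3,
    qtl_chrom = c("Gm20", "Gm15", "Gm01", "Gm16"),
    qtl_fraction = c(0.378, 0.145, 0.088, 0.082),
    epistasis_chrom = c("Gm05", "Gm20"), epistasis_fraction = 0.006,
    map_step_scale = 1,
    bsa_populations = 4, bsa_high_high = TRUE,
    panel_lines = 150, snp_density = 200, n_rare = 60,
    rare_frequency = NULL,               # default 1 / panel_lines
    n_derivatives = 7,
    retention_probability_outside = 0.25,
    # scan
    scan_mode = "SIM", step_cM = 1, n_permutations = 1000, alpha = 0.05,
    # bsa
    tail_fraction = 0.1, min_bulk = 8, delta_threshold = 0.4,
    bsa_alpha = 0.05, fixed_threshold = 0.95, merge_window_cM = 10,
    # retention
    max_panel_frequency = 0.02, min_ratio = 0.66, min_informative = 4,
    max_gap_bp = 5e5, min_snps = 2, link_distance_bp = 5e5,
    novel_only_strict = TRUE
  )
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; keys override [default_config()].
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  cfg
}

config_digest <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config[order(names(config))], tf)
  unname(tools::md5sum(tf))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages on simulated data with known truth:
#' `simulate` builds the map, a RIL population with phenotypes, BSA
#' populations and a diversity panel with pedigree descent; `scan` runs the
#' permutation-thresholded genome scan plus the anchored re-scan; `bsa`
#' builds bulks, classifies markers and summarizes across populations;
#' `retain` runs the rare-allele retention scan at both the broad and strict
#' ratio and writes the genomic blocks. All outputs are plain text under
#' `out_dir`; `provenance.json` carries the config digest, seed registry and
#' package version, so identical configurations give identical outputs.
#'
#' @param config list from [default_config()] / [read_config()], or a path
#'   to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = "protmap_out") {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  seeds <- derive_seeds(cfg$seed, 10)
  res <- list()
  cat("", file = log_path)

  map <- x4050_map_skeleton(cfg$map_step_scale)
  write_genetic_map(map, file.path(out_dir, "map.csv"))

  if ("simulate" %in% cfg$stages || any(c("scan", "bsa") %in% cfg$stages)) {
    log("simulate: RIL population (n=", cfg$n_lines, ", F",
        cfg$derived_generation, "-derived), seed ", seeds[1])
    loci <- data.frame(chrom = cfg$qtl_chrom,
                       pos_cM = vapply(cfg$qtl_chrom, function(cc)
                         map$pos_cM[.mid_marker(map, cc)], numeric(1)))
    ep <- NULL
    if (length(cfg$epistasis_chrom) == 2) {
      extra <- setdiff(cfg$epistasis_chrom, cfg$qtl_chrom)
      if (length(extra)) {
        loci <- rbind(loci, data.frame(
          chrom = extra,
          pos_cM = vapply(extra, function(cc)
            map$pos_cM[.mid_marker(map, cc)], numeric(1))))
      }
      ep <- data.frame(locus_i = match(cfg$epistasis_chrom[1], loci$chrom),
                       locus_j = match(cfg$epistasis_chrom[2], loci$chrom),
                       target_variance_fraction = cfg$epistasis_fraction)
    }
    tv <- c(cfg$qtl_fraction, rep(0, nrow(loci) - length(cfg$qtl_fraction)))
    model <- qtl_model(loci, epistatic_pairs = ep,
                       target_variance_fractions = tv)
    ril <- simulate_ril_population(map, cfg$n_lines, cfg$derived_generation,
                                   seed = seeds[1])
    phen <- simulate_phenotypes(ril, model, cfg$n_trials, seed = seeds[2])
    write_ril_tsv(ril, file.path(out_dir, "ril_genotypes.tsv"))
    write_phenotypes(phen, file.path(out_dir, "phenotypes.csv"))
    res$ril <- ril; res$phenotypes <- phen; res$model <- model
  }

  if ("scan" %in% cfg$stages) {
    log("scan: ", cfg$scan_mode, " with ", cfg$n_permutations,
        " permutations")
    thr <- permutation_threshold(res$ril, res$phenotypes,
                                 mode = cfg$scan_mode,
                                 n_permutations = cfg$n_permutations,
                                 alpha = cfg$alpha, step_cM = cfg$step_cM,
                                 seed = seeds[3])
    sc <- qtl_scan(res$ril, res$phenotypes, mode = cfg$scan_mode,
                   step_cM = cfg$step_cM, threshold = as.numeric(thr))
    prof <- as.data.frame(sc)
    prof$above_threshold <- prof$ts >= as.numeric(thr)
    utils::write.table(prof, file.path(out_dir, "scan_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pk <- attr(sc, "peaks")
    utils::write.table(pk, file.path(out_dir, "scan_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(pk)) {
      anchor <- pk[which.max(pk$ts), ]
      an <- anchored_scan(res$ril, res$phenotypes,
                          list(chrom = anchor$chrom, pos_cM = anchor$pos_cM),
                          step_cM = cfg$step_cM)
      utils::write.table(as.data.frame(an),
                         file.path(out_dir, "anchored_scan.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$anchored <- an
    }
    res$scan <- sc; res$threshold <- thr
  }

  if ("bsa" %in% cfg$stages) {
    n_pop <- cfg$bsa_populations + as.integer(isTRUE(cfg$bsa_high_high))
    log("bsa: ", n_pop, " populations")
    calls <- list()
    pops <- character(0)
    for (i in seq_len(n_pop)) {
      hh <- isTRUE(cfg$bsa_high_high) && i == n_pop
      pop <- if (hh) "HxH" else sprintf("P%d", i)
      rg <- simulate_ril_population(map, cfg$n_lines,
                                    cfg$derived_generation,
                                    seed = seeds[4] + i)
      # a high x high cross segregates for none of the protein loci
      mdl <- if (hh) qtl_model(res$model$loci[0, , drop = FALSE])
             else res$model
      ph <- simulate_phenotypes(rg, mdl, cfg$n_trials, seed = seeds[5] + i)
      bp <- make_bulks(ph, cfg$tail_fraction, cfg$min_bulk, population = pop)
      cl <- classify_markers(bp, rg, cfg$delta_threshold, cfg$bsa_alpha,
                             cfg$fixed_threshold)
      utils::write.table(as.data.frame(cl),
                         file.path(out_dir, sprintf("bsa_calls_%s.tsv", pop)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      calls[[pop]] <- cl
      pops <- c(pops, pop)
    }
    summ <- cross_population_summary(
      calls, map, cfg$merge_window_cM,
      exclude_from_discovery = intersect("HxH", pops))
    utils::write.table(as.data.frame(summ),
                       file.path(out_dir, "bsa_loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$bsa <- calls; res$bsa_summary <- summ
  }

  if ("retain" %in% cfg$stages) {
    log("retain: panel of ", cfg$panel_lines, " lines, ",
        cfg$snp_density, " SNPs/chromosome + ", cfg$n_rare, " rare")
    pan <- simulate_panel(
      cfg$panel_lines, map, cfg$snp_density,
      donor_rare_config = list(
        n_rare = cfg$n_rare,
        rare_frequency = cfg$rare_frequency %||% (1 / cfg$panel_lines)),
      seed = seeds[6])
    derivs <- sprintf("Deriv%02d", seq_len(cfg$n_derivatives))
    ped <- pedigree(nodes = c("Donor", "V002", "V003", "V004", derivs),
                    parents = stats::setNames(
                      rep(list(c("Donor", "V002")), length(derivs)), derivs),
                    donor = "Donor", recurrent_parent = "V002",
                    derivatives = derivs, low_lines = c("V003", "V004"))
    clus <- attr(pan, "rare_clusters")
    blocks_true <- do.call(rbind, lapply(clus, function(ids) {
      i <- match(ids, pan$snp_info$id)
      data.frame(chrom = pan$snp_info$chrom[i[1]],
                 start = min(pan$snp_info$bp[i]),
                 end = max(pan$snp_info$bp[i]))
    }))
    pan <- simulate_descent(pan, ped, blocks_true,
                            cfg$retention_probability_outside,
                            seed = seeds[7])
    write_hapmap(pan, file.path(out_dir, "panel.hmp.tsv"))
    cand <- rare_allele_scan(pan, "Donor", cfg$max_panel_frequency,
                             exclude = derivs)
    filt <- contrast_filter(cand, pan, "V002", c("V003", "V004"))
    for (ratio in unique(c(cfg$min_ratio, 1.0))) {
      rec <- retention_filter(filt, pan, derivs, ratio,
                              cfg$min_informative)
      blk <- build_blocks(rec, cfg$max_gap_bp, cfg$min_snps)
      if (ratio == 1 && isTRUE(cfg$novel_only_strict) &&
          cfg$min_ratio < 1 && nrow(blk)) {
        broad <- res$retention_blocks
        if (!is.null(broad) && nrow(broad)) {
          dup <- vapply(seq_len(nrow(blk)), function(i)
            any(broad$chrom == blk$chrom[i] &
                  broad$start <= blk$end[i] & broad$end >= blk$start[i]),
            logical(1))
          blk <- blk[!dup, , drop = FALSE]
        }
      }
      tag <- if (ratio == 1) "strict" else "broad"
      write_blocks(blk,
                   bed = file.path(out_dir, sprintf("blocks_%s.bed", tag)),
                   tsv = file.path(out_dir, sprintf("blocks_%s.tsv", tag)))
      if (ratio == cfg$min_ratio) res$retention_blocks <- blk
      if (ratio == 1) res$retention_blocks_strict <- blk
    }
    res$panel <- pan
    res$true_blocks <- blocks_true
  }

  prov <- list(package = "protmap",
               version = as.character(utils::packageVersion("protmap")),
               config_digest = config_digest(cfg),
               seed = cfg$seed,
               stage_seeds = as.list(stats::setNames(
                 seeds, paste0("s", seq_along(seeds)))))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("done")
  invisible(res)
}
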