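# Dosage of the parent-2 allele at a marker: A=-1, H=0, B=+1.
marker_dosage <- function(genotypes, chrom, pos_cM, tol = 1e-6) {
  map <- attr(genotypes, "map")
  i <- which(map$chrom == chrom & abs(map$pos_cM - pos_cM) <= tol)
  if (!length(i))
    stop_protmap("no marker at ", chrom, ":", pos_cM, " cM")
  as.vector(code_to_int(unclass(genotypes)[, i[1]])) - 2
}

#' Simulate multi-trial phenotypes under a QTL model
#'
#' Trait value = population mean + additive locus effects (dosage coded
#' -1/0/+1) + epistatic products + a common trial effect + a within-trial
#' residual, over `n_trials` balanced trials. When the model carries target
#' variance fractions, additive (and epistatic) effects are solved against
#' the empirical dosage variances of this population so that each locus's
#' marginal share of the line-mean variance matches its target in
#' expectation. By default the trait-increasing alleles come from parent 1
#' (code `"A"`), matching a high x low protein cross with the high parent
#' listed first.
#'
#' @param genotypes a [ril_geno()].
#' @param model a [qtl_model()]; each locus must coincide with a map marker.
#' @param n_trials number of balanced trials (default 3).
#' @param effect_sign `-1` (default) if parent 1 carries the trait-increasing
#'   alleles, `+1` for parent 2.
#' @param seed integer seed.
#' @return A `phenotype_records` data frame with columns `line`, `trial`,
#'   `protein`, `oil`, `yield`; realized effects are in `attr(, "effects")`.
#' @examples
#' gm <- genetic_map(paste0("M", 1:5), "Gm01", c(0, 20, 40, 60, 80))
#' rg <- simulate_ril_population(gm, 50, seed = 1)
#' m <- qtl_model(data.frame(chrom = "Gm01", pos_cM = 40),
#'                target_variance_fractions = 0.6)
#' ph <- simulate_phenotypes(rg, m, seed = 2)
#' @export
simulate_phenotypes <- function(genotypes, model, n_trials = 3,
                                effect_sign = -1, seed = NULL) {
  loci <- model$loci
  n <- nrow(genotypes)
  X <- if (nrow(loci)) {
    vapply(seq_len(nrow(loci)), function(i)
      marker_dosage(genotypes, loci$chrom[i], loci$pos_cM[i]), numeric(n))
  } else matrix(0, n, 0)
  X[is.na(X)] <- 0   # missing causal calls contribute the population mean
  pairs <- model$epistatic_pairs
  W <- if (!is.null(pairs) && nrow(pairs)) {
    vapply(seq_len(nrow(pairs)), function(k)
      X[, pairs$locus_i[k]] * X[, pairs$locus_j[k]], numeric(n))
  } else matrix(0, n, 0)

  sigma_m2 <- model$residual_sd^2 / n_trials   # line-mean residual variance
  if (!is.null(model$target_variance_fractions)) {
    tv <- model$target_variance_fractions
    tw <- if (ncol(W)) pairs$target_variance_fraction %||% rep(0, ncol(W))
          else numeric(0)
    Tsum <- sum(tv) + sum(tw)
    if (Tsum >= 1) stop_protmap("variance fractions must sum to < 1")
    V <- sigma_m2 / (1 - Tsum)
    vx <- apply(X, 2, stats::var)
    if (any(vx[tv > 0] <= 0))
      stop_protmap("a target locus is monomorphic in this population")
    a <- effect_sign * sqrt(tv * V / pmax(vx, 1e-12))
    a[tv == 0] <- 0
    w <- if (ncol(W)) {
      vw <- apply(W, 2, stats::var)
      ifelse(tw > 0, sqrt(tw * V / pmax(vw, 1e-12)), 0)
    } else numeric(0)
  } else {
    a <- loci$additive_effect %||% numeric(0)
    w <- if (ncol(W)) pairs$interaction_effect else numeric(0)
  }
  g <- as.vector(X %*% a) + (if (ncol(W)) as.vector(W %*% w) else 0)

  with_seed(seed, {
    trial_eff <- stats::rnorm(n_trials, 0, model$trial_effect_sd)
    recs <- do.call(rbind, lapply(seq_len(n_trials), function(t) {
      prot <- model$population_mean + g + trial_eff[t] +
        stats::rnorm(n, 0, model$residual_sd)
      data.frame(line = rownames(genotypes), trial = sprintf("T%02d", t),
                 protein = prot,
                 oil = 62 - 0.45 * prot + stats::rnorm(n, 0, 0.5),
                 yield = stats::rnorm(n, 3500, 300),
                 stringsAsFactors = FALSE)
    }))
    rownames(recs) <- NULL
    structure(recs, effects = list(additive = a, interaction = w,
                                   genetic_value = stats::setNames(g, rownames(genotypes))),
              aggregation = "mean",
              class = c("phenotype_records", "data.frame"))
  })
}

#' Per-line trait means over trials
#'
#' @param phenotypes a `phenotype_records` data frame (or any data frame with
#'   `line` and trait columns).
#' @param trait trait column name (default `"protein"`).
#' @return Named numeric vector of line means (arithmetic mean over trials,
#'   which equals the least-squares mean under balanced trials).
#' @export
line_means <- function(phenotypes, trait = "protein") {
  tapply(phenotypes[[trait]], phenotypes$line, mean, na.rm = TRUE)
}
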