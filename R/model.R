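#' Describe a breeding pedigree
#'
#' A light container for the pedigree structure behind a donor line and its
#' descendants: named nodes, each with zero or two parents, an operation
#' label, and designated roles (donor, recurrent parent, derivative
#' cultivars, low-protein contrast lines).
#'
#' @param nodes character vector of individual names.
#' @param parents named list: for each non-founder node, a character vector of
#'   its two parents. Founders are omitted or `NULL`.
#' @param operations named character vector per node, from
#'   `cross`, `backcross`, `self`, `selection_for_trait` (free-form suffixes
#'   such as `"self x4"` are allowed).
#' @param donor,recurrent_parent single node names.
#' @param derivatives character vector (>= 1) of derived cultivar nodes.
#' @param low_lines character vector of low-trait contrast lines.
#' @return A `pedigree` object (list).
#' @examples
#' ped <- pedigree(
#'   nodes = c("Donor", "Recurrent", "Cultivar", "Derived1"),
#'   parents = list(Cultivar = c("Donor", "Recurrent"),
#'                  Derived1 = c("Cultivar", "Recurrent")),
#'   donor = "Donor", recurrent_parent = "Recurrent",
#'   derivatives = "Derived1")
#' @export
pedigree <- function(nodes, parents = list(), operations = NULL,
                     donor, recurrent_parent, derivatives,
                     low_lines = character()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_protmap("duplicate pedigree node names")
  for (nm in names(parents)) {
    pp <- parents[[nm]]
    if (!is.null(pp) && (length(pp) != 2 || !all(pp %in% nodes)))
      stop_protmap("node ", nm, " must have exactly 2 parents drawn from nodes")
  }
  roles <- c(donor, recurrent_parent, derivatives, low_lines)
  if (!all(roles %in% nodes))
    stop_protmap("pedigree roles must refer to existing nodes")
  if (length(derivatives) < 1) stop_protmap("need at least one derivative")
  # acyclicity: iteratively peel founders
  left <- nodes
  repeat {
    founders <- left[vapply(left, function(n)
      is.null(parents[[n]]) || !any(parents[[n]] %in% left), logical(1))]
    if (!length(founders)) stop_protmap("pedigree contains a cycle")
    left <- setdiff(left, founders)
    if (!length(left)) break
  }
  structure(list(nodes = nodes, parents = parents,
                 operations = operations, donor = donor,
                 recurrent_parent = recurrent_parent,
                 derivatives = as.character(derivatives),
                 low_lines = as.character(low_lines)),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", length(x$nodes), "nodes; donor =", x$donor,
      "; recurrent parent =", x$recurrent_parent, "\n")
  cat("  derivatives:", paste(x$derivatives, collapse = ", "), "\n")
  if (length(x$low_lines))
    cat("  low-trait contrast lines:", paste(x$low_lines, collapse = ", "),
        "\n")
  invisible(x)
}

#' Specify a QTL architecture for phenotype simulation
#'
#' Defines additive loci and epistatic pairs on a genetic map, either through
#' explicit effects (trait units per dosage unit) or through target fractions
#' of the phenotypic variance among line means, which
#' [simulate_phenotypes()] realizes by solving for the effects against the
#' empirical dosage variances of the simulated population.
#'
#' @param loci data frame with columns `chrom`, `pos_cM` and either
#'   `additive_effect` or nothing (when `target_variance_fractions` is used).
#' @param epistatic_pairs optional data frame with columns `locus_i`,
#'   `locus_j` (row indices into `loci`) and either `interaction_effect` or
#'   `target_variance_fraction`.
#' @param target_variance_fractions optional numeric, one per locus, each in
#'   `[0, 1]`; together with any epistatic target fractions they must sum to
#'   at most 1.
#' @param population_mean trait mean (percent protein; default 44, midway
#'   between high-protein parents near 48 and low-protein parents near 40).
#' @param residual_sd within-trial residual standard deviation (trait units).
#' @param trial_effect_sd standard deviation of the common trial effect.
#' @return A `qtl_model` object.
#' @examples
#' gm <- x4050_map_skeleton()
#' m <- qtl_model(data.frame(chrom = "Gm20", pos_cM = 36),
#'                target_variance_fractions = 0.6)
#' @export
qtl_model <- function(loci, epistatic_pairs = NULL,
                      target_variance_fractions = NULL,
                      population_mean = 44, residual_sd = 2.4,
                      trial_effect_sd = 0.8) {
  loci <- as.data.frame(loci)
  if (!all(c("chrom", "pos_cM") %in% names(loci)))
    stop_protmap("loci need columns chrom and pos_cM")
  tv <- target_variance_fractions
  if (!is.null(tv)) {
    if (length(tv) != nrow(loci))
      stop_protmap("one target variance fraction per locus required")
    if (any(tv < 0 | tv > 1)) stop_protmap("variance fractions must be in [0,1]")
  }
  tot <- sum(tv %||% 0)
  if (!is.null(epistatic_pairs)) {
    epistatic_pairs <- as.data.frame(epistatic_pairs)
    tot <- tot + sum(epistatic_pairs$target_variance_fraction %||% 0)
  }
  if (tot > 1) stop_protmap("variance fractions sum to ", round(tot, 3),
                            " > 1; not realizable")
  structure(list(loci = loci, epistatic_pairs = epistatic_pairs,
                 target_variance_fractions = tv,
                 population_mean = population_mean,
                 residual_sd = residual_sd,
                 trial_effect_sd = trial_effect_sd),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat("QTL model:", nrow(x$loci), "locus/loci")
  if (!is.null(x$epistatic_pairs))
    cat(",", nrow(x$epistatic_pairs), "epistatic pair(s)")
  cat("\n  mean =", x$population_mean, "; residual sd =", x$residual_sd,
      "; trial sd =", x$trial_effect_sd, "\n")
  if (!is.null(x$target_variance_fractions))
    cat("  target variance fractions:",
        paste(round(x$target_variance_fractions, 3), collapse = ", "), "\n")
  invisible(x)
}
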