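#' Two-deme demography configuration
#'
#' Describes the demographic model used by [simulate_two_pop()]: an ancestral
#' population (optionally with one instantaneous step expansion) that splits
#' into two demes A and B of equal size `split_time` generations before
#' present, connected from the split onwards by symmetric migration.
#'
#' The defaults emulate a pair of neighbouring European sub-populations:
#' 10,000 haplotypes (5,000 diploid individuals) per deme, an 80-generation
#' split, and an ancestral effective size chosen so that nucleotide diversity
#' (`2 * ancestral_haplotypes * mutation_rate`) matches the ~0.001/bp typical
#' of human European samples.  `region_length` is calibrated so that a
#' 2,000-individual case/control sample carries on the order of 31 analyzed
#' rare variants per gene.
#'
#' @param split_time_generations generations before present at which the two
#'   demes split from the ancestral population.
#' @param deme_haplotypes haplotypes per deme (must be even; half as many
#'   diploid individuals).
#' @param migration_rate symmetric per-haplotype per-generation migration
#'   probability, applied from the split to the present; in `[0, 0.5]`.
#' @param ancestral_haplotypes effective size (haplotypes) of the ancestral
#'   population.
#' @param expansion optional `list(time = , haplotypes = )`: further back than
#'   `time` generations the ancestral size is `haplotypes` (a single step
#'   expansion when `haplotypes < ancestral_haplotypes`).
#' @param region_length_bp simulated gene length in bp; positions are 1-based
#'   within `[1, region_length_bp]`.
#' @param mutation_rate per-bp per-generation mutation rate.
#' @param recombination_rate accepted for completeness; within-gene
#'   recombination is not modelled and the value must be 0 (genes are
#'   unlinked, i.e. free recombination between replicates).
#' @param n_genes number of independent gene panels to simulate.
#'
#' @return An object of class `demography_config`.
#' @examples
#' demography_config(migration_rate = 0.01, n_genes = 2)
#' @export
demography_config <- function(split_time_generations = 80L,
                              deme_haplotypes = 10000L,
                              migration_rate = 0.01,
                              ancestral_haplotypes = 33334L,
                              expansion = NULL,
                              region_length_bp = 10750L,
                              mutation_rate = 1.5e-8,
                              recombination_rate = 0,
                              n_genes = 1L) {
  if (!is_count(split_time_generations) || split_time_generations < 0)
    stopf("split_time_generations must be a non-negative integer")
  if (!is_count(deme_haplotypes) || deme_haplotypes < 2 || deme_haplotypes %% 2 != 0)
    stopf("deme_haplotypes must be a positive even integer")
  if (!is.numeric(migration_rate) || migration_rate < 0 || migration_rate > 0.5)
    stopf("migration_rate must lie in [0, 0.5]")
  if (!is_count(ancestral_haplotypes) || ancestral_haplotypes < 2)
    stopf("ancestral_haplotypes must be a positive integer")
  if (!is.null(expansion)) {
    if (!is.list(expansion) || is.null(expansion$time) || is.null(expansion$haplotypes))
      stopf("expansion must be list(time =, haplotypes =)")
    if (expansion$time <= split_time_generations)
      stopf("expansion$time must predate the split")
  }
  if (!is_count(region_length_bp) || region_length_bp < 1)
    stopf("region_length_bp must be a positive integer")
  if (!is.numeric(mutation_rate) || mutation_rate <= 0)
    stopf("mutation_rate must be positive")
  if (!identical(as.numeric(recombination_rate), 0))
    stopf("within-gene recombination is not modelled; recombination_rate must be 0")
  if (!is_count(n_genes) || n_genes < 1) stopf("n_genes must be a positive integer")
  structure(list(
    split_time_generations = as.integer(split_time_generations),
    deme_haplotypes = as.integer(deme_haplotypes),
    migration_rate = as.numeric(migration_rate),
    ancestral_haplotypes = as.integer(ancestral_haplotypes),
    expansion = expansion,
    region_length_bp = as.integer(region_length_bp),
    mutation_rate = as.numeric(mutation_rate),
    recombination_rate = 0,
    n_genes = as.integer(n_genes)
  ), class = "demography_config")
}

#' @export
print.demography_config <- function(x, ...) {
  cat("Two-deme demography\n")
  cat(sprintf("  split: %d generations ago; %d haplotypes/deme; migration %g\n",
              x$split_time_generations, x$deme_haplotypes, x$migration_rate))
  cat(sprintf("  ancestral: %d haplotypes%s\n", x$ancestral_haplotypes,
              if (is.null(x$expansion)) "" else
                sprintf(" (%d before generation %g)", x$expansion$haplotypes, x$expansion$time)))
  cat(sprintf("  gene: %d bp, mu = %g; %d gene(s)\n",
              x$region_length_bp, x$mutation_rate, x$n_genes))
  invisible(x)
}

#' Disease effect model for the alternative hypothesis
#'
#' Under H1 the disease status of a candidate individual with rare-variant
#' genotypes `x` is Bernoulli with `logit(P(Y = 1 | x)) = alpha0 + beta'x`,
#' where a fraction `prop_deleterious` of rare variants (chosen at random)
#' carries `beta = log(odds_ratio)` and the remainder 0.
#'
#' @param prop_deleterious fraction of rare variants that are deleterious.
#' @param odds_ratio per-allele odds ratio of a deleterious variant.
#' @param alpha0 baseline log-odds of disease. With fixed case/control quotas
#'   the baseline prevalence affects only sampling efficiency, not the target
#'   estimands; the default corresponds to a 10% prevalence.
#' @return An object of class `effect_model`.
#' @examples
#' effect_model()
#' @export
effect_model <- function(prop_deleterious = 0.5, odds_ratio = 1.5,
                         alpha0 = qlogis(0.1)) {
  if (prop_deleterious < 0 || prop_deleterious > 1)
    stopf("prop_deleterious must lie in [0, 1]")
  if (odds_ratio <= 0) stopf("odds_ratio must be positive")
  structure(list(prop_deleterious = prop_deleterious,
                 odds_ratio = odds_ratio, alpha0 = alpha0),
            class = "effect_model")
}

#' @export
print.effect_model <- function(x, ...) {
  cat(sprintf("Effect model: %g%% of rare variants deleterious at OR = %g (alpha0 = %.3f)\n",
              100 * x$prop_deleterious, x$odds_ratio, x$alpha0))
  invisible(x)
}
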