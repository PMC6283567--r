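#' Simulation scenario
#'
#' One cell of the study design: a migration rate, a percentage of controls
#' drawn from deme B, the hypothesis (H0 for type-I error, H1 for power),
#' sample sizes, the methods to run, and the stratification correction.
#'
#' Corrections are disabled when all controls come from deme B
#' (`pct_controls_B = 100`): the leading components may then explain the
#' phenotype completely, leaving no genetic effect testable (the null-model
#' fit separates).
#'
#' @param migration_rate symmetric migration rate of the demography.
#' @param pct_controls_B percentage of controls drawn from deme B.
#' @param hypothesis `"H0"` or `"H1"`.
#' @param n_cases,n_controls sample sizes.
#' @param methods methods to evaluate (subset of [rv_methods()]).
#' @param correction `"none"`, `"pca_model"` or `"pca_perm"`.
#' @param n_pcs number of leading principal components used by corrections.
#' @param replicates number of replicate genes.
#' @param effects an [effect_model()] (H1).
#' @param rare_threshold deme-A MAF threshold defining rare variants.
#' @return An `rv_scenario`.
#' @export
scenario <- function(migration_rate = 0.01, pct_controls_B = 0,
                     hypothesis = c("H0", "H1"),
                     n_cases = 1000L, n_controls = 1000L,
                     methods = c("CAST", "Sum", "SKAT"),
                     correction = c("none", "pca_model", "pca_perm"),
                     n_pcs = 2L, replicates = 100L,
                     effects = effect_model(), rare_threshold = 0.01) {
  hypothesis <- match.arg(hypothesis)
  correction <- match.arg(correction)
  if (pct_controls_B < 0 || pct_controls_B > 100)
    stopf("pct_controls_B must lie in [0, 100]")
  if (pct_controls_B == 100 && correction != "none")
    stopf("corrections are disabled when 100%% of controls come from deme B")
  methods <- vapply(methods, function(m) match.arg(m, rv_methods()), character(1))
  structure(list(migration_rate = migration_rate,
                 pct_controls_B = pct_controls_B,
                 hypothesis = hypothesis,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 methods = unname(methods),
                 correction = correction,
                 n_pcs = as.integer(n_pcs),
                 replicates = as.integer(replicates),
                 effects = effects,
                 rare_threshold = rare_threshold),
            class = "rv_scenario")
}

#' @export
print.rv_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s, m = %g, %d%% controls from B, %d+%d, correction %s, %d replicates\n",
              x$hypothesis, x$migration_rate, x$pct_controls_B,
              x$n_cases, x$n_controls, x$correction, x$replicates))
  invisible(x)
}

#' Reference panel of common variants for the structure corrections
#'
#' Simulates `n_genes` independent genes under the scenario's demography and
#' keeps, for each, the LD-pruned common variants (deme-A MAF >= `maf_min`,
#' pairwise `r2 < r2_max` among the deme-A individuals).  Per replicate,
#' sampled individuals receive genotypes from this fixed panel (each
#' individual is an unused haplotype pair of its deme, drawn without
#' replacement), and the leading principal components of those genotypes
#' feed the stratification corrections — mirroring a PCA on genome-wide
#' common variants rather than on the single tested gene.
#'
#' @param demography a [demography_config()].
#' @param n_genes number of reference genes.
#' @param seed integer seed.
#' @param maf_min,r2_max pruning parameters.
#' @return A `structure_reference` with per-gene pruned haplotype matrices.
#' @export
structure_reference <- function(demography, n_genes = 150L, seed = NULL,
                                maf_min = 0.05, r2_max = 0.2) {
  dem <- demography
  dem$n_genes <- 1L
  genes <- with_seed(seed, lapply(seq_len(n_genes), function(g) {
    panel <- simulate_two_pop(dem)[[1]]
    maf <- panel_maf(panel, "A")
    common <- which(classify_variants(maf)$common)
    if (length(common) == 0) return(NULL)
    # prune within deme A, the reference population for variant definitions
    nA_ind <- panel$n_hap_A %/% 2L
    XA <- panel$H[seq(1, panel$n_hap_A, by = 2), common, drop = FALSE] +
          panel$H[seq(2, panel$n_hap_A, by = 2), common, drop = FALSE]
    kept <- ld_prune(XA, maf = maf[common], maf_min = maf_min, r2_max = r2_max)
    if (length(kept) == 0) return(NULL)
    list(H = panel$H[, common[kept], drop = FALSE],
         n_hap_A = panel$n_hap_A, n_hap_B = panel$n_hap_B)
  }))
  genes <- genes[!vapply(genes, is.null, logical(1))]
  structure(list(genes = genes,
                 n_variants = sum(vapply(genes, function(g) ncol(g$H), integer(1))),
                 n_ind_A = demography$deme_haplotypes %/% 2L,
                 n_ind_B = demography$deme_haplotypes %/% 2L),
            class = "structure_reference")
}

#' @export
print.structure_reference <- function(x, ...) {
  cat(sprintf("Structure reference: %d genes, %d pruned common variants\n",
              length(x$genes), x$n_variants))
  invisible(x)
}

# genotype matrix of n_A + n_B sampled individuals on the reference panel
.structure_genotypes <- function(ref, n_A, n_B) {
  idx_A <- if (n_A > 0) sample.int(ref$n_ind_A, n_A) else integer(0)
  idx_B <- if (n_B > 0) sample.int(ref$n_ind_B, n_B) else integer(0)
  do.call(cbind, lapply(ref$genes, function(g) {
    h1 <- c(2L * idx_A - 1L, g$n_hap_A + 2L * idx_B - 1L)
    g$H[h1, , drop = FALSE] + g$H[h1 + 1L, , drop = FALSE]
  }))
}

#' Run one simulation scenario
#'
#' For each replicate: simulate one gene under the demography, draw the
#' case/control sample according to the scenario, and evaluate every
#' requested method (with the scenario's correction, if any) on the rare
#' variants segregating in the sample.  Per-replicate seeds are derived
#' deterministically from `master_seed`, so the full table is reproducible.
#'
#' @param sc an [scenario()].
#' @param demography a [demography_config()]; its migration rate is
#'   overridden by the scenario's.
#' @param master_seed integer master seed.
#' @param structure_ref optional precomputed [structure_reference()] (built
#'   automatically when a correction is requested).
#' @param plan a [permutation_plan()] for permutation-based methods.
#' @param verbose print a line per 100 replicates.
#' @return A `data.frame` with one row per (replicate, method): columns
#'   `replicate`, `method`, `correction`, `statistic`, `p`, `permutations`,
#'   `n_variants`, `seed`.  Replicates that fail (e.g. no rare variant in
#'   the sample after resimulation) are excluded with a warning counting
#'   them; the count is also in `attr(, "failed")`.
#' @export
run_scenario <- function(sc, demography = demography_config(),
                         master_seed = 1L, structure_ref = NULL,
                         plan = permutation_plan(), verbose = FALSE) {
  stopifnot(inherits(sc, "rv_scenario"))
  dem <- demography
  dem$migration_rate <- sc$migration_rate
  dem$n_genes <- 1L
  use_corr <- sc$correction != "none"
  if (use_corr && is.null(structure_ref))
    structure_ref <- structure_reference(dem, seed = derive_seed(master_seed, 0L))
  effects <- if (sc$hypothesis == "H1") sc$effects else NULL

  rows <- vector("list", sc$replicates)
  failed <- 0L
  for (rep_i in seq_len(sc$replicates)) {
    seed_i <- derive_seed(master_seed, rep_i)
    res <- tryCatch(
      .run_one_replicate(sc, dem, seed_i, structure_ref, plan, effects),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      next
    }
    res$replicate <- rep_i
    res$seed <- seed_i
    rows[[rep_i]] <- res
    if (verbose && rep_i %% 100L == 0L)
      message(sprintf("replicate %d/%d", rep_i, sc$replicates))
  }
  if (failed > 0)
    warning(sprintf("%d of %d replicates failed and were excluded", failed, sc$replicates))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "failed") <- failed
  attr(out, "master_seed") <- master_seed
  out
}

.run_one_replicate <- function(sc, dem, seed_i, structure_ref, plan, effects) {
  with_seed(seed_i, {
    # resimulate until the sample carries at least one polymorphic rare variant
    for (try_i in 1:50) {
      panel <- simulate_two_pop(dem)[[1]]
      s <- sample_case_control(panel, sc, effects = effects,
                               rare_threshold = sc$rare_threshold)
      g <- s$genotypes
      rare <- classify_variants(g, rare_threshold = sc$rare_threshold)$rare
      poly <- colSums(g$X) > 0 & colSums(g$X) < 2L * nrow(g$X)
      keep <- rare & poly
      if (any(keep)) break
    }
    if (!any(keep)) stopf("no analyzable rare variant after 50 attempts")
    X <- g$X[, keep, drop = FALSE]
    positions <- g$positions[keep]
    Y <- s$phenotypes$Y
    Z <- NULL
    if (sc$correction != "none") {
      n_B <- sum(g$origin == "B")
      Xs <- .structure_genotypes(structure_ref, nrow(X) - n_B, n_B)
      # rows of Xs are ordered A then B, matching the sample construction
      Z <- pca_genotypes(Xs, K = sc$n_pcs)$x
    }
    do.call(rbind, lapply(sc$methods, function(m) {
      r <- rv_test(X, Y, m, positions = positions, Lg = g$region_length_bp,
                   Z = Z, correction = sc$correction, plan = plan)
      data.frame(method = m, correction = r$correction,
                 statistic = r$statistic, p = r$p,
                 permutations = r$permutations, n_variants = r$n_variants,
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Empirical rejection rate with confidence bands
#'
#' The fraction of p-values at or below `alpha`, with (a) an exact binomial
#' 95% confidence interval around the observed rate and (b) the null
#' acceptance band `alpha +- 1.96 sqrt(alpha (1 - alpha) / n)` obtained from
#' the normal approximation to `Binomial(n, alpha)` — the band within which
#' an empirical type-I error is consistent with the nominal level.
#'
#' @param p_values vector of p-values.
#' @param alpha significance level.
#' @return List with `rate`, `n`, `ci_low`/`ci_high` (around the rate) and
#'   `band_low`/`band_high` (around `alpha`).
#' @examples
#' rejection_rate(runif(1000))
#' @export
rejection_rate <- function(p_values, alpha = 0.05) {
  p_values <- p_values[!is.na(p_values)]
  n <- length(p_values)
  if (n == 0) stopf("no p-values supplied")
  k <- sum(p_values <= alpha)
  ci <- binom.test(k, n)$conf.int
  half <- qnorm(0.975) * sqrt(alpha * (1 - alpha) / n)
  list(rate = k / n, n = n, ci_low = ci[1], ci_high = ci[2],
       band_low = alpha - half, band_high = alpha + half)
}

#' Combine per-scenario result tables into a long summary
#'
#' Stacks [run_scenario()] outputs, labels them with their scenario's
#' design cell, and summarizes each (scenario, method, correction) cell
#' with its rejection rate and confidence bounds at `alpha`.
#'
#' @param ... named arguments, each a list `list(scenario =, results =)`, or
#'   a single list of such pairs.
#' @param alpha significance level of the summary.
#' @param plot also return a `ggplot2` bar chart (requires ggplot2).
#' @return A `data.frame` keyed by `(migration_rate, pct_controls_B,
#'   hypothesis, method, correction)` with `rate`, `ci_low`, `ci_high`,
#'   `band_low`, `band_high`, `n`; with `plot = TRUE`, a list
#'   `list(summary =, plot =)`.
#' @export
compare_scenarios <- function(..., alpha = 0.05, plot = FALSE) {
  args <- list(...)
  if (length(args) == 1 && is.null(args[[1]]$scenario)) args <- args[[1]]
  rows <- lapply(args, function(item) {
    sc <- item$scenario
    res <- item$results
    if (is.null(sc) || is.null(res)) stopf("each item needs $scenario and $results")
    cells <- split(res, list(res$method, res$correction), drop = TRUE)
    do.call(rbind, lapply(cells, function(cell) {
      rr <- rejection_rate(cell$p, alpha)
      data.frame(migration_rate = sc$migration_rate,
                 pct_controls_B = sc$pct_controls_B,
                 hypothesis = sc$hypothesis,
                 method = cell$method[1], correction = cell$correction[1],
                 rate = rr$rate, ci_low = rr$ci_low, ci_high = rr$ci_high,
                 band_low = rr$band_low, band_high = rr$band_high,
                 n = rr$n, stringsAsFactors = FALSE)
    }))
  })
  keys <- lapply(rows, function(r) sort(unique(r$method)))
  if (length(unique(vapply(keys, paste, character(1), collapse = ","))) > 1)
    stopf("scenario tables do not share the same method set")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!plot) return(out)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot = TRUE requires the ggplot2 package")
  gg <- ggplot2::ggplot(out, ggplot2::aes(x = factor(pct_controls_B), y = rate,
                                          fill = method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = alpha, colour = "red") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = band_low), colour = "blue",
                        linetype = 2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = band_high), colour = "blue",
                        linetype = 2) +
    ggplot2::facet_grid(hypothesis + correction ~ migration_rate) +
    ggplot2::labs(x = "% controls from deme B", y = "rejection rate")
  list(summary = out, plot = gg)
}
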