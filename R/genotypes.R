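#' Build diploid genotypes from a haplotype panel
#'
#' Diploid individual `i` of a deme is the pair of haplotypes `(2i - 1, 2i)`
#' of that deme's panel; sampling draws individuals without replacement.
#' Genotypes are recoded to minor-allele counts relative to the deme-A
#' frequency (sites whose derived allele exceeds frequency 0.5 in the full
#' deme-A panel are flipped).
#'
#' @param panel a `haplotype_panel` from [simulate_two_pop()].
#' @param n_A,n_B number of diploid individuals to draw from each deme.
#' @param seed optional integer seed.
#' @param indices_A,indices_B optional explicit individual indices (1-based,
#'   within deme) overriding random sampling.
#' @param keep_haplotypes keep the sampled phased haplotypes (needed by
#'   [write_vcf()]).
#' @return A `genotype_matrix`: list with `X` (individuals x sites
#'   minor-allele counts in `{0,1,2}`), `positions`, `maf_A` (full-panel
#'   deme-A MAF), `origin` (factor `"A"`/`"B"`), `region_length_bp`, and
#'   optionally `haplotypes`.
#' @examples
#' dem <- demography_config(deme_haplotypes = 200, ancestral_haplotypes = 600,
#'                          region_length_bp = 5000)
#' panel <- simulate_two_pop(dem, seed = 1)[[1]]
#' g <- haplotypes_to_genotypes(panel, n_A = 20, n_B = 20, seed = 2)
#' table(g$X[, 1])
#' @export
haplotypes_to_genotypes <- function(panel, n_A, n_B = 0L, seed = NULL,
                                    indices_A = NULL, indices_B = NULL,
                                    keep_haplotypes = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  max_A <- panel$n_hap_A %/% 2L
  max_B <- panel$n_hap_B %/% 2L
  with_seed(seed, {
    if (is.null(indices_A)) {
      if (n_A > max_A) stopf("requested %d deme-A individuals but only %d available", n_A, max_A)
      indices_A <- if (n_A > 0) sample.int(max_A, n_A) else integer(0)
    }
    if (is.null(indices_B)) {
      if (n_B > max_B) stopf("requested %d deme-B individuals but only %d available", n_B, max_B)
      indices_B <- if (n_B > 0) sample.int(max_B, n_B) else integer(0)
    }
    .genotypes_from_indices(panel, indices_A, indices_B, keep_haplotypes)
  })
}

# indices are within-deme diploid indices; deme-B haplotype rows are offset
.genotypes_from_indices <- function(panel, indices_A, indices_B, keep_haplotypes = FALSE) {
  hap1 <- c(2L * indices_A - 1L, panel$n_hap_A + 2L * indices_B - 1L)
  hap2 <- hap1 + 1L
  .genotypes_from_hap_rows(panel, hap1, hap2,
                           origin = rep(c("A", "B"), c(length(indices_A), length(indices_B))),
                           keep_haplotypes = keep_haplotypes)
}

.genotypes_from_hap_rows <- function(panel, hap1, hap2, origin, keep_haplotypes = FALSE) {
  H1 <- panel$H[hap1, , drop = FALSE]
  H2 <- panel$H[hap2, , drop = FALSE]
  X <- H1 + H2
  fA <- panel$counts_A / panel$n_hap_A
  flip <- fA > 0.5
  if (any(flip)) {
    X[, flip] <- 2L - X[, flip]
    if (keep_haplotypes) { H1[, flip] <- 1L - H1[, flip]; H2[, flip] <- 1L - H2[, flip] }
  }
  out <- list(X = X,
              positions = panel$positions,
              maf_A = ifelse(flip, 1 - fA, fA),
              flipped = flip,
              origin = factor(origin, levels = c("A", "B")),
              region_length_bp = panel$region_length_bp)
  if (keep_haplotypes) out$haplotypes <- list(H1 = H1, H2 = H2)
  structure(out, class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals (%d A, %d B) x %d sites\n",
              nrow(x$X), sum(x$origin == "A"), sum(x$origin == "B"), ncol(x$X)))
  invisible(x)
}

#' Classify variants as rare or common by deme-A frequency
#'
#' Rare and common status is defined on the full deme-A panel MAF (not the
#' sampled subset): rare when `0 < maf_A <= rare_threshold`, common when
#' `maf_A >= common_threshold`.  Sites absent from deme A (`maf_A == 0`) are
#' neither.
#'
#' @param g a `genotype_matrix` (or any object with a `maf_A` field).
#' @param rare_threshold MAF threshold defining rare variants.
#' @param common_threshold MAF floor defining common variants (used by the
#'   population-structure analyses).
#' @return List with logical masks `rare` and `common`.
#' @export
classify_variants <- function(g, rare_threshold = 0.01, common_threshold = 0.05) {
  maf <- if (is.list(g)) g$maf_A else g
  stopifnot(is.numeric(maf), all(maf >= 0 & maf <= 0.5))
  list(rare = maf > 0 & maf <= rare_threshold,
       common = maf >= common_threshold)
}

#' Draw per-variant effect sizes under the disease model
#'
#' Exactly `round(prop_deleterious * rare_count)` variants (round half up),
#' chosen uniformly at random, receive `log(odds_ratio)`; the rest 0.
#'
#' @param rare_count number of rare variants.
#' @param model an [effect_model()].
#' @param seed optional integer seed.
#' @return Numeric vector of log-odds-ratios of length `rare_count`.
#' @export
draw_effect_sizes <- function(rare_count, model = effect_model(), seed = NULL) {
  stopifnot(inherits(model, "effect_model"))
  if (!is_count(rare_count) || rare_count < 1)
    stopf("rare_count must be a positive integer (H1 requires at least one rare variant)")
  n_del <- as.integer(floor(model$prop_deleterious * rare_count + 0.5))
  beta <- numeric(rare_count)
  if (n_del > 0) {
    idx <- with_seed(seed, sample.int(rare_count, n_del))
    beta[idx] <- log(model$odds_ratio)
  }
  beta
}

#' Sample a case/control panel from the two demes
#'
#' Draws `scenario$n_cases` cases and `scenario$n_controls` controls, with a
#' fraction `scenario$pct_controls_B / 100` of controls taken from deme B.
#' Cases always originate from deme A.
#'
#' Under H0 disease labels are independent of genotype: individuals are
#' sampled without replacement and labelled by quota.  Under H1 candidate
#' deme-A individuals are formed by drawing fresh random haplotype pairs from
#' the deme-A panel, their status is Bernoulli with
#' `logit(P(Y=1)) = alpha0 + beta'x` on the rare variants, and sampling
#' repeats until the case and deme-A control quotas are filled; deme-B
#' controls are drawn irrespective of genotype.
#'
#' @param panel a `haplotype_panel`.
#' @param scenario a [scenario()] (uses `n_cases`, `n_controls`,
#'   `pct_controls_B`, `hypothesis`).
#' @param effects an [effect_model()]; required under H1.
#' @param rare_threshold deme-A MAF threshold defining the rare variants that
#'   carry effects under H1.
#' @param seed optional integer seed.
#' @param max_batches cap on H1 candidate-sampling batches before erroring.
#' @param keep_haplotypes keep phased haplotypes for VCF export.
#' @return List with `genotypes` (a `genotype_matrix`), `phenotypes` (a
#'   `phenotype_panel` with fields `Y`, `origin`, `n_cases`, `n_controls`),
#'   and `beta` (H1 effect vector over rare variants, else `NULL`).
#' @examples
#' dem <- demography_config(deme_haplotypes = 400, ancestral_haplotypes = 1200,
#'                          region_length_bp = 20000)
#' panel <- simulate_two_pop(dem, seed = 1)[[1]]
#' sc <- scenario(migration_rate = 0.01, pct_controls_B = 25,
#'                n_cases = 50, n_controls = 40)
#' s <- sample_case_control(panel, sc, seed = 3)
#' table(s$phenotypes$Y, s$phenotypes$origin)
#' @export
sample_case_control <- function(panel, scenario, effects = NULL,
                                rare_threshold = 0.01, seed = NULL,
                                max_batches = 200L, keep_haplotypes = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(scenario, "rv_scenario"))
  N1 <- scenario$n_cases
  N0 <- scenario$n_controls
  n0_B <- as.integer(round(N0 * scenario$pct_controls_B / 100))
  n0_A <- N0 - n0_B
  h1 <- identical(scenario$hypothesis, "H1")
  if (h1 && is.null(effects)) stopf("H1 sampling requires an effect_model")

  with_seed(seed, {
    if (!h1) {
      g <- haplotypes_to_genotypes(panel, n_A = N1 + n0_A, n_B = n0_B,
                                   keep_haplotypes = keep_haplotypes)
      Y <- rep(c(1L, 0L, 0L), c(N1, n0_A, n0_B))
      beta <- NULL
    } else {
      maf_A <- panel_maf(panel, "A")
      rare <- maf_A > 0 & maf_A <= rare_threshold
      if (!any(rare)) stopf("H1 sampling requires at least one rare variant in the panel")
      beta <- draw_effect_sizes(sum(rare), effects)
      fA <- panel$counts_A / panel$n_hap_A
      flip <- fA > 0.5
      # effects apply to minor-allele counts: flip haplotype coding where needed
      Hm <- panel$H[seq_len(panel$n_hap_A), rare, drop = FALSE]
      fl <- flip[rare]
      if (any(fl)) Hm[, fl] <- 1L - Hm[, fl]
      hap_eff <- as.numeric(Hm %*% beta)

      need_case <- N1; need_ctrlA <- n0_A
      case_h1 <- integer(0); case_h2 <- integer(0)
      ctrl_h1 <- integer(0); ctrl_h2 <- integer(0)
      batch <- max(1000L, N1)
      for (b in seq_len(max_batches)) {
        if (need_case <= 0 && need_ctrlA <= 0) break
        i1 <- sample.int(panel$n_hap_A, batch, replace = TRUE)
        i2 <- sample.int(panel$n_hap_A, batch, replace = TRUE)
        ok <- i1 != i2
        i1 <- i1[ok]; i2 <- i2[ok]
        p <- plogis(effects$alpha0 + hap_eff[i1] + hap_eff[i2])
        y <- runif(length(p)) < p
        if (need_case > 0) {
          take <- which(y)[seq_len(min(need_case, sum(y)))]
          case_h1 <- c(case_h1, i1[take]); case_h2 <- c(case_h2, i2[take])
          need_case <- N1 - length(case_h1)
        }
        if (need_ctrlA > 0) {
          take <- which(!y)[seq_len(min(need_ctrlA, sum(!y)))]
          ctrl_h1 <- c(ctrl_h1, i1[take]); ctrl_h2 <- c(ctrl_h2, i2[take])
          need_ctrlA <- n0_A - length(ctrl_h1)
        }
      }
      if (need_case > 0 || need_ctrlA > 0)
        stopf("case/control quotas unattainable within %d sampling batches", max_batches)
      idx_B <- if (n0_B > 0) sample.int(panel$n_hap_B %/% 2L, n0_B) else integer(0)
      hap1 <- c(case_h1, ctrl_h1, panel$n_hap_A + 2L * idx_B - 1L)
      hap2 <- c(case_h2, ctrl_h2, panel$n_hap_A + 2L * idx_B)
      g <- .genotypes_from_hap_rows(panel, hap1, hap2,
                                    origin = rep(c("A", "B"), c(N1 + n0_A, n0_B)),
                                    keep_haplotypes = keep_haplotypes)
      Y <- rep(c(1L, 0L, 0L), c(N1, n0_A, n0_B))
    }
    phen <- structure(list(Y = Y, origin = g$origin,
                           n_cases = N1, n_controls = N0),
                      class = "phenotype_panel")
    list(genotypes = g, phenotypes = phen, beta = beta)
  })
}

#' @export
print.phenotype_panel <- function(x, ...) {
  cat(sprintf("Phenotypes: %d cases / %d controls (%d controls from deme B)\n",
              x$n_cases, x$n_controls, sum(x$Y == 0 & x$origin == "B")))
  invisible(x)
}
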