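test_that("simulation is reproducible and panels satisfy their invariants", {
  dem <- small_dem(n_genes = 3)
  a <- simulate_two_pop(dem, seed = 42)
  b <- simulate_two_pop(dem, seed = 42)
  expect_identical(a, b)

  for (panel in a) {
    expect_true(all(panel$H %in% 0:1))
    expect_true(all(diff(panel$positions) > 0))
    expect_true(all(panel$positions >= 1 & panel$positions <= dem$region_length_bp))
    # every site segregates in the union of demes
    tot <- colSums(panel$H)
    expect_true(all(tot > 0 & tot < nrow(panel$H)))
  }
})

test_that("demography configuration rejects invalid values", {
  expect_error(demography_config(migration_rate = 0.6), "migration_rate")
  expect_error(demography_config(deme_haplotypes = 101), "even")
  expect_error(demography_config(recombination_rate = 1e-8), "not modelled")
  expect_error(demography_config(expansion = list(time = 10, haplotypes = 5000)),
               "predate")
})

test_that("diploid genotypes are haplotype sums recoded to the deme-A minor allele", {
  panel <- simulate_two_pop(small_dem(), seed = 7)[[1]]
  g <- haplotypes_to_genotypes(panel, n_A = 50, n_B = 50, seed = 8,
                               keep_haplotypes = TRUE)
  expect_true(all(g$X %in% 0:2))
  expect_true(all(g$maf_A >= 0 & g$maf_A <= 0.5))
  # conservation: column sums equal the allele counts of the drawn haplotypes
  expect_equal(colSums(g$X), colSums(g$haplotypes$H1) + colSums(g$haplotypes$H2))
  # explicit indices reproduce the draw
  g2 <- haplotypes_to_genotypes(panel, n_A = 2, indices_A = c(5L, 9L))
  x_manual <- panel$H[c(9L, 17L), , drop = FALSE] + panel$H[c(10L, 18L), , drop = FALSE]
  fA <- panel$counts_A / panel$n_hap_A
  x_manual[, fA > 0.5] <- 2L - x_manual[, fA > 0.5]
  expect_equal(unname(g2$X), unname(x_manual))
  # size errors
  expect_error(haplotypes_to_genotypes(panel, n_A = 10000), "available")
})

test_that("variant classification follows the deme-A reference MAF", {
  maf <- c(0, 0.004, 0.01, 0.03, 0.05, 0.4)
  cl <- classify_variants(maf, rare_threshold = 0.01)
  expect_equal(cl$rare, c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cl$common, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  # monotone nesting of thresholds
  cl5 <- classify_variants(maf, rare_threshold = 0.05)
  expect_true(all(!cl$rare | cl5$rare))
})

test_that("effect sizes follow the disease model", {
  beta <- draw_effect_sizes(4, effect_model(), seed = 1)
  expect_equal(sum(beta != 0), 2)
  expect_true(all(beta[beta != 0] == log(1.5)))
  expect_equal(draw_effect_sizes(5, effect_model(odds_ratio = 1), seed = 1),
               rep(0, 5))
  # round-half-up on 0.5 * count
  expect_equal(sum(draw_effect_sizes(5, effect_model(), seed = 2) != 0), 3)
  expect_error(draw_effect_sizes(0, effect_model()), "positive")
})

test_that("case/control sampling honours quotas and origins", {
  panel <- simulate_two_pop(small_dem(), seed = 11)[[1]]
  sc <- scenario(pct_controls_B = 25, n_cases = 40, n_controls = 40)
  s <- sample_case_control(panel, sc, seed = 12)
  expect_equal(sum(s$phenotypes$Y), 40)
  expect_equal(sum(s$phenotypes$Y == 0 & s$phenotypes$origin == "B"), 10)
  expect_true(all(s$phenotypes$origin[s$phenotypes$Y == 1] == "A"))
  # pctB = 0 keeps everyone in deme A
  s0 <- sample_case_control(panel, scenario(pct_controls_B = 0, n_cases = 20,
                                            n_controls = 20), seed = 13)
  expect_true(all(s0$phenotypes$origin == "A"))
  # same seed, same draw
  expect_identical(sample_case_control(panel, sc, seed = 5),
                   sample_case_control(panel, sc, seed = 5))
})

test_that("H1 sampling fills quotas and attaches effects to rare variants", {
  dem <- small_dem(region_length_bp = 20000)
  panel <- simulate_two_pop(dem, seed = 21)[[1]]
  sc <- scenario(pct_controls_B = 50, hypothesis = "H1", n_cases = 30,
                 n_controls = 30)
  s <- sample_case_control(panel, sc, effects = effect_model(),
                           rare_threshold = 0.05, seed = 22)
  expect_equal(sum(s$phenotypes$Y), 30)
  expect_equal(sum(s$phenotypes$Y == 0 & s$phenotypes$origin == "B"), 15)
  expect_true(all(s$phenotypes$origin[s$phenotypes$Y == 1] == "A"))
  maf <- panel_maf(panel, "A")
  expect_length(s$beta, sum(maf > 0 & maf <= 0.05))
  expect_error(sample_case_control(panel, sc, effects = effect_model(),
                                   rare_threshold = 1e-9, seed = 1),
               "rare variant")
})

test_that("an immediate split leaves the demes exchangeable (FST near zero)", {
  dem <- small_dem(split_time_generations = 0L, region_length_bp = 2000,
                   n_genes = 40)
  panels <- simulate_two_pop(dem, seed = 31)
  Xs <- lapply(panels, function(p) {
    g <- haplotypes_to_genotypes(p, n_A = 100, n_B = 100,
                                 indices_A = 1:100, indices_B = 1:100)
    g$X[, g$maf_A >= 0.05, drop = FALSE]
  })
  X <- do.call(cbind, Xs)
  theta <- wc_fst(X, rep(c("A", "B"), each = 100))$theta
  expect_lt(abs(theta), 0.01)
})
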