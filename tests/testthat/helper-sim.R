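# small demographies used across tests: tiny demes and an inflated mutation
# rate keep simulations fast while providing enough segregating sites
small_dem <- function(migration_rate = 0.01, region_length_bp = 5000,
                      mutation_rate = 1e-6, ...) {
  demography_config(deme_haplotypes = 400L, ancestral_haplotypes = 1200L,
                    migration_rate = migration_rate,
                    region_length_bp = region_length_bp,
                    mutation_rate = mutation_rate, ...)
}

# a small case/control instance on a simulated gene
small_instance <- function(seed, n_cases = 30, n_controls = 30, pct_B = 0,
                           hypothesis = "H0", dem = small_dem()) {
  sc <- scenario(migration_rate = dem$migration_rate, pct_controls_B = pct_B,
                 hypothesis = hypothesis, n_cases = n_cases,
                 n_controls = n_controls)
  panel <- simulate_two_pop(dem, seed = seed)[[1]]
  s <- sample_case_control(panel, sc, seed = seed + 1,
                           effects = if (hypothesis == "H1") effect_model() else NULL,
                           rare_threshold = 0.05)
  g <- s$genotypes
  keep <- classify_variants(g, rare_threshold = 0.05)$rare & colSums(g$X) > 0
  list(X = g$X[, keep, drop = FALSE], Y = s$phenotypes$Y,
       positions = g$positions[keep], Lg = g$region_length_bp,
       origin = s$phenotypes$origin)
}

# permutation mid-p reference: atoms of the discrete permutation null are
# split in half, the natural comparison point for a continuous approximation
perm_mid_p <- function(stat_fn, X, Y, n_perm, seed) {
  obs <- stat_fn(X, Y)
  qs <- with_test_seed(seed, replicate(n_perm, stat_fn(X, sample(Y))))
  tol <- 1e-9 * max(1, abs(obs))
  mean(qs > obs + tol) + 0.5 * mean(abs(qs - obs) <= tol)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
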