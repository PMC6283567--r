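test_that("LD pruning removes duplicates and low-MAF columns, keeps independence", {
  set.seed(201)
  base <- rbinom(200, 2, 0.3)
  X <- cbind(base, base, rbinom(200, 2, 0.4), rbinom(200, 2, 0.25))
  kept <- ld_prune(X)
  expect_true(sum(kept %in% 1:2) == 1)       # r2 = 1 pair: one survivor
  expect_true(all(3:4 %in% kept))            # independent columns retained
  # MAF floor applies before the correlation stage
  Xf <- cbind(X, c(rep(1, 3), rep(0, 197)))  # MAF 0.0075
  expect_false(ncol(Xf) %in% ld_prune(Xf))
  # every retained pair within a window is below the r2 ceiling
  set.seed(202)
  Xr <- matrix(rbinom(200 * 30, 2, 0.3), 200)
  Xr[, 5] <- Xr[, 4]; Xr[, 20] <- Xr[, 19]
  k <- ld_prune(Xr)
  r2 <- suppressWarnings(cor(Xr[, k]))^2
  diag(r2) <- 0
  expect_lt(max(r2, na.rm = TRUE), 0.2)
})

test_that("genotype PCA separates divergent demes and satisfies its contracts", {
  set.seed(211)
  # two groups with many frequency-differentiated variants
  n <- 120; P <- 80
  pA <- runif(P, 0.1, 0.5); pB <- pmin(pA + 0.4, 0.95)
  X <- rbind(matrix(rbinom(n / 2 * P, 2, rep(pA, each = n / 2)), n / 2),
             matrix(rbinom(n / 2 * P, 2, rep(pB, each = n / 2)), n / 2))
  pc <- pca_genotypes(X, K = 2)
  expect_equal(colMeans(pc$x), c(0, 0), tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))
  g1 <- pc$x[1:(n / 2), 1]; g2 <- pc$x[(n / 2 + 1):n, 1]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))  # zero overlap
  # variant order only affects signs
  ord <- sample(P)
  pc2 <- pca_genotypes(X[, ord], K = 2)
  expect_equal(abs(pc2$x[, 1]), abs(pc$x[, 1]), tolerance = 1e-6)
  # iterative and exact route agree
  pc3 <- pca_genotypes(X, K = 2, exact_limit = 1L)
  expect_equal(abs(pc3$x[, 1]), abs(pc$x[, 1]), tolerance = 1e-3)
  # monomorphic columns dropped
  Xm <- cbind(X, 0L)
  expect_equal(pca_genotypes(Xm, K = 2)$dropped, ncol(Xm))
})

test_that("Weir-Cockerham estimator matches hand evaluation of the 1984 components", {
  # pop1: n = 100, genotype counts 72/26/2 (p = 0.15, h = 0.26)
  # pop2: n = 100, genotype counts 56/38/6 (p = 0.25, h = 0.38)
  X <- c(rep(0, 72), rep(1, 26), rep(2, 2), rep(0, 56), rep(1, 38), rep(2, 6))
  pop <- rep(c("A", "B"), each = 100)
  est <- wc_fst(matrix(X, ncol = 1), pop)
  # scalar transcription of the variance components
  n1 <- 100; n2 <- 100; r <- 2
  p1 <- 0.15; p2 <- 0.25; h1 <- 0.26; h2 <- 0.38
  nbar <- 100; ncoef <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- 0.20
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- 0.32
  a <- (nbar / ncoef) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  expect_equal(est$a[1], a)
  expect_equal(est$b[1], b)
  expect_equal(est$c[1], cc)
  expect_equal(est$theta, a / (a + b + cc))

  # allele-label swap invariance at one locus
  X2 <- cbind(matrix(X, ncol = 1), rbinom(200, 2, 0.3))
  sw <- X2; sw[, 1] <- 2 - sw[, 1]
  expect_equal(wc_fst(sw, pop)$theta, wc_fst(X2, pop)$theta)

  # limits: identical frequencies ~ 0, fixed differences -> 1
  set.seed(221)
  Xsame <- matrix(rbinom(400 * 50, 2, 0.3), 400)
  expect_lt(abs(wc_fst(Xsame, rep(c("A", "B"), each = 200))$theta), 0.02)
  Xfix <- rbind(matrix(0L, 100, 20), matrix(2L, 100, 20))
  expect_gt(wc_fst(Xfix, rep(c("A", "B"), each = 100))$theta, 0.99)
  expect_error(wc_fst(matrix(1L, 10, 2) * 0L, rep(c("A", "B"), each = 5)),
               "monomorphic")
})

test_that("differentiation decreases with migration on simulated panels", {
  fst_at <- function(m, seed) {
    dem <- small_dem(migration_rate = m, region_length_bp = 2000, n_genes = 60)
    panels <- simulate_two_pop(dem, seed = seed)
    X <- do.call(cbind, lapply(panels, function(p) {
      g <- haplotypes_to_genotypes(p, n_A = 150, n_B = 150,
                                   indices_A = 1:150, indices_B = 1:150)
      g$X[, g$maf_A >= 0.05, drop = FALSE]
    }))
    wc_fst(X, rep(c("A", "B"), each = 150))$theta
  }
  # small demes drift fast, so the ordering is sharp even at 60 loci
  f0 <- fst_at(0, 231)
  f01 <- fst_at(0.01, 232)
  f1 <- fst_at(0.1, 233)
  expect_gt(f0, f01)
  expect_gt(f01, f1)
})
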