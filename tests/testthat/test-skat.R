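test_that("mixture-of-chi-squares tail matches closed forms", {
  expect_equal(as.numeric(mixture_chisq_sf(1, qchisq(0.95, 1))), 0.05,
               tolerance = 1e-5)
  q <- 5.3
  expect_equal(as.numeric(mixture_chisq_sf(c(1, 1), q)), exp(-q / 2),
               tolerance = 1e-6)
  # scale invariance
  expect_equal(as.numeric(mixture_chisq_sf(c(2.5), 2.5 * 3.2)),
               as.numeric(mixture_chisq_sf(1, 3.2)), tolerance = 1e-6)
  expect_equal(as.numeric(mixture_chisq_sf(c(0.5, 2), 0)), 1)
  expect_error(mixture_chisq_sf(c(0, 0), 1), "zero")
})

test_that("SKAT quadratic form matches hand arithmetic and its limits", {
  fx <- make_fixture("skat_4")
  expect_equal(skat_Q(fx$X, fx$Y, fx$mu, fx$weights, rho = 0), fx$expected$Q_rho0)
  expect_equal(skat_Q(fx$X, fx$Y, fx$mu, fx$weights, rho = 1), fx$expected$Q_rho1)
  # rho = 1 with unit weights is the squared burden score numerator
  inst <- small_instance(71)
  null <- fit_null(inst$Y)
  U <- sum(rowSums(inst$X) * (inst$Y - null$mu))
  expect_equal(skat_Q(inst$X, inst$Y, null$mu, rep(1, ncol(inst$X)), 1), U^2)
  # monotone and continuous in rho when per-variant scores share a sign
  X <- cbind(c(2, 1, 0, 0), c(1, 1, 0, 0))
  Y <- c(1, 1, 0, 0)
  qs <- vapply(seq(0, 1, 0.05), function(r) skat_Q(X, Y, rep(0.5, 4), c(1, 1), r),
               numeric(1))
  expect_true(all(diff(qs) >= -1e-12))
})

test_that("kernel algebra: duplicated columns with halved weights keep the p-value", {
  inst <- small_instance(73, n_cases = 100, n_controls = 100)
  null <- fit_null(inst$Y)
  P <- ncol(inst$X)
  p1 <- skat_pvalue(inst$X, inst$Y, null, weights = rep(1, P))$p
  p2 <- skat_pvalue(cbind(inst$X, inst$X), inst$Y, null,
                    weights = rep(0.5, 2 * P))$p
  # Q halves and so do all eigenvalues; the tail probability is unchanged
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("single-variant SKAT agrees with the burden score test asymptotically", {
  set.seed(81)
  N <- 2000
  X <- matrix(rbinom(N, 2, 0.02), ncol = 1)
  Y <- rep(0:1, each = N / 2)
  null <- fit_null(Y)
  p_skat <- skat_pvalue(X, Y, null, weights = 2)$p
  p_score <- score_test(2 * X[, 1], Y, null)$p
  expect_equal(p_skat, p_score, tolerance = 1e-3)
})

test_that("analytic SKAT family p-values agree with the permutation oracle", {
  # moderate-frequency N = 20 instances; 500-permutation mid-p reference
  for (seed in c(91, 92, 93)) {
    set.seed(seed)
    N <- 20; P <- 4
    X <- matrix(rbinom(N * P, 2, 0.35), N)
    Y <- sample(rep(0:1, N / 2))
    null <- fit_null(Y)
    w <- rep(1, P)

    p_an <- skat_pvalue(X, Y, null)$p
    ref <- perm_mid_p(function(X, Yp) skat_Q(X, Yp, null$mu, w, 0),
                      X, Y, 500, seed + 1000)
    se <- sqrt(max(ref * (1 - ref), 0.25 / 500) / 500)
    expect_lt(abs(p_an - ref), 3 * se + 0.02)

    p_o <- skato_pvalue(X, Y, null)$p
    stat_o <- rvstrat:::.perm_stat_fn("SKATO", X, Y, null, list())
    ref_o <- perm_mid_p(stat_o, X, Y, 500, seed + 2000)
    se_o <- sqrt(max(ref_o * (1 - ref_o), 0.25 / 500) / 500)
    expect_lt(abs(p_o - ref_o), 3 * se_o + 0.025)
  }
})

test_that("SKAT-O collapses to SKAT for one variant and finds the burden optimum", {
  set.seed(101)
  X <- matrix(rbinom(30, 2, 0.3), ncol = 1)
  Y <- rep(0:1, 15)
  null <- fit_null(Y)
  expect_equal(skato_pvalue(X, Y, null)$p, skat_pvalue(X, Y, null)$p)
  # perfectly correlated variants: full correlation attains the grid minimum
  # (all rho values are then equivalent up to scale, so the whole grid ties)
  Xb <- cbind(X, X, X)
  res <- skato_pvalue(Xb, Y, null, weights = rep(1, 3))
  expect_equal(res$p_rho[11], min(res$p_rho), tolerance = 1e-6)
  expect_true(res$p >= min(res$p_rho) - 1e-6)
  expect_true(res$p <= 1)
})

test_that("position kernel and PODKAT match their closed forms", {
  fx <- make_fixture("podkat_kernel")
  A <- podkat_kernel(fx$positions, fx$radius)
  expect_equal(diag(A), rep(1, 3), ignore_attr = TRUE)
  expect_equal(A[1, 2], fx$expected$A12)
  expect_equal(A[1, 3], fx$expected$A13)
  expect_true(isSymmetric(unclass(A)))

  # two-variant instance against direct matrix multiplication
  X <- rbind(c(1, 0), c(0, 2), c(1, 1), c(0, 0))
  Y <- c(1, 0, 1, 0)
  mu <- rep(0.5, 4)
  w <- c(0.7, 1.3)
  A2 <- podkat_kernel(c(100, 600), 1000)
  r <- Y - mu
  W <- diag(w)
  Qdirect <- drop(t(r) %*% X %*% W %*% A2 %*% t(A2) %*% t(W) %*% t(X) %*% r)
  expect_equal(podkat_Q(X, Y, mu, w, A2), Qdirect)

  # identity kernel (distant variants) reduces PODKAT to SKAT at rho = 0
  inst <- small_instance(111)
  null <- fit_null(inst$Y)
  far <- seq(0, by = 2000, length.out = ncol(inst$X))
  expect_equal(podkat_Q(inst$X, inst$Y, null$mu, rep(1, ncol(inst$X)),
                        podkat_kernel(far, 1000)),
               skat_Q(inst$X, inst$Y, null$mu, rep(1, ncol(inst$X)), 0))
  pk <- podkat_pvalue(inst$X, inst$Y, null, positions = far, radius = 1000)
  sk <- skat_pvalue(inst$X, inst$Y, null)
  expect_equal(pk$p, sk$p, tolerance = 1e-8)
  # co-located variants: A = 11', so A A' = P 11' and the statistic is P
  # times the rho = 1 burden form; the p-value is scale-invariant and equal
  same <- rep(500, ncol(inst$X))
  expect_equal(podkat_Q(inst$X, inst$Y, null$mu, rep(1, ncol(inst$X)),
                        podkat_kernel(same, 1000)),
               ncol(inst$X) *
                 skat_Q(inst$X, inst$Y, null$mu, rep(1, ncol(inst$X)), 1))
  p_same <- podkat_pvalue(inst$X, inst$Y, null, positions = same)$p
  p_rho1 <- skat_pvalue(inst$X, inst$Y, null, rho = 1)$p
  expect_equal(p_same, p_rho1, tolerance = 1e-6)
})

test_that("PODKAT analytic p agrees with the permutation oracle", {
  set.seed(121)
  N <- 20; P <- 4
  X <- matrix(rbinom(N * P, 2, 0.35), N)
  Y <- sample(rep(0:1, N / 2))
  null <- fit_null(Y)
  pos <- c(100, 300, 1500, 1800)
  A <- podkat_kernel(pos, 1000)
  p_an <- podkat_pvalue(X, Y, null, positions = pos, radius = 1000)$p
  ref <- perm_mid_p(function(X, Yp) podkat_Q(X, Yp, null$mu, rep(1, P), A),
                    X, Y, 500, 1121)
  se <- sqrt(max(ref * (1 - ref), 0.25 / 500) / 500)
  expect_lt(abs(p_an - ref), 3 * se + 0.02)
})
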