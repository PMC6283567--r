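test_that("null model fitting: closed form, separation, score equations", {
  Y <- rep(0:1, each = 1000)
  null <- fit_null(Y)
  expect_equal(null$mu, rep(0.5, 2000))
  expect_equal(null$alpha0, 0)

  expect_error(fit_null(Y, Z = cbind(Y)), "separation")
  expect_error(fit_null(rep(1, 10)), "constant")

  set.seed(141)
  Z <- cbind(rnorm(2000), rbinom(2000, 1, 0.4))
  Yz <- rbinom(2000, 1, plogis(-0.5 + 0.8 * Z[, 1]))
  nz <- fit_null(Yz, Z)
  # MLE score equations at convergence
  expect_lt(max(abs(crossprod(cbind(1, Z), Yz - nz$mu))), 1e-6)
})

test_that("a constant covariate column is aliased away harmlessly", {
  set.seed(142)
  Y <- rep(0:1, each = 50)
  X <- matrix(rbinom(300, 2, 0.2), 100)
  Z <- cbind(rnorm(100))
  p_base <- rv_test(X, Y, "SKAT", Z = Z, correction = "pca_model")$p
  p_const <- rv_test(X, Y, "SKAT", Z = cbind(Z, 1), correction = "pca_model")$p
  expect_equal(p_base, p_const)
})

test_that("adaptive permutation hits its boundaries and the enumeration oracle", {
  # observed statistic at the top / bottom of the permutation distribution
  X <- matrix(c(10, 4, 2, 0, 0, 0), ncol = 1)
  statf0 <- function(X, Yp) sum(X[, 1] * Yp)
  plan <- permutation_plan(max_perm = 50, precision = 1e-6, alpha = 1e-6)
  top <- adaptive_permutation(statf0, X, c(1, 1, 1, 0, 0, 0), plan, seed = 1)
  expect_equal(top$p, (top$b + 1) / (top$permutations_used + 1))
  expect_lt(top$p, 0.2)  # only ties with the observed assignment count
  bottom <- adaptive_permutation(statf0, X, c(0, 0, 0, 1, 1, 1), plan, seed = 1)
  expect_equal(bottom$p, 1)  # every permuted value is at least as large

  # exhaustive enumeration at N = 6 (all 20 case assignments)
  Xe <- matrix(c(2, 1, 0, 0, 0, 0), ncol = 1)
  Ye <- c(1, 1, 1, 0, 0, 0)
  null <- fit_null(Ye)
  statf <- function(X, Yp) score_test(X[, 1], Yp, null)$Q
  combs <- utils::combn(6, 3)
  stats <- apply(combs, 2, function(ix) {
    Yp <- integer(6); Yp[ix] <- 1L; statf(Xe, Yp)
  })
  p_exact <- mean(stats >= statf(Xe, Ye) - 1e-12)
  # alpha ~ 1 disables the non-significance stop so the estimate converges
  ap2 <- adaptive_permutation(statf, Xe, Ye,
                              permutation_plan(alpha = 0.99, max_perm = 20000,
                                               precision = 0.05),
                              seed = 2)
  expect_lt(abs(ap2$p - p_exact), 0.05)

  # early-stopped and full-budget estimates agree within the precision c
  set.seed(143)
  Xr <- matrix(rbinom(60, 2, 0.3), 30)
  Yr <- sample(rep(0:1, 15))
  nr <- fit_null(Yr)
  fr <- function(X, Yp) skat_Q(X, Yp, nr$mu, rep(1, 2), 0)
  a_small <- adaptive_permutation(fr, Xr, Yr,
                                  permutation_plan(max_perm = 5000, precision = 0.2),
                                  seed = 3)
  a_full <- adaptive_permutation(fr, Xr, Yr,
                                 permutation_plan(max_perm = 5000, precision = 0.001),
                                 seed = 4)
  expect_lt(abs(a_small$p - a_full$p) / a_full$p, 3 * 0.2)
})

test_that("permutation p-values respect the (b+1)/(m+1) bounds", {
  set.seed(144)
  X <- matrix(rbinom(40, 1, 0.3), 20)
  Y <- rep(0:1, 10)
  null <- fit_null(Y)
  for (s in 1:5) {
    ap <- adaptive_permutation(function(X, Yp) score_test(rowSums(X), Yp, null)$Q,
                               X, Y, permutation_plan(max_perm = 100), seed = s)
    expect_gt(ap$p, 0)
    expect_lte(ap$p, 1)
    expect_gte(ap$p, 1 / (ap$permutations_used + 1))
  }
})

test_that("stratified permutation follows Fisher's noncentral hypergeometric law", {
  # conservation of the case count in every draw
  set.seed(151)
  theta <- exp(rnorm(12))
  for (i in 1:50) expect_equal(sum(stratified_permutation_theta(theta, 5)), 5)

  # N = 3, N1 = 1, odds (2,1,1): individual 1 is the case with probability 1/2
  set.seed(152)
  hits <- sum(replicate(8000, stratified_permutation_theta(c(2, 1, 1), 1)[1]))
  expect_gt(binom.test(hits, 8000, 0.5)$p.value, 0.001)

  # equal odds reduce to the uniform choice of N1 cases (chi-square GOF over
  # all 20 subsets at N = 6)
  set.seed(153)
  draws <- replicate(10000, paste(stratified_permutation_theta(rep(1, 6), 3),
                                  collapse = ""))
  tab <- table(draws)
  expect_equal(length(tab), 20L)
  gof <- sum((tab - 500)^2 / 500)
  expect_lt(gof, qchisq(0.99, df = 19))

  # interface over a fitted null: odds exp(alpha0 + alpha'Z)
  Y <- rep(0:1, each = 30)
  Z <- cbind(c(rnorm(30, -1), rnorm(30, 1)))
  null <- fit_null(Y, Z)
  draw <- stratified_permutation(null, 30, seed = 9)
  expect_equal(sum(draw), 30)
  draw2 <- stratified_permutation(null, 30, seed = 9, literal_exp_prob = TRUE)
  expect_equal(sum(draw2), 30)
})

test_that("score-test p matches the logistic Wald test at large N", {
  set.seed(161)
  N <- 2000
  S <- rbinom(N, 3, 0.2)
  Y <- rbinom(N, 1, plogis(-0.1 + 0.1 * S))
  st <- score_test(S, Y, fit_null(Y))
  fit <- glm(Y ~ S, family = binomial())
  p_wald <- summary(fit)$coefficients["S", "Pr(>|z|)"]
  expect_lt(abs(st$p - p_wald) / p_wald, 0.1)
})

test_that("null covariates leave p-values essentially unchanged", {
  set.seed(171)
  diffs <- replicate(40, {
    inst <- small_instance(sample.int(1e6, 1), n_cases = 40, n_controls = 40)
    Z <- cbind(rnorm(length(inst$Y)))
    p0 <- rv_test(inst$X, inst$Y, "Sum")$p
    p1 <- rv_test(inst$X, inst$Y, "Sum", Z = Z, correction = "pca_model")$p
    p1 - p0
  })
  # no systematic shift at the 1% level
  expect_gt(t.test(diffs)$p.value, 0.01)
  expect_lt(mean(abs(diffs)), 0.05)
})

test_that("permutation correction preserves quotas and reduces to plain permutation without covariates", {
  inst <- small_instance(181, n_cases = 25, n_controls = 25)
  res <- pca_permutation_correction("KBAC", inst$X, inst$Y, Z_pcs = NULL,
                                    plan = permutation_plan(max_perm = 100),
                                    seed = 3)
  expect_s3_class(res, "rv_test_result")
  expect_true(res$p > 0 && res$p <= 1)
  # stratified draws with constant odds are uniform: same law as plain
  null <- fit_null(inst$Y)
  set.seed(4)
  d <- replicate(200, sum(stratified_permutation_theta(exp(null$eta), 25)))
  expect_true(all(d == 25))
})

test_that("model correction is refused for non-regression tests", {
  inst <- small_instance(191, n_cases = 20, n_controls = 20)
  Z <- cbind(rnorm(40))
  expect_error(rv_test(inst$X, inst$Y, "KBAC", Z = Z, correction = "pca_model"),
               "not representable")
  expect_error(rv_test(inst$X, inst$Y, "DoEstRare", Z = Z,
                       correction = "pca_model", positions = inst$positions,
                       Lg = inst$Lg),
               "not representable")
})
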