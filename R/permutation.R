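#' Adaptive permutation plan
#'
#' Parameters of the adaptive permutation procedure: permutations are added
#' until either (a) the Monte-Carlo coefficient of variation of the p-value
#' estimate falls below `precision`, or (b) the one-sided 99% lower
#' confidence bound on the p-value exceeds `alpha` (the result is then
#' provably non-significant at `alpha`), or (c) `max_perm` permutations have
#' been used.  The estimate is `p_hat = (b + 1) / (m + 1)` with `b` the
#' number of permuted statistics at least as large as the observed one.
#'
#' @param alpha significance threshold driving early stopping.
#' @param precision target coefficient of variation `c` of the estimate.
#' @param max_perm permutation budget (default `10 / alpha`).
#' @param mode `"plain"` permutes labels uniformly; `"stratified"` draws
#'   labels from Fisher's noncentral hypergeometric distribution with the
#'   per-individual disease odds `theta` as weights.
#' @param theta per-individual disease odds (stratified mode).
#' @return A `permutation_plan`.
#' @export
permutation_plan <- function(alpha = 0.01, precision = 0.2,
                             max_perm = ceiling(10 / alpha),
                             mode = c("plain", "stratified"), theta = NULL) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, precision > 0, precision < 1, max_perm >= 1)
  if (mode == "stratified" && is.null(theta))
    stopf("stratified mode requires theta")
  if (!is.null(theta) && any(theta <= 0)) stopf("theta must be positive")
  structure(list(alpha = alpha, precision = precision,
                 max_perm = as.integer(max_perm), mode = mode, theta = theta),
            class = "permutation_plan")
}

#' Adaptive permutation p-value
#'
#' Recomputes `stat_fn(X, Y*)` under permuted phenotypes and returns the
#' `(b + 1) / (m + 1)` permutation p-value with early stopping as described
#' in [permutation_plan()].  Larger statistics must indicate stronger
#' association.
#'
#' @param stat_fn function of `(X, Y)` returning a scalar statistic,
#'   deterministic given its arguments.
#' @param X genotype matrix passed through to `stat_fn`.
#' @param Y observed 0/1 phenotypes.
#' @param plan a [permutation_plan()].
#' @param seed optional integer seed.
#' @return List with `p`, `permutations_used`, `b`, and `stopped_early`.
#' @examples
#' X <- matrix(rbinom(40, 1, 0.2), 20)
#' f <- function(X, Y) abs(sum(X[Y == 1, ]) - sum(X[Y == 0, ]))
#' adaptive_permutation(f, X, rep(0:1, 10), permutation_plan(max_perm = 200), seed = 1)
#' @export
adaptive_permutation <- function(stat_fn, X, Y, plan = permutation_plan(),
                                 seed = NULL) {
  obs <- stat_fn(X, Y)
  if (!is.finite(obs)) stopf("observed statistic is not finite")
  tol <- 1e-12 * max(1, abs(obs))
  check_every <- 20L
  with_seed(seed, {
    b <- 0L; m <- 0L; stopped <- FALSE
    while (m < plan$max_perm) {
      Yp <- if (plan$mode == "plain") sample(Y)
            else stratified_permutation_theta(plan$theta, sum(Y == 1))
      m <- m + 1L
      if (stat_fn(X, Yp) >= obs - tol) b <- b + 1L
      if (m %% check_every == 0L && m >= 20L) {
        p_hat <- (b + 1) / (m + 1)
        cv <- sqrt((1 - p_hat) / (m * p_hat))
        lower <- p_hat - qnorm(0.99) * sqrt(p_hat * (1 - p_hat) / m)
        if (cv <= plan$precision || lower > plan$alpha) { stopped <- TRUE; break }
      }
    }
    list(p = (b + 1) / (m + 1), permutations_used = m, b = b,
         stopped_early = stopped)
  })
}

#' Stratification-preserving label permutation
#'
#' Draws a relabelling with exactly `N1` cases from the multivariate Fisher
#' noncentral hypergeometric distribution with per-individual disease odds
#' `theta_i` — the law of independent Bernoulli draws with success odds
#' `theta_i` conditioned on their sum equalling `N1` — so that permuted data
#' retain the covariate-driven (e.g. stratification) structure of the
#' original sample.  Sampling is by conditional-Bernoulli rejection, which
#' is exact; when `theta` comes from a fitted null model the acceptance
#' probability is high because the MLE intercept centres the Bernoulli sum
#' at `N1`.
#'
#' @param null a [fit_null()] model; the odds are
#'   `theta_i = exp(alpha0 + alpha'Z_i)` (set `literal_exp_prob = TRUE` for
#'   the variant `theta_i = exp(P(Y_i = 1 | Z_i))`).
#' @param N1 number of cases in each draw.
#' @param seed optional integer seed.
#' @param literal_exp_prob use the exponential of the fitted probability as
#'   the odds instead of the fitted odds.
#' @return Integer 0/1 vector with `sum == N1`.
#' @export
stratified_permutation <- function(null, N1, seed = NULL,
                                   literal_exp_prob = FALSE) {
  theta <- if (literal_exp_prob) exp(null$mu) else exp(null$eta)
  with_seed(seed, stratified_permutation_theta(theta, N1))
}

#' @rdname stratified_permutation
#' @param theta positive per-individual disease odds.
#' @export
stratified_permutation_theta <- function(theta, N1) {
  n <- length(theta)
  if (N1 < 0 || N1 > n) stopf("N1 must lie in [0, length(theta)]")
  if (N1 == 0) return(integer(n))
  if (N1 == n) return(rep(1L, n))
  if (N1 == 1) {  # closed form: inclusion proportional to the odds
    out <- integer(n)
    out[sample.int(n, 1, prob = theta)] <- 1L
    return(out)
  }
  pi <- theta / (1 + theta)
  batch <- 64L
  for (round in seq_len(4000L)) {
    U <- matrix(runif(n * batch), n, batch) < pi
    hit <- which(colSums(U) == N1)
    if (length(hit)) return(as.integer(U[, hit[1]]))
  }
  stopf("conditional-Bernoulli sampler failed to hit the case quota; odds are too extreme")
}
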