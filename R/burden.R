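#' CAST carrier indicator score
#'
#' The cohort allelic sums test collapses a gene to a binary score: 1 when an
#' individual carries at least one rare allele, 0 otherwise.
#'
#' @param X rare-variant minor-allele count matrix (individuals x variants).
#' @return Numeric 0/1 vector of length `nrow(X)`.
#' @examples
#' cast_scores(rbind(c(0, 0), c(0, 2), c(1, 1)))
#' @export
cast_scores <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) == 0) stopf("CAST requires at least one variant")
  as.numeric(rowSums(X) >= 1)
}

#' Weighted-sum burden score
#'
#' `S_i = sum_j w_j X_ij`, the weighted sum of minor-allele counts.
#'
#' @param X rare-variant count matrix.
#' @param weights per-variant weights (length `ncol(X)`).
#' @return Numeric score vector of length `nrow(X)`.
#' @examples
#' weighted_sum_scores(rbind(c(1, 0, 2)), c(1, 1, 1))
#' @export
weighted_sum_scores <- function(X, weights) {
  X <- as.matrix(X)
  if (length(weights) != ncol(X))
    stopf("weight length (%d) does not match variant count (%d)", length(weights), ncol(X))
  as.numeric(X %*% weights)
}

#' Score test for a burden score
#'
#' Tests `beta = 0` in `logit(P(Y=1)) = alpha0 + beta S` with the score
#' statistic `U = S'(Y - mu_hat)` and, without covariates, the variance
#' `V = (Y - mu_hat)'(Y - mu_hat) (S - S_bar)'(S - S_bar) / (N - 1)`;
#' with covariates in the null model the efficient score variance
#' `S'DS - S'D Zt (Zt'D Zt)^-1 Zt'D S` (with `D = diag(mu(1 - mu))`) is
#' used.  `Q = U^2 / V` is referred to a 1-df chi-square.
#'
#' @param S numeric score vector.
#' @param Y 0/1 phenotype vector.
#' @param null a [fit_null()] model.
#' @return A `score_test_result`: list with `U`, `V`, `Q`, `p`, and
#'   `degenerate` (`TRUE` when `S` is constant, in which case `p = 1`).
#' @examples
#' st <- score_test(c(1, 1, 0, 0), c(1, 1, 0, 0), fit_null(c(1, 1, 0, 0)))
#' st$Q  # 3
#' @export
score_test <- function(S, Y, null) {
  S <- as.numeric(S)
  Y <- as.numeric(Y)
  if (length(S) != length(Y)) stopf("S must have length N")
  n <- length(Y)
  r <- Y - null$mu
  U <- sum(S * r)
  if (isTRUE(null$has_covariates)) {
    B <- .half_projected(matrix(S, ncol = 1), null)
    V <- sum(B^2)
  } else {
    Sc <- S - mean(S)
    V <- sum(r^2) * sum(Sc^2) / (n - 1)
  }
  if (V <= .Machine$double.eps * n) {
    return(structure(list(U = U, V = 0, Q = 0, p = 1, degenerate = TRUE),
                     class = "score_test_result"))
  }
  Q <- U^2 / V
  structure(list(U = U, V = V, Q = Q,
                 p = pchisq(Q, df = 1, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "score_test_result")
}

#' @export
print.score_test_result <- function(x, ...) {
  cat(sprintf("Score test: U = %.4g, V = %.4g, Q = %.4g, p = %.4g%s\n",
              x$U, x$V, x$Q, x$p, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Adaptive signs for the aSum burden test
#'
#' A marginal score test is applied to each variant; a variant is flagged
#' protective (sign -1) when its marginal test is significant at
#' `marginal_alpha` with the minor allele enriched in controls (`U_j < 0`);
#' all other variants keep sign +1.
#'
#' @param X rare-variant count matrix.
#' @param Y 0/1 phenotypes.
#' @param null a [fit_null()] model.
#' @param marginal_alpha significance level of the marginal classification
#'   (the source method's conventional 0.10).
#' @return Integer vector of +1/-1 signs, length `ncol(X)`.
#' @export
asum_signs <- function(X, Y, null, marginal_alpha = 0.10) {
  stopifnot(marginal_alpha > 0, marginal_alpha < 1)
  X <- as.matrix(X)
  n <- nrow(X)
  r <- Y - null$mu
  U <- as.numeric(crossprod(X, r))
  if (isTRUE(null$has_covariates)) {
    B <- .half_projected(X, null)
    V <- colSums(B^2)
  } else {
    ss <- colSums(X^2) - n * colMeans(X)^2
    V <- sum(r^2) * ss / (n - 1)
  }
  p <- ifelse(V <= .Machine$double.eps * n, 1,
              pchisq(U^2 / pmax(V, .Machine$double.eps), df = 1, lower.tail = FALSE))
  ifelse(p < marginal_alpha & U < 0, -1L, +1L)
}
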