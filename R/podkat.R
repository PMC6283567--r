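#' Position proximity kernel
#'
#' Triangular proximity between variants `j, j'`:
#' `A[j, j'] = max(1 - d_jj' / radius, 0)` with `d` the absolute physical
#' distance in bp, so the kernel is 1 on the diagonal and 0 at or beyond the
#' radius of tolerance.
#'
#' @param positions variant positions in bp.
#' @param radius maximal radius of tolerance in bp (default 1,000).
#' @return A `position_kernel`: symmetric P x P matrix with unit diagonal.
#' @examples
#' podkat_kernel(c(100, 350, 2000), radius = 1000)
#' @export
podkat_kernel <- function(positions, radius = 1000) {
  if (radius <= 0) stopf("radius must be positive")
  d <- abs(outer(positions, positions, `-`))
  A <- pmax(1 - d / radius, 0)
  structure(A, class = c("position_kernel", "matrix"), radius = radius)
}

#' PODKAT statistic
#'
#' `Q = (Y - mu_hat)' X W A A' W X' (Y - mu_hat)`, the SKAT quadratic form
#' with the position kernel `A A'` in place of the identity; equivalently the
#' squared Euclidean norm of `A' W X' (Y - mu_hat)`.
#'
#' @inheritParams skat_Q
#' @param kernel a [podkat_kernel()] (dimension `ncol(X)`).
#' @return The statistic `Q` (scalar).
#' @export
podkat_Q <- function(X, Y, mu_hat, weights, kernel) {
  if (inherits(mu_hat, "null_model")) mu_hat <- mu_hat$mu
  X <- as.matrix(X)
  if (nrow(kernel) != ncol(X)) stopf("kernel dimension must equal ncol(X)")
  u <- as.numeric(crossprod(X, Y - mu_hat)) * weights
  sum(as.numeric(crossprod(kernel, u))^2)
}

#' PODKAT analytic p-value
#'
#' Null tail of [podkat_Q()] via the mixture-of-chi-squares distribution of
#' the covariate-projected kernel, as for [skat_pvalue()].
#'
#' @inheritParams skat_pvalue
#' @param radius kernel radius in bp.
#' @param positions variant positions in bp.
#' @return List with `Q`, `p`, `lambdas`.
#' @export
podkat_pvalue <- function(X, Y, null, weights = NULL, positions, radius = 1000) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, ncol(X))
  A <- podkat_kernel(positions, radius)
  Q <- podkat_Q(X, Y, null$mu, weights, A)
  M <- sweep(X, 2, weights, `*`) %*% A
  B <- .half_projected(M, null)
  ev <- eigen(crossprod(B), symmetric = TRUE, only.values = TRUE)$values
  lam <- ev[ev > max(ev) * 1e-10]
  if (length(lam) == 0) return(list(Q = Q, p = 1, lambdas = lam, degenerate = TRUE))
  list(Q = Q, p = as.numeric(mixture_chisq_sf(lam, Q)), lambdas = lam,
       degenerate = FALSE)
}
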