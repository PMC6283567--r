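#' Fit the logistic null model
#'
#' Maximum-likelihood logistic regression of the case/control status on the
#' covariates (model `logit(P(Y=1|Z)) = alpha0 + alpha'Z`), fitted by
#' iteratively reweighted least squares.  Without covariates the closed form
#' `mu_hat = mean(Y)` is used.
#'
#' @param Y 0/1 phenotype vector (non-constant).
#' @param Z optional numeric covariate matrix (one row per individual),
#'   e.g. principal components.
#' @return A `null_model`: list with `alpha0`, `alpha`, `mu` (fitted means),
#'   `eta` (linear predictor), `Z`, and `has_covariates`.
#' @section Errors: perfect (quasi-)separation of `Y` by `Z` — fitted
#'   probabilities numerically 0 or 1 — raises an error; stratification
#'   corrections are undefined in that regime (e.g. when the leading PC
#'   coincides with the phenotype).
#' @examples
#' fit_null(rep(0:1, each = 10))$alpha0
#' @export
fit_null <- function(Y, Z = NULL) {
  Y <- as.numeric(Y)
  if (!all(Y %in% c(0, 1))) stopf("Y must be binary 0/1")
  if (length(unique(Y)) < 2) stopf("Y is constant; the null model is undefined")
  n <- length(Y)
  if (is.null(Z)) {
    p <- mean(Y)
    out <- list(alpha0 = qlogis(p), alpha = numeric(0),
                mu = rep(p, n), eta = rep(qlogis(p), n),
                Z = NULL, has_covariates = FALSE)
  } else {
    Z <- as.matrix(Z)
    if (nrow(Z) != n) stopf("Z must have one row per individual")
    Zt <- cbind(`(Intercept)` = 1, Z)
    fit <- suppressWarnings(glm.fit(Zt, Y, family = binomial()))
    aliased <- is.na(fit$coefficients)
    if (any(aliased)) {  # drop aliased columns (e.g. constants) and refit
      Zt <- Zt[, !aliased, drop = FALSE]
      fit <- suppressWarnings(glm.fit(Zt, Y, family = binomial()))
    }
    mu <- fit$fitted.values
    if (any(mu < 1e-10 | mu > 1 - 1e-10))
      stopf("perfect separation: covariates fully determine some phenotypes")
    out <- list(alpha0 = unname(fit$coefficients[1]),
                alpha = unname(fit$coefficients[-1]),
                mu = as.numeric(mu),
                eta = as.numeric(fit$linear.predictors),
                Z = Z, Zt = Zt, has_covariates = TRUE)
  }
  structure(out, class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("Logistic null model: alpha0 = %.4f, %d covariate(s), n = %d\n",
              x$alpha0, length(x$alpha), length(x$mu)))
  invisible(x)
}

# Residuals and the covariate-adjusted variance machinery shared by the
# kernel tests.  Returns the adjusted half-kernel B = P^(1/2) M for an
# N x P matrix M, where P = D - D Zt (Zt' D Zt)^-1 Zt' D is the logistic
# projection with D = diag(mu (1 - mu)).
.half_projected <- function(M, null) {
  v <- null$mu * (1 - null$mu)
  sv <- sqrt(v)
  B <- M * sv
  n <- length(v)
  Zt <- if (is.null(null$Zt)) matrix(1, n, 1) else null$Zt
  ZtD <- Zt * v
  A <- crossprod(Zt, ZtD)          # Zt' D Zt
  C <- crossprod(ZtD, M)           # Zt' D M
  B - (Zt * sv) %*% solve(A, C)
}
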