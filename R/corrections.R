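#' PCA model correction
#'
#' Applies the "PCA model correction": the leading principal components
#' enter the logistic null model as covariates
#' (`logit(P(Y=1|X,Z)) = alpha0 + alpha'Z + beta'X`), so score and kernel
#' statistics use covariate-adjusted residuals and the covariate-projected
#' variance.  Only regression-representable tests support it (the burden
#' family, SKAT family and PODKAT); KBAC and DoEstRare do not.
#'
#' @param method method name (see [rv_test()]).
#' @param X rare-variant count matrix.
#' @param Y 0/1 phenotypes.
#' @param Z_pcs principal-component covariate matrix.
#' @param ... further arguments passed to [rv_test()].
#' @return An `rv_test_result`.
#' @export
pca_model_correction <- function(method, X, Y, Z_pcs, ...) {
  rv_test(X, Y, method, Z = Z_pcs, correction = "pca_model", ...)
}

#' PCA permutation correction
#'
#' Applies the "PCA permutation correction": the null model
#' `logit(P(Y=1|Z)) = alpha0 + alpha'Z` is fitted once per gene, the fitted
#' disease odds become individual weights, and adaptive permutation draws
#' each permuted phenotype from Fisher's noncentral hypergeometric
#' distribution ([stratified_permutation()]) so permuted data retain the
#' population stratification.  Applicable to every method, including KBAC
#' and DoEstRare.
#'
#' @inheritParams pca_model_correction
#' @param plan a [permutation_plan()] (mode is switched to stratified
#'   internally).
#' @param seed optional integer seed.
#' @return An `rv_test_result`.
#' @export
pca_permutation_correction <- function(method, X, Y, Z_pcs,
                                       plan = permutation_plan(), seed = NULL,
                                       ...) {
  rv_test(X, Y, method, Z = Z_pcs, correction = "pca_perm",
          plan = plan, seed = seed, ...)
}
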