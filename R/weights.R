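#' Per-variant MAF-based weights
#'
#' The weighting systems used by the weighted burden and kernel tests:
#' \describe{
#'   \item{`uniform`}{`w_j = 1`.}
#'   \item{`beta_maf_total`}{`w_j = Beta(MAF_j; 1, 25)` density evaluated at
#'     the plug-in sample MAF over all individuals (cases and controls), the
#'     SKAT convention; equals `25 (1 - MAF)^24`, so 25 at MAF 0.}
#'   \item{`invsd_maf_total`}{`w_j = 1 / sqrt(N MAF_j (1 - MAF_j))` with the
#'     plug-in total-sample MAF; columns monomorphic in the sample
#'     (MAF 0 or 1) receive weight 0 and are recorded in the `"excluded"`
#'     attribute (they carry no information for the score).}
#'   \item{`invsd_maf_controls`}{same form but with the pseudo-count control
#'     MAF estimator `(sum_{controls} X_ij + 1) / (2 N0 + 2)`, which is
#'     always in (0, 1) so the weight is finite.}
#' }
#'
#' @param scheme weighting scheme name.
#' @param X minor-allele count matrix.
#' @param Y 0/1 phenotypes; required by `invsd_maf_controls`.
#' @param a1,a2 Beta parameters of the `beta_maf_total` scheme.
#' @return Non-negative weight vector of length `ncol(X)`.
#' @examples
#' X <- rbind(c(0, 1), c(0, 1), c(0, 0), c(1, 0))
#' compute_weights("beta_maf_total", X)
#' compute_weights("invsd_maf_controls", X, Y = c(1, 1, 0, 0))
#' @export
compute_weights <- function(scheme = c("uniform", "beta_maf_total",
                                       "invsd_maf_total", "invsd_maf_controls"),
                            X, Y = NULL, a1 = 1, a2 = 25) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  N <- nrow(X)
  switch(scheme,
    uniform = rep(1, ncol(X)),
    beta_maf_total = {
      maf <- colMeans(X) / 2
      dbeta(maf, a1, a2)
    },
    invsd_maf_total = {
      maf <- colMeans(X) / 2
      mono <- maf <= 0 | maf >= 1
      w <- numeric(ncol(X))
      w[!mono] <- 1 / sqrt(N * maf[!mono] * (1 - maf[!mono]))
      structure(w, excluded = which(mono))
    },
    invsd_maf_controls = {
      if (is.null(Y)) stopf("invsd_maf_controls requires Y")
      N0 <- sum(Y == 0)
      if (N0 < 1) stopf("invsd_maf_controls requires at least one control")
      maf0 <- (colSums(X[Y == 0, , drop = FALSE]) + 1) / (2 * N0 + 2)
      1 / sqrt(N * maf0 * (1 - maf0))
    })
}
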