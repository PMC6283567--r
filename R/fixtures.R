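#' Hand-verified test fixtures
#'
#' Tiny deterministic genotype/phenotype instances with expected statistic
#' values derived by hand; regenerated identically on every call.
#'
#' Available fixtures:
#' \describe{
#'   \item{`score_4`}{`S = (1,1,0,0)`, `Y = (1,1,0,0)`: `U = 1`, `V = 1/3`,
#'     `Q = 3`.}
#'   \item{`kbac_4`}{2 cases / 2 controls, one carrier genotype in one case:
#'     carrier weight `0.5`, statistic `0.0625` under the full
#'     (wild-type-inclusive) sum.}
#'   \item{`skat_4`}{`Y = (1,1,0,0)`, `mu = 0.5`, unit weights, two
#'     single-carrier columns: `Q(rho = 0) = 0.5`.}
#'   \item{`podkat_kernel`}{positions `(0, 250, 1000)` at radius 1,000 with
#'     expected proximities 1, 0.75, 0.}
#'   \item{`weights_4`}{`N = 4`, `N0 = 2`, control allele count 2: control
#'     MAF estimate 0.5, inverse-sd weight 1; Beta(1, 25) weight at MAF 0
#'     is 25.}
#' }
#'
#' @param name fixture name.
#' @return A list with the instance and its `expected` values.
#' @examples
#' make_fixture("score_4")$expected$Q
#' @export
make_fixture <- function(name = c("score_4", "kbac_4", "skat_4",
                                  "podkat_kernel", "weights_4")) {
  name <- match.arg(name)
  switch(name,
    score_4 = list(
      S = c(1, 1, 0, 0), Y = c(1, 1, 0, 0), mu = rep(0.5, 4),
      expected = list(U = 1, V = 1 / 3, Q = 3,
                      p = pchisq(3, 1, lower.tail = FALSE))),
    kbac_4 = list(
      X = matrix(c(1, 0, 0, 0), ncol = 1), Y = c(1, 0, 1, 0),
      expected = list(carrier_weight = 0.5, statistic = 0.0625)),
    skat_4 = list(
      X = cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)), Y = c(1, 1, 0, 0),
      mu = rep(0.5, 4), weights = c(1, 1),
      expected = list(Q_rho0 = 0.5, Q_rho1 = 1)),
    podkat_kernel = list(
      positions = c(0, 250, 1000), radius = 1000,
      expected = list(A12 = 0.75, A13 = 0, diag = 1)),
    weights_4 = list(
      X = rbind(c(0), c(0), c(1), c(1)), Y = c(1, 1, 0, 0),
      expected = list(maf_ctrl = 0.5, w_invsd_ctrl = 1, w_beta_at_0 = 25)))
}
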