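#' Gene-based rare-variant association tests
#'
#' Unified interface to the nine association strategies and their weighting
#' variants.  Available methods:
#'
#' | method | statistic | default significance |
#' |---|---|---|
#' | `CAST` | carrier-indicator score test | analytic (1-df chi-square) |
#' | `Sum` | unweighted allele-count score test | analytic |
#' | `wSum_MAFtot`, `wSum_betaMAFtot` | weighted sum, total-sample MAF weights | analytic |
#' | `wSum_MAFctrl` | weighted sum, control-MAF weights | adaptive permutation |
#' | `aSum` | adaptive-sign sum | adaptive permutation |
#' | `KBAC` | multi-site genotype kernel | adaptive permutation |
#' | `SKAT`, `wSKAT_MAFtot`, `wSKAT_betaMAFtot` | variance-component quadratic form | analytic (chi-square mixture) |
#' | `SKATO`, `wSKATO_MAFtot`, `wSKATO_betaMAFtot` | optimal-rho SKAT | analytic |
#' | `PODKAT` | position-kernel quadratic form | analytic (requires `positions`) |
#' | `DoEstRare` | position-density comparison | adaptive permutation (requires `positions`, `Lg`) |
#'
#' Analytic significance is used by default wherever the statistic's null
#' distribution is valid without resampling; `aSum` and `wSum_MAFctrl`
#' select signs/weights from the phenotype, so their chi-square reference is
#' anti-conservative and permutation (which recomputes the selection in
#' every replay) is the default.  `significance = "permutation"` forces the
#' permutation route for any method.
#'
#' @param X minor-allele count matrix of the gene's rare variants
#'   (individuals x variants); columns monomorphic in the sample are allowed
#'   and contribute nothing.
#' @param Y 0/1 phenotype vector.
#' @param method method name (see table).
#' @param positions variant positions in bp (position tests).
#' @param Lg gene length in bp (DoEstRare).
#' @param Z covariate matrix (principal components) used by the corrections.
#' @param correction `"none"`, `"pca_model"` (covariates enter the null
#'   model; not available for KBAC/DoEstRare), or `"pca_perm"`
#'   (stratification-preserving permutation, any method).
#' @param significance `"default"`, `"analytic"` or `"permutation"`.
#' @param plan a [permutation_plan()] for permutation significance.
#' @param seed optional integer seed (permutation routes).
#' @param marginal_alpha aSum marginal classification level.
#' @param radius PODKAT kernel radius in bp.
#' @param kbac_include_wildtype include the wild-type class in the KBAC sum.
#' @return An `rv_test_result`: list with `method`, `statistic`, `p`,
#'   `permutations` (NA for analytic routes), `correction`, `n_variants`.
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(600, 2, 0.03), nrow = 100)
#' Y <- rep(0:1, each = 50)
#' rv_test(X, Y, "Sum")
#' rv_test(X, Y, "SKAT")
#' @export
rv_test <- function(X, Y, method = "Sum", positions = NULL, Lg = NULL,
                    Z = NULL,
                    correction = c("none", "pca_model", "pca_perm"),
                    significance = c("default", "analytic", "permutation"),
                    plan = permutation_plan(), seed = NULL,
                    marginal_alpha = 0.10, radius = 1000,
                    kbac_include_wildtype = TRUE) {
  correction <- match.arg(correction)
  significance <- match.arg(significance)
  method <- match.arg(method, rv_methods())
  X <- as.matrix(X)
  if (ncol(X) == 0) stopf("no variants to test")
  Y <- as.numeric(Y)
  if (nrow(X) != length(Y)) stopf("X and Y dimensions disagree")
  info <- .method_info(method)
  if (info$positional && is.null(positions))
    stopf("%s requires variant positions", method)
  if (method == "DoEstRare" && is.null(Lg)) stopf("DoEstRare requires Lg")
  if (correction == "pca_model" && is.null(Z)) stopf("pca_model correction requires Z")
  if (correction == "pca_model" && !info$model_correctable)
    stopf("%s is not representable as a logistic regression; use the permutation correction", method)

  null <- fit_null(Y, if (correction %in% c("pca_model", "pca_perm")) Z else NULL)
  use_perm <- switch(significance,
                     permutation = TRUE,
                     analytic = FALSE,
                     default = info$perm_default || correction == "pca_perm")
  if (correction == "pca_perm") use_perm <- TRUE
  if (use_perm && significance == "analytic")
    stopf("analytic significance is not available for this configuration")
  if (!use_perm && !info$analytic)
    stopf("%s has no analytic null; use permutation significance", method)

  ctx <- list(marginal_alpha = marginal_alpha, radius = radius,
              kbac_include_wildtype = kbac_include_wildtype,
              positions = positions, Lg = Lg)

  if (!use_perm) {
    res <- .analytic_route(method, X, Y, null, ctx)
    out <- list(method = method, statistic = res$statistic, p = res$p,
                permutations = NA_integer_, correction = correction,
                n_variants = ncol(X))
  } else {
    stat_fn <- .perm_stat_fn(method, X, Y, null, ctx)
    pl <- plan
    if (correction == "pca_perm")
      pl <- permutation_plan(plan$alpha, plan$precision, plan$max_perm,
                             mode = "stratified", theta = exp(null$eta))
    ap <- adaptive_permutation(stat_fn, X, Y, pl, seed = seed)
    out <- list(method = method, statistic = stat_fn(X, Y), p = ap$p,
                permutations = ap$permutations_used, correction = correction,
                n_variants = ncol(X))
  }
  structure(out, class = "rv_test_result")
}

#' @export
print.rv_test_result <- function(x, ...) {
  cat(sprintf("%s%s: statistic = %.4g, p = %.4g%s (%d variants)\n",
              x$method,
              if (x$correction == "none") "" else paste0(" [", x$correction, "]"),
              x$statistic, x$p,
              if (is.na(x$permutations)) "" else sprintf(" (%d permutations)", x$permutations),
              x$n_variants))
  invisible(x)
}

#' Names of the implemented association methods
#' @return Character vector of method names accepted by [rv_test()].
#' @export
rv_methods <- function() {
  c("CAST", "Sum", "wSum_MAFtot", "wSum_betaMAFtot", "wSum_MAFctrl", "aSum",
    "KBAC", "SKAT", "wSKAT_MAFtot", "wSKAT_betaMAFtot",
    "SKATO", "wSKATO_MAFtot", "wSKATO_betaMAFtot", "PODKAT", "DoEstRare")
}

.method_info <- function(method) {
  burden <- c("CAST", "Sum", "wSum_MAFtot", "wSum_betaMAFtot", "wSum_MAFctrl", "aSum")
  skat <- c("SKAT", "wSKAT_MAFtot", "wSKAT_betaMAFtot")
  skato <- c("SKATO", "wSKATO_MAFtot", "wSKATO_betaMAFtot")
  list(
    family = if (method %in% burden) "burden"
             else if (method %in% skat) "skat"
             else if (method %in% skato) "skato"
             else tolower(method),
    weight_scheme = switch(method,
      wSum_MAFtot = , wSKAT_MAFtot = , wSKATO_MAFtot = "invsd_maf_total",
      wSum_betaMAFtot = , wSKAT_betaMAFtot = , wSKATO_betaMAFtot = "beta_maf_total",
      wSum_MAFctrl = "invsd_maf_controls",
      "uniform"),
    perm_default = method %in% c("wSum_MAFctrl", "aSum", "KBAC", "DoEstRare"),
    analytic = !(method %in% c("KBAC", "DoEstRare")),
    model_correctable = !(method %in% c("KBAC", "DoEstRare")),
    positional = method %in% c("PODKAT", "DoEstRare")
  )
}

# burden score builder; Y-dependent parts (signs, control weights) are
# recomputed from the supplied phenotype so permutation replays them
.burden_scores <- function(method, X, Y, null, ctx) {
  info <- .method_info(method)
  if (method == "CAST") return(cast_scores(X))
  if (method == "aSum") {
    s <- asum_signs(X, Y, null, ctx$marginal_alpha)
    return(weighted_sum_scores(X, s))
  }
  w <- compute_weights(info$weight_scheme, X, Y = Y)
  weighted_sum_scores(X, w)
}

.analytic_route <- function(method, X, Y, null, ctx) {
  info <- .method_info(method)
  if (info$family == "burden") {
    st <- score_test(.burden_scores(method, X, Y, null, ctx), Y, null)
    return(list(statistic = st$Q, p = st$p))
  }
  w <- compute_weights(info$weight_scheme, X, Y = Y)
  if (info$family == "skat") {
    res <- skat_pvalue(X, Y, null, weights = w, rho = 0)
    return(list(statistic = res$Q, p = res$p))
  }
  if (info$family == "skato") {
    res <- skato_pvalue(X, Y, null, weights = w)
    return(list(statistic = min(res$Q_rho), p = res$p))
  }
  if (method == "PODKAT") {
    res <- podkat_pvalue(X, Y, null, weights = w, positions = ctx$positions,
                         radius = ctx$radius)
    return(list(statistic = res$Q, p = res$p))
  }
  stopf("no analytic route for %s", method)
}

# statistic closures for the permutation routes (null model fixed per gene)
.perm_stat_fn <- function(method, X, Y, null, ctx) {
  info <- .method_info(method)
  if (info$family == "burden") {
    return(function(X, Yp) score_test(.burden_scores(method, X, Yp, null, ctx),
                                      Yp, null)$Q)
  }
  if (method == "KBAC") {
    cls <- .kbac_classes(X)
    N1 <- sum(Y == 1); N0 <- sum(Y == 0)
    return(function(X, Yp)
      .kbac_from_classes(cls, Yp, N1, N0, ctx$kbac_include_wildtype)$statistic)
  }
  if (method == "DoEstRare") {
    setup <- .doestrare_setup(X, ctx$positions, ctx$Lg)
    return(function(X, Yp) .doestrare_stat(setup, X, Yp)$statistic)
  }
  if (info$family == "skat") {
    w <- compute_weights(info$weight_scheme, X, Y = Y)
    return(function(X, Yp) skat_Q(X, Yp, null$mu, w, rho = 0))
  }
  if (method == "PODKAT") {
    w <- compute_weights(info$weight_scheme, X, Y = Y)
    A <- podkat_kernel(ctx$positions, ctx$radius)
    return(function(X, Yp) podkat_Q(X, Yp, null$mu, w, A))
  }
  if (info$family == "skato") {
    w <- compute_weights(info$weight_scheme, X, Y = Y)
    Xw <- sweep(X, 2, w, `*`)
    B <- .half_projected(Xw, null)
    C <- crossprod(B)
    rho_grid <- seq(0, 1, by = 0.1)
    lam_list <- lapply(rho_grid, function(r) .skat_lambdas(C, r))
    return(function(X, Yp) {
      u <- as.numeric(crossprod(X, Yp - null$mu)) * w
      q <- (1 - rho_grid) * sum(u^2) + rho_grid * sum(u)^2
      pr <- vapply(seq_along(rho_grid), function(i) {
        if (length(lam_list[[i]]) == 0) 1 else .liu_sf(lam_list[[i]], q[i])
      }, numeric(1))
      -log(max(min(pr), 1e-300))
    })
  }
  stopf("no permutation statistic for %s", method)
}
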