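#' Greedy LD pruning of common variants
#'
#' Sliding-window pruning: variants failing the MAF floor are removed first,
#' then within each window of `window` variants (advanced by `step`) the
#' lower-MAF member of any pair with squared genotype correlation at least
#' `r2_max` is dropped.  Every retained pair within a window has `r2 <
#' r2_max`.
#'
#' @param X genotype count matrix (individuals x variants), position-ordered.
#' @param maf per-variant reference MAF used for the floor and tie-breaking;
#'   defaults to the sample MAF of `X`, but the deme-A panel MAF should be
#'   supplied when available.
#' @param maf_min MAF floor.
#' @param r2_max squared-correlation ceiling.
#' @param window,step window size and advance, in variants.
#' @return Integer vector of retained column indices (relative to `X`).
#' @export
ld_prune <- function(X, maf = NULL, maf_min = 0.05, r2_max = 0.2,
                     window = 50L, step = 5L) {
  X <- as.matrix(X)
  if (is.null(maf)) {
    f <- colMeans(X) / 2
    maf <- pmin(f, 1 - f)
  }
  if (length(maf) != ncol(X)) stopf("maf must have length ncol(X)")
  candidates <- which(maf >= maf_min)
  keep <- rep(TRUE, ncol(X))
  keep[-candidates] <- FALSE
  if (length(candidates) == 0) return(integer(0))
  # windows are taken over the ordered candidate list
  nc <- length(candidates)
  s <- 1L
  while (s <= nc) {
    e <- min(s + window - 1L, nc)
    w_idx <- candidates[s:e]
    w_idx <- w_idx[keep[w_idx]]
    if (length(w_idx) > 1) {
      cc <- suppressWarnings(cor(X[, w_idx, drop = FALSE]))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      for (a in seq_len(length(w_idx) - 1L)) {
        if (!keep[w_idx[a]]) next
        for (b in seq((a + 1L), length(w_idx))) {
          if (!keep[w_idx[b]]) next
          if (r2[a, b] >= r2_max) {
            drop <- if (maf[w_idx[a]] >= maf[w_idx[b]]) w_idx[b] else w_idx[a]
            keep[drop] <- FALSE
            if (drop == w_idx[a]) break
          }
        }
      }
    }
    if (e == nc) break
    s <- s + step
  }
  intersect(candidates, which(keep))
}

#' Principal component analysis of genotypes
#'
#' Ancestry-style PCA: each variant column is centred at twice its sample
#' allele frequency and scaled by the binomial standard deviation
#' `sqrt(2 p (1 - p))`; individual coordinates are the projections onto the
#' leading eigenvectors of the resulting covariance.  Monomorphic columns
#' are dropped (recorded in `dropped`).  For large matrices the top-`K`
#' subspace is found by deterministic orthogonal iteration; small problems
#' use an exact singular value decomposition.  Component signs follow the
#' convention that each component's largest-magnitude loading is positive.
#'
#' @param X genotype count matrix (individuals x variants).
#' @param K number of components.
#' @param exact_limit below this `min(N, P)`, use exact SVD.
#' @param iter_max,tol orthogonal-iteration controls.
#' @return A `pca_result`: list with `x` (N x K coordinates, mean zero per
#'   component), `eigenvalues` (non-increasing), `loadings` (P x K),
#'   `dropped` (indices of monomorphic columns).
#' @export
pca_genotypes <- function(X, K = 2L, exact_limit = 400L, iter_max = 30L,
                          tol = 1e-4) {
  X <- as.matrix(X)
  if (nrow(X) < K + 1) stopf("PCA requires at least K + 1 individuals")
  p <- colMeans(X) / 2
  mono <- p <= 0 | p >= 1
  dropped <- which(mono)
  Xu <- X[, !mono, drop = FALSE]
  p <- p[!mono]
  if (ncol(Xu) < K) stopf("PCA requires at least K polymorphic variants")
  G <- sweep(sweep(Xu, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), `/`)
  n <- nrow(G); m <- ncol(G)
  if (min(n, m) <= exact_limit) {
    sv <- svd(G, nu = K, nv = K)
    V <- sv$v
    d2 <- sv$d[seq_len(K)]^2
  } else {
    # orthogonal (subspace) iteration on G'G without forming it
    V <- qr.Q(qr(matrix(sin(outer(seq_len(m), seq_len(K) * 2)), m, K)))
    prev <- rep(Inf, K)
    for (it in seq_len(iter_max)) {
      W <- crossprod(G, G %*% V)
      qrW <- qr(W)
      V <- qr.Q(qrW)
      d2 <- abs(diag(qr.R(qrW)))
      if (max(abs(d2 - prev) / pmax(d2, 1e-12)) < tol) break
      prev <- d2
    }
    ord <- order(d2, decreasing = TRUE)
    V <- V[, ord, drop = FALSE]
    d2 <- d2[ord]
  }
  # deterministic sign: largest-|loading| entry positive
  for (k in seq_len(K)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  scores <- G %*% V
  structure(list(x = scores,
                 eigenvalues = d2 / (n - 1),
                 loadings = V,
                 dropped = dropped,
                 n_variants = m),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("Genotype PCA: %d individuals, %d variants, %d components\n",
              nrow(x$x), x$n_variants, ncol(x$x)))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Weir-Cockerham fixation index for two populations
#'
#' Per-locus variance components `a` (between populations), `b` (between
#' individuals within populations) and `c` (within individuals) of the 1984
#' Weir & Cockerham analysis-of-variance estimator, computed from genotype
#' counts, and the multi-locus ratio-of-sums estimate
#' `theta_hat = sum(a) / sum(a + b + c)`.
#'
#' @param X genotype count matrix (individuals x loci).
#' @param pop population labels (exactly two levels, each with at least two
#'   individuals).
#' @return An `fst_estimate`: list with `theta` (multi-locus estimate),
#'   per-locus `a`, `b`, `c`, and `n_loci` (loci polymorphic overall).
#' @examples
#' X <- rbind(matrix(rbinom(200, 2, 0.1), 20), matrix(rbinom(200, 2, 0.4), 20))
#' wc_fst(X, rep(c("A", "B"), each = 20))$theta
#' @export
wc_fst <- function(X, pop) {
  X <- as.matrix(X)
  pop <- factor(pop)
  if (nlevels(pop) != 2) stopf("exactly two populations are required")
  if (any(table(pop) < 2)) stopf("each population needs at least 2 individuals")
  g1 <- X[pop == levels(pop)[1], , drop = FALSE]
  g2 <- X[pop == levels(pop)[2], , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  r <- 2
  p1 <- colMeans(g1) / 2; p2 <- colMeans(g2) / 2
  h1 <- colMeans(g1 == 1); h2 <- colMeans(g2 == 1)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  if (!any(poly)) stopf("all loci are monomorphic; FST is undefined")
  theta <- sum(a[poly]) / sum((a + b + cc)[poly])
  structure(list(theta = theta, a = a, b = b, c = cc,
                 polymorphic = poly, n_loci = sum(poly)),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("Weir-Cockerham FST: %.6f over %d polymorphic loci\n",
              x$theta, x$n_loci))
  invisible(x)
}
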