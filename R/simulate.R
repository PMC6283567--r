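#' Simulate haplotype panels under the two-deme demography
#'
#' Runs the backward-in-time simulator for each of `demography$n_genes`
#' independent genes and returns one haplotype panel per gene.  Each panel
#' holds the full binary haplotype matrix of both demes (rows = haplotypes,
#' deme A first), the 1-based site positions within the region, and cached
#' per-deme derived-allele counts.
#'
#' Genes with zero segregating sites are resimulated (up to `max_tries`
#' attempts) when `on_empty = "resimulate"`, or returned as `NULL` entries
#' when `on_empty = "skip"`.
#'
#' @param demography a [demography_config()].
#' @param seed integer seed; the same seed reproduces the panels bit for bit.
#' @param on_empty what to do with genes without segregating sites.
#' @param max_tries resimulation attempts per gene before erroring.
#' @return A list of `haplotype_panel` objects (length `n_genes`).
#' @examples
#' dem <- demography_config(deme_haplotypes = 200, ancestral_haplotypes = 600,
#'                          region_length_bp = 5000)
#' panel <- simulate_two_pop(dem, seed = 1)[[1]]
#' dim(panel$H)
#' @export
simulate_two_pop <- function(demography, seed = NULL,
                             on_empty = c("resimulate", "skip"), max_tries = 100L) {
  stopifnot(inherits(demography, "demography_config"))
  on_empty <- match.arg(on_empty)
  with_seed(seed, {
    lapply(seq_len(demography$n_genes), function(g) {
      for (try in seq_len(max_tries)) {
        panel <- .sim_one_gene(demography)
        if (ncol(panel$H) > 0L) return(panel)
        if (on_empty == "skip") return(NULL)
      }
      stopf("gene %d: no segregating sites after %d attempts", g, max_tries)
    })
  })
}

.sim_one_gene <- function(demography) {
  exp_t <- if (is.null(demography$expansion)) 0 else demography$expansion$time
  exp_n <- if (is.null(demography$expansion)) 0 else demography$expansion$haplotypes
  res <- .sim_gene_cpp(demography$deme_haplotypes,
                       demography$split_time_generations,
                       demography$migration_rate,
                       demography$ancestral_haplotypes,
                       exp_t, exp_n,
                       demography$region_length_bp,
                       demography$mutation_rate)
  n_hap <- demography$deme_haplotypes
  H <- res$H
  counts_A <- if (ncol(H) > 0) colSums(H[seq_len(n_hap), , drop = FALSE]) else integer(0)
  counts_B <- if (ncol(H) > 0) colSums(H) - counts_A else integer(0)
  structure(list(
    H = H,
    positions = as.integer(res$positions),
    n_hap_A = n_hap,
    n_hap_B = n_hap,
    region_length_bp = demography$region_length_bp,
    counts_A = as.integer(counts_A),
    counts_B = as.integer(counts_B)
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d + %d haplotypes, %d segregating sites over %d bp\n",
              x$n_hap_A, x$n_hap_B, ncol(x$H), x$region_length_bp))
  invisible(x)
}

#' Minor allele frequency of panel sites within one deme
#'
#' Frequencies are computed on the full deme panel (all haplotypes), with the
#' minor allele defined relative to deme A: the derived allele when its
#' deme-A frequency is at most 0.5, the ancestral allele otherwise.
#'
#' @param panel a `haplotype_panel`.
#' @param deme `"A"` or `"B"`.
#' @return Numeric vector of per-site MAFs in `[0, 0.5]` (relative to the
#'   deme-A minor allele, so deme-B values may exceed 0.5).
#' @export
panel_maf <- function(panel, deme = c("A", "B")) {
  deme <- match.arg(deme)
  fA <- panel$counts_A / panel$n_hap_A
  f <- if (deme == "A") fA else panel$counts_B / panel$n_hap_B
  ifelse(fA <= 0.5, f, 1 - f)
}
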