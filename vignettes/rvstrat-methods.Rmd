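---
title: "Methods: simulating fine-scale stratification and testing rare-variant association"
author: "rvstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating fine-scale stratification and testing rare-variant association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rvstrat studies a practical question in rare-variant case/control analysis:
when controls are drawn partly from a *neighbouring* population — a very
fine geographical scale, on the order of adjacent regions within a country —
how badly do gene-based rare-variant tests inflate, and how much of that
inflation do standard PCA corrections remove?  The package provides the
three ingredients needed to answer it by simulation: a two-deme coalescent
generator, the association statistics themselves, and the
type-I-error/power harness.  This vignette records the models, parameter
choices, numerical policies, and the limits of what the simulations show.

## The demographic model

`demography_config()` describes a single ancestral lineage that splits into
two demes A and B of `deme_haplotypes` = 10,000 haplotypes (5,000 diploids)
each, `split_time_generations` = 80 generations before present, with
symmetric per-haplotype per-generation migration `migration_rate`
$\in \{0, 0.001, 0.01, 0.025, 0.05, 0.1\}$ across the study grid.  Cases
always come from deme A; the fraction of controls from deme B (0–100%) sets
the stratification severity.

The simulator (`simulate_two_pop()`, C++ core) works backward in time in
two phases:

* **Recent phase (0–80 generations).**  The sample *is* the population
  (all 20,000 haplotypes), so the classical coalescent approximation
  ($n \ll N$) does not apply.  We therefore run a discrete-time
  Wright–Fisher model backwards: each lineage migrates with probability
  $m$, then picks a uniformly random parent haplotype in its deme;
  lineages picking the same parent merge (simultaneous and multiple
  mergers are allowed, as they must be at this sampling depth).
* **Ancestral phase (older than the split).**  The few hundred surviving
  lineages coalesce under a standard Hudson coalescent in an ancestral
  population of `ancestral_haplotypes` (piecewise constant, with one
  optional step `expansion`).

Mutations follow the infinite-sites model at `mutation_rate` $1.5\times
10^{-8}$ per bp per generation with positions uniform on
`[1, region_length_bp]`.  Within-gene recombination is not modelled (genes
are unlinked, i.e. recombination between replicates is free); for
gene-scale regions and the time depths involved its effect on the
quantities studied here is negligible, and the configuration rejects a
non-zero `recombination_rate` rather than silently ignoring it.

Two defaults are calibrations rather than free dials, chosen once:

* `ancestral_haplotypes = 33334` makes nucleotide diversity
  $2 N_{hap} \mu \approx 10^{-3}$ per bp, the value typical of human
  European samples.  Ancestral diversity controls the denominator of
  $F_{ST}$ (mean coalescence time), so this is the single most important
  constant for placing the migration grid on a realistic differentiation
  scale.
* `region_length_bp = 10750`, set by pilot simulation so that a
  2,000-individual case/control sample carries a mean of about 31 analyzed
  rare variants per gene, matching the variant density of the study design
  the package emulates.

With these defaults the package's own measurements (the acceptance suite)
give a multi-locus Weir–Cockerham $F_{ST}$ of roughly $2\times10^{-3}$
at migration 0.01 and $7\times10^{-3}$ at migration 0 — the regime of
neighbouring and of distant European countries respectively —
monotonically decreasing in the migration rate.  A matched configuration
of an independent coalescent simulator (msprime, run during development
with identical downstream processing) reproduces these values, so they
reflect the model, not the implementation.  The residual factor of ~1.6
versus the more detailed multi-bottleneck worldwide demography that the
grid was originally tuned against is the documented cost of the
single-lineage simplification.

## Case/control sampling

Rare variants are classified on the *full deme-A panel* (MAF $\le$
`rare_threshold`, default 1%), not on the sampled subset; sites absent
from deme A are excluded, and columns that end up monomorphic in a drawn
sample are retained but contribute nothing to any statistic (so matrix
dimensions never change across permutations).

* **H0**: individuals (fixed haplotype pairs) are sampled without
  replacement and labelled case/control by quota, independent of genotype;
  the deme-B control quota is exact.
* **H1**: disease status follows
  $\mathrm{logit}\,P(Y=1\mid x) = \alpha_0 + \beta'x$ on the rare-variant
  minor-allele counts, with 50% of rare variants deleterious at
  OR = 1.5 ($\beta = \ln 1.5$, deleterious set drawn uniformly,
  round-half-up on the count) and $\alpha_0 = \mathrm{logit}(0.1)$.
  Because a fixed pool of 5,000 deme-A individuals cannot produce 1,000
  cases at 10% baseline prevalence, H1 candidates are formed by drawing
  fresh random haplotype pairs from the deme-A panel until the case and
  control quotas fill; deme-B controls are drawn irrespective of genotype.
  The baseline prevalence only changes sampling efficiency, not the
  estimands.

## The association statistics

All nine strategies operate on the $N \times P$ matrix of rare-variant
minor-allele counts.  Burden tests reduce each individual to a score
$S_i$ — the carrier indicator (CAST), the allele-count sum (Sum), weighted
sums (wSum variants), or the adaptively signed sum (aSum, marginal
classification at level 0.10) — and test $\beta = 0$ with the score
statistic $U = S'(Y-\hat\mu)$, $V = (Y-\hat\mu)'(Y-\hat\mu)\,
(S-\bar S)'(S-\bar S)/(N-1)$, $Q = U^2/V \sim \chi^2_1$.  With covariates
in the null model the efficient score variance
$S'DS - S'DZ(Z'DZ)^{-1}Z'DS$, $D = \mathrm{diag}(\hat\mu(1-\hat\mu))$,
replaces the $N-1$ form.

Weighting systems: unit weights; $\mathrm{Beta}(\widehat{MAF}_j; 1, 25)$
density on the total-sample MAF; $1/\sqrt{N\,\widehat{MAF}_j
(1-\widehat{MAF}_j)}$ on the total-sample MAF; and the same inverse-sd
form on the control-only estimator $(\sum_{controls} X_{ij}+1)/(2N_0+2)$,
whose pseudo-count keeps weights finite.  Total-MAF inverse-sd weights
zero out columns monomorphic in the sample (they carry no score
information).

The variance-component family uses
$Q_\rho = (Y-\hat\mu)' XWR_\rho WX'(Y-\hat\mu)$ with
$R_\rho = (1-\rho)I + \rho\mathbf{1}\mathbf{1}'$: SKAT is $\rho = 0$,
SKAT-O optimises over $\rho \in \{0, 0.1, \ldots, 1\}$.  PODKAT replaces
the identity with the triangular position kernel
$A_{jj'} = \max(1 - d_{jj'}/w, 0)$ (radius $w$ = 1,000 bp).  KBAC
compares multi-site genotype class frequencies with hypergeometric
upper-tail weights $w_l = P(H \ge n_l^1)$, summing over all classes
including the wild type (a switch excludes it for cross-checks against
the original formulation).  DoEstRare integrates
$|\hat p^1 \hat f^1 - \hat p^0 \hat f^0|$ over the gene, where
$\hat f^g$ are Gaussian kernel density estimates of the rare-allele
positions and $\hat p^g$ binomial-weighted mean allele frequencies.

## Significance

Analytic routes: the 1-df chi-square for burden score tests; for the
quadratic forms, the mixture $\sum_k \lambda_k \chi^2_{1,k}$ with
$\lambda_k$ the eigenvalues of the covariate-projected kernel, evaluated
by numerical inversion of the characteristic function (Imhof's formula,
absolute tolerance $10^{-9}$ via adaptive quadrature) with a
kurtosis-matched noncentral-chi-square fallback when inversion fails.
SKAT-O follows the optimal-test construction: per-$\rho$ p-values and
their quantiles on the moment-matched scale (self-consistent within the
grid search), a one-dimensional integral over the shared burden-direction
component, and the final p capped by the Bonferroni bound
$\min_\rho p_\rho \times 11$; the degenerate single-variant case returns
the plain SKAT p-value.

Permutation route: adaptive permutation with $\hat p = (b+1)/(m+1)$,
significance threshold $\alpha = 0.01$ and precision $c = 0.2$.  The
stopping rule — an interpretation, since the cited procedure's precision
semantics are not printed — stops when the Monte-Carlo coefficient of
variation of $\hat p$ falls below $c$, or when the one-sided 99% lower
bound on $\hat p$ exceeds $\alpha$, with a default budget of
$10/\alpha = 1000$ permutations.

Defaults per method: analytic wherever the statistic's null is valid
without resampling (CAST, Sum, total-MAF weighted Sums, SKAT, SKAT-O,
PODKAT); permutation for aSum and control-MAF-weighted Sum — their
phenotype-dependent sign/weight selection makes the chi-square reference
anti-conservative, and each permutation replay recomputes the selection —
and for KBAC and DoEstRare, which have no analytic null.  The
analytic-vs-permutation oracle tests compare the two routes on small
instances using the permutation *mid-p* (atoms of the discrete null split
in half), the natural comparison point for a continuous approximation.

DoEstRare numerical policy: trapezoidal integration on a 1,024-point
uniform grid; Gaussian bandwidth by Silverman's rule on the *pooled*
allele-position sample, shared by the two groups and held fixed across
permutations (comparable densities, and the per-variant kernel columns can
be precomputed once per gene, which is what makes the permutation route
affordable); degenerate position samples (fewer than two alleles or zero
spread) fall back to 1% of the gene length.

## Stratification corrections

*PCA model correction* puts the leading `n_pcs` (default 2; 5 and 10 as
options) principal components into the null model; applicable to the
regression-representable tests only (burden, SKAT family, PODKAT).
*PCA permutation correction* fits the covariate-only null once per gene,
takes $\theta_i = \exp(\alpha_0 + \alpha'Z_i)$ — the fitted odds; the
printed form "exp of the fitted probability" is available behind a flag
but read as a typo — and draws permuted labels from the multivariate
Fisher noncentral hypergeometric distribution with weights $\theta_i$, so
permuted data retain the stratification.  Sampling is exact
conditional-Bernoulli rejection; the MLE intercept centres the Bernoulli
sum at $N_1$, so acceptance is fast.  This correction applies to every
method, including KBAC and DoEstRare.  At 100% controls from deme B both
corrections are disabled: the components can explain the phenotype
completely and the null fit separates (an explicit error).

PCs come from a fixed per-scenario *structure reference*: `n_genes`
(default 150) independent genes, reduced to common variants (deme-A MAF
$\ge$ 5%) LD-pruned at $r^2 < 0.2$ in deme A (window 50 variants, step 5,
higher-MAF variant kept on conflict), on which each replicate's sampled
individuals are genotyped and decomposed.  PCA standardises columns to
binomial scale and extracts the top components by deterministic orthogonal
iteration (exact SVD below 400 dimensions); component signs follow the
largest-loading-positive convention.  Correction completeness scales with
the number of reference variants: with ~800 pruned variants PC1 separates
the demes at migration 0.001 by ~3.6 within-group standard deviations,
enough to remove most but not all inflation, whereas a genome-scale panel
(hundreds of thousands of variants, as in a full-size study) separates
them essentially perfectly.  The desk-scale default therefore
demonstrates the direction and bulk of the correction, not its asymptote.

## The experiment harness

`run_scenario()` simulates one gene per replicate, draws the scenario's
case/control sample, runs every requested method, and streams one row per
(replicate, method); per-replicate seeds derive deterministically from the
master seed, so paired comparisons (corrected vs uncorrected on the same
genes) use the same master seed.  Replicate failures are counted and
excluded, never silent.  `rejection_rate()` reports the empirical rate at
$\alpha = 0.05$ with an exact binomial CI around the rate and the
alpha-centred normal band $\alpha \pm 1.96\sqrt{\alpha(1-\alpha)/n}$ — the
acceptance band for a nominal test.  Desk-scale replicate counts
(hundreds to 2,000, versus 10,000/1,000 in a full-size run) are the
package defaults; all counts are configurable, and confidence bands scale
as $1/\sqrt{n}$.

## What the simulations do and do not show

The generator reproduces the features that drive the studied phenomenon:
realistic diversity, a rare-variant-heavy site frequency spectrum
(roughly 55% of deme-A variants at MAF $\le$ 1%), and differentiation
spanning the country-to-neighbouring-region range.  It does not model
within-gene recombination, population growth differences between the
demes, sequencing error, missingness, or covariates other than ancestry —
so nominal type-I error here certifies the statistics and corrections
under the stated model, not robustness to those real-data complications.
Per-gene significance is evaluated at $\alpha = 0.05$; behaviour at
exome-wide thresholds is out of scope.
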