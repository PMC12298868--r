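---
title: "Methods: core germplasm construction and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core germplasm construction and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germcore)
```

# Scope

`germcore` implements the complete analysis chain used to distil a large
crop germplasm panel into a compact core collection: phenotypic diversity
statistics, cluster-based stepwise core sampling over a strategy grid with
MD/VD/CR/VR evaluation, SNP diversity and population-structure summaries,
genotypic core selection by entry-to-nearest-entry (E-NE) distance
maximization, integration of the two selections, and membership-function
scoring of germination-stage salt–alkali tolerance. Because panels of this
kind are rarely deposited publicly, the package ships first-class
synthetic-data generators that emulate the statistical structure such a
panel exhibits, so the whole chain is testable end to end.

# Phenotypic diversity

`summarize_traits()` reports, per trait, the sample moments plus two
field-standard indices:

* **Coefficient of variation** CV% $= 100\,s/\bar{x}$ with the sample SD
  ($n-1$ denominator). A trait with mean zero has an undefined CV and is
  flagged rather than silently reported as 0. One SD convention (sample,
  $n-1$) is used everywhere in the package, including z-scores.
* **Shannon–Weaver diversity index** $H' = -\sum_i p_i \ln p_i$ over ten
  frequency classes: class 1 below $\bar{x} - 2s$, classes 2–9 in
  half-SD steps, class 10 at or above $\bar{x} + 2s$. This ten-class
  scheme is the convention of the germplasm-diversity literature, but
  sources rarely print their exact binning; the break points are therefore
  configurable, and we treat published GDI columns as indicative rather
  than as reproduction targets.

Kurtosis is reported as *excess* kurtosis (normal = 0), matching how
published trait tables in this literature report near-zero values for
approximately normal traits.

Trait PCA is an eigendecomposition of the correlation matrix (covariance
optional); contributions are $100\,\lambda_i/\sum\lambda$, and missing
trait values are mean-imputed for PCA and distances only — raw summaries
always use the available data.

# Clustering engine

All agglomerative methods run through one Lance–Williams recurrence

$$d(k, i \cup j) = \alpha_i d(k,i) + \alpha_j d(k,j) + \beta d(i,j) +
\gamma\,|d(k,i) - d(k,j)|$$

with the classical parameter table for eight linkages: single, complete,
median, centroid, group average (UPGMA), weighted average (WPGMA),
flexible ($\beta = -0.25$ by default), and Ward. The traditional Chinese
germplasm-software method names map onto these as: shortest distance →
single, longest distance → complete, intermediate distance → median,
class averaging → group average, variable class averaging → weighted
average, sum-of-squares of deviations → Ward. This mapping is a documented
choice: the software in question publishes names, not formulas.

Numerical conventions:

* Ward, centroid and median run on **squared** distances — the scale on
  which their Lance–Williams parameters are geometrically exact — and
  reported heights are square roots, matching the `ward.D2` and
  squared-input conventions of `stats::hclust`. The test suite
  cross-checks all shared methods against `hclust` and all eight against
  a naive recompute-from-scratch oracle.
* Nearest-pair ties break on the smallest (i, j) index pair, rows first,
  so merges are deterministic.
* `cut_tree(tree, k)` undoes the last $k-1$ merges rather than cutting at
  a height, so non-monotone trees (centroid/median can invert) still cut
  deterministically. Inversions are left as-is, not corrected.

Mahalanobis distances use the sample covariance; a singular covariance
falls back to the Moore–Penrose pseudo-inverse, and an optional ridge
$\lambda$ gives $(S + \lambda I)^{-1}$. Neighbor-joining trees use the
Saitou–Nei algorithm (via `ape::nj`) with negative branch lengths clamped
to zero.

# Stepwise phenotypic core sampling

A strategy is the tuple (distance, ratio, allocation, linkage). The
stepwise procedure is realized as: z-standardize, build the distance
matrix, agglomerate, cut into $k = \mathrm{round}(\text{ratio}\cdot n)$
clusters (round half away from zero), and take one representative per
cluster — either a seeded uniform draw (*random* allocation) or the member
with the largest sum of squared deviations from its cluster centroid in
standardized trait space (*deviation* allocation, ties to the first id in
panel order). Deviation allocation deliberately retains the most extreme
member, which is why core CVs typically exceed the source population's
(VR > 100%). The commercial tools used in this literature do not publish
their internal stepwise algorithm; cut-at-k with one representative per
cluster is our documented realization — it uses all four strategy factors
and yields exact core sizes. `strategy_grid()` enumerates the factorial in
a fixed order and reuses merge trees across ratios and allocations; the
grid composition (e.g. 2 × 2 × 2 × 2 = 16 or 2 × 2 × 2 × 3 = 24
strategies) is entirely caller-supplied, since published strategy counts
do not always state their factorization.

## Evaluation

With $m$ traits, MD% and VD% are the percentages of traits whose core
vs. population means (Welch t) or variances (two-sided F) differ at
$\alpha$; CR% and VR% are 100 times the mean range and CV ratios. The
core is compared against the *full* population as if independent — the
convention of the MD/VD literature — and no multiple-testing correction
is applied, because the statistic is defined on raw per-trait tests. A
core passes when MD < 20% and CR > 80% (configurable). Strategies are
ranked: pass first, then ascending MD, then descending CR, VR, VD; the
ordering is a total, deterministic one. Traits with zero range or zero CV
in the full population are excluded from CR/VR with a warning.

# SNP diversity and structure

Genotypes are biallelic calls coded 0/1/2 with missing allowed, read from
GT-only VCF (via `vcfR`; phased and unphased identical, multi-allelic
records dropped with a count) or from a HapMap-like TSV. Filtering keeps
loci with MAF strictly above 0.01 and missingness strictly below 0.01
(both thresholds configurable); MAF uses allele counts, so a heterozygote
counts once. Per locus, $H_e = 1 - p^2 - q^2$, $H_o$ = heterozygote
fraction of called genotypes, and Shannon's information index
$I = -(p\ln p + q\ln q) \le \ln 2$ (per-locus allele-frequency form, as in
GenAlEx); panel values are unweighted locus means. Published tables
sometimes print "corrected" Shannon indices without defining the
correction; we do not implement an undefined correction.

The genetic similarity coefficient is identity-by-state allele sharing:
$1 - |g_a - g_b|/2$ averaged over co-called loci, so identical genotypes
score 1, half-shared score 0.5 and opposite homozygotes score 0.

Evanno's $\Delta K$ post-processes a replicate log-likelihood table
$L(K)$: $\Delta K = |L''(K)| / \mathrm{sd}(L(K))$, defined for interior
$K$ only and requiring at least three replicates (the SD). The package
does not run STRUCTURE itself; `simulate_structure_likelihoods()`
produces the piecewise-linear-plus-noise tables that the method assumes,
with the slope change at the true $K$.

# Genotypic core and integration

The genotypic core maximizes the mean E-NE distance (each selected entry's
distance to its nearest other entry) over modified Rogers distances
$d(a,b) = \sqrt{\tfrac{1}{L'}\sum_l (x_{al} - x_{bl})^2}$, $x = g/2$,
computed over co-called loci; opposite homozygotes at every locus give the
maximum $d = 1$. The optimizer is a deterministic greedy build from the
most distant pair followed by steepest-ascent single swaps (default budget
1000). This single-objective E-NE maximizer is the documented surrogate
for the multi-objective engine of dedicated core-selection software, whose
default objective it mirrors; "diversity captured" is operationalized as
allele coverage — the percentage of (locus, allele) pairs observed in the
panel that the core retains. Integration is a set union: phenotypic-only
selections are added to the genotypic core, and everything unselected
forms the reserve set.

# Salt–alkali tolerance scoring

Each germination indicator is rescaled by the min–max membership function
($U = (x - \min)/(\max - \min)$, reversed for lower-is-better
indicators — the standard form in the crop stress-tolerance literature).
The comprehensive value is $D_i = \sum_j w_j U_{ij}$ with weights either
equal or PCA contribution rates (squared eigenvector entries weighted by
eigenvalue share, normalized); PCA weighting is the default reading of
"weighted membership function" in this literature. Accessions are
clustered on the 1-D $D$ values by Ward into five groups labelled I–V by
descending group mean $D$; groups I–III form the tolerant set. Clustering
on $D$ rather than the full $U$ matrix keeps group boundaries
interpretable as $D$ ranges; a $U$-matrix clustering can be run through
`agglomerate()` directly if preferred.

# Synthetic data: what it does and does not emulate

* **Phenotypes** — a Gaussian copula with user-supplied correlation and
  exact affine rescaling of every column to the target mean/SD. Exact
  scaling (rather than matching in expectation) makes CV checks against a
  configured trait table deterministic. Marginals are normal: published
  trait tables report skewness, which we deliberately do not inject,
  because every downstream statistic used here depends only on moments
  and correlations. Consequently GDI values of simulated traits are
  near-identical across traits and should not be compared to published
  GDI columns. The reference trait table shipped in
  `inst/extdata/maize_trait_reference.csv` carries the means/SDs of a
  588-accession maize panel; its correlation matrix is unknown, so the
  default is identity and a correlation must be supplied to emulate one.
* **Genotypes** — the Balding–Nichols model with a single $F_{ST}$ for
  all $K$ subpopulations, inbred (homozygous) draws with a small residual
  heterozygosity, uniform missingness, and chromosome assignments with
  sorted uniform positions. Defaults are calibrated to the emulated
  panel: 588 accessions, 7439 loci over 10 chromosomes, $K = 6$,
  ancestral MAF in (0.13, 0.5) giving panel $H_e \approx 0.40$, residual
  heterozygosity 0.03 giving $H_o \approx 0.03$, missingness 0.005. There
  is no linkage disequilibrium, pedigree or genotype-by-environment
  structure.
* **Germination indicators** — five latent tolerance groups with
  largest-remainder-rounded counts (exact proportions give exact counts),
  group-mean indicator profiles and Gaussian noise. The default
  proportions are those of an observed 172-accession core
  (4/14/47/64/43).
* **Likelihood tables** — piecewise-linear mean $L(K)$ with replicate
  noise; real STRUCTURE output is noisier and can drift with $K$, so
  $\Delta K$ success rates on synthetic tables are an upper bound.

Passing tests on these generators demonstrates the *algorithms* are
correct and the pipeline's arithmetic identities hold; they do not
demonstrate that any particular real panel would yield the same rankings
or group sizes.

# Problem sizes and seeds

The test suite and acceptance script run at reduced, representative
sizes chosen to exercise every code path: oracle comparisons on 15-point
instances (50 replicates, all 8 linkages), 6-leaf additive trees (100
replicates), a $300 \times 2000$ structured panel for PCA recovery, a
$200 \times 2000$ panel for E-NE coverage, and the full 588-accession
scale for the trait-table checks and the analysis scripts. Every source
of randomness sits behind an explicit integer seed; fixed seeds reproduce
bit-identical outputs, which the pipeline tests assert file-by-file.

# Known limitations

* The stepwise sampling procedure is a documented reconstruction, not a
  reverse-engineered copy of any proprietary tool.
* MD/VD treat overlapping samples as independent (literature convention);
  p-values are therefore conservative for large ratios.
* Centroid/median linkages can produce height inversions; they are
  reported unmodified.
* The E-NE optimizer is a local search: it dominates random search in
  tests but is not guaranteed globally optimal.
* Shannon's $I$ is capped at $\ln 2$ per biallelic locus by construction;
  published panel values above that imply a different (undocumented)
  estimator and are not comparable.
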