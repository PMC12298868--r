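# germcore

Construction and evaluation of **core germplasm collections** — compact,
minimally redundant subsets of a crop germplasm bank that preserve the full
panel's genetic diversity. The package implements the complete analysis
chain used for large inbred panels (the motivating case is a 588-accession
maize panel scored for 19 quantitative traits and genotyped at
Maize6H-60K scale):

1. **Phenotypic diversity** — descriptive statistics, coefficient of
   variation (CV% = 100·s/x̄), ten-class Shannon–Weaver diversity index
   (H′ = −Σ pᵢ ln pᵢ), trait correlations, PCA.
2. **Stepwise phenotypic core sampling** — a generalized Lance–Williams
   agglomeration engine covering eight classical linkages (single,
   complete, median, centroid, group average, weighted average, flexible,
   Ward), driven over a strategy grid of distance (Euclidean /
   Mahalanobis) × sampling ratio × allocation (random / deviation) ×
   linkage; the dendrogram is cut into k = round(ratio·n) clusters and one
   representative is kept per cluster.
3. **Core evaluation** — MD% / VD% (share of traits with significant
   mean / variance differences by Welch t and F tests), CR% (mean range
   ratio) and VR% (mean CV ratio), with the pass rule MD < 20% and
   CR > 80%, plus deterministic strategy ranking and PCA comparison.
4. **SNP diversity and structure** — VCF / HapMap-like I/O, strict
   MAF > 0.01 and missingness < 0.01 filtering, per-locus and panel
   Hₑ = 1 − p² − q², H₀, Shannon information index I, identity-by-state
   genetic similarity coefficients (GSC), SNP density, genotype PCA, and
   Evanno ΔK post-processing of STRUCTURE-style replicate likelihood
   tables.
5. **Genotypic core selection** — entry-to-nearest-entry (E-NE) distance
   maximization on modified Rogers distances (greedy build plus
   steepest-ascent swaps), with allele-coverage reporting.
6. **Integration and stress scoring** — union of phenotypic and genotypic
   selections with a reserve set, then membership-function scoring
   (U = (x − min)/(max − min)) of germination-stage salt–alkali
   indicators, PCA-weighted comprehensive values D = Σ wⱼUᵢⱼ, and
   five-group Ward classification (groups I–V by descending mean D;
   I–III = tolerant).

Because panels of this kind are typically not deposited, the package also
ships calibrated synthetic-data generators (Gaussian-copula phenotypes,
Balding–Nichols structured genotypes, latent-group germination
indicators, replicate likelihood tables) so the entire pipeline runs and
is tested end to end without external data.

## Worked example

```r
library(germcore)

# a 120-accession panel calibrated to the shipped 19-trait reference table
tm <- simulate_phenotypes(pheno_sim_config(n_accessions = 120, seed = 42))
head(summarize_traits(tm)[, c("trait", "mean", "sd", "cv_percent")], 4)
#>                  trait   mean     sd cv_percent
#> 1        growth_period 148.47  6.571    4.42581
#> 2 tassel_branch_number   7.78  4.314   55.44987
#> 3         plant_height 203.36 28.659   14.09274
#> 4  ear_position_height  76.22 19.758   25.92233

core <- sample_core(tm, sampling_strategy(distance = "mahalanobis",
                                          ratio = 0.2,
                                          allocation = "deviation",
                                          linkage = "flexible"))
print(core)
#> core_set [mahalanobis+20%+deviation+flexible]: 24 selected, 96 reserve
evaluate_core(subset_accessions(tm, core$selected), tm)
#> core evaluation: MD 0.00%, VD 5.26%, CR 85.82%, VR 112.34% [pass]

g  <- simulate_genotypes(geno_sim_config(n_accessions = 120, n_loci = 1000,
                                         chrom_sizes = rep(100, 10), seed = 43))
gf <- filter_loci(g)                      # MAF > 0.01, missingness < 0.01
round(diversity_stats(gf)$panel, 4)
#>           he           ho    shannon_i          maf missing_rate       n_loci
#>       0.4041       0.0296       0.5898       0.3119       0.0032     891.0000

gc <- select_geno_core(gf, ratio = 0.15)  # E-NE maximization
print(gc)
#> genotypic core: 18 accessions (ratio 0.15), E-NE 0.6170, coverage 99.61%
integrate_cores(core$selected, gc$selected, rownames(tm$values))
#> integrated core: 38 accessions (31.67% of 120); pheno 24, geno 18, overlap 4, reserve 82
```

Reading the output: the 20% deviation-sampled core leaves every trait mean
statistically indistinguishable from the population (MD 0%), keeps ~86% of
every trait's range (CR) and *inflates* the coefficients of variation
(VR 112%) — the signature of deviation sampling, which retains each
cluster's most extreme member. The filtered SNP panel shows the low
observed heterozygosity (H₀ ≈ 0.03) expected of inbred lines against
Hₑ ≈ 0.40, and an 18-accession E-NE core still carries 99.6% of all
observed alleles.

## Analysis workflow

The `analysis/` directory contains the numbered drivers that reproduce the
full study flow at panel scale on the synthetic data
(`Rscript analysis/01_simulate_panel.R`, then `02`…`07` in order):
simulate panel → trait diversity → strategy grid and ranking → SNP
diversity, GSC, ΔK → genotypic cores across ratios → integration → salt–
alkali tolerance classification. Each script prints its findings and
writes its tables under `results/`.

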