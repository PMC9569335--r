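# epienrich

Tools for testing whether GWAS risk variants for a disorder concentrate at
epigenetically active regulatory elements — active promoters and enhancers
— in particular tissues or immune cell states.

Most risk variants for complex (e.g. psychiatric) disorders are
non-coding, so a central interpretive question is *which cell types'
regulatory DNA* they perturb. `epienrich` implements the two standard,
complementary answers as reusable, tested R components:

* **Stratified LD-score regression** (`fitSldsc()`): genome-wide
  partitioning of SNP heritability. For variant *j* with chi-square
  statistic χ²ⱼ, sample size *N* and binary annotations *C*,

  E[χ²ⱼ] = 1 + N Σ_C τ_C ℓ(j, C),  ℓ(j, C) = Σ_{k∈C, |pos_k−pos_j|≤w} r²(j, k),

  estimated by (optionally variance-weighted) least squares with
  delete-one-block jackknife standard errors, one-sided p-values for
  τ_C > 0, conditional models (`fitConditional()`) to control for shared
  regulatory architecture between tissues, a coefficient-difference
  Z-test, and heritability Z-scores (`heritabilitySummary()`).

* **A specificity-rank enrichment statistic** (`cheersTest()`): locus-level
  enrichment in the CHEERS style. Peaks are scored for specificity to
  each cell state (quantile normalization → bottom-decile removal →
  Euclidean row scaling → within-state ranks normalized to (0,1]);
  genome-wide-significant leads are LD-expanded (r² > 0.8) and overlapped
  with peaks; the mean normalized rank x̄ of the n unique overlapped peaks
  is tested against a discrete-uniform null with mean (N+1)/2N and SE
  √((N²−1)/(12N²n)), with exact and Monte-Carlo null modes for small
  overlaps and a stimulated-vs-unstimulated contrast
  (`stimulationContrast()`).

Around these sit binary annotation building from chromatin-state
segmentations (`mergeActiveStates()`, `classAnnotations()`), partitioned
LD scores (`partitionedLdScores()`), distance-based clumping to
independent risk loci (`clumpVariants()`), cross-disorder sharing and
discordance summaries, exact small-sample Spearman correlation
(`spearmanExact()`, `spearmanFromS()`), hypergeometric over-representation
analysis with peak-to-gene assignment (`peaksToGenes()`, `oraTest()`), a
synthetic-data module that generates every input with planted truth, and a
one-call pipeline (`runPipeline()`) driven by a YAML config
(a thin CLI wrapper lives at `inst/scripts/epienrich.R`).

## Worked example

Simulate a panel with block LD, plant a per-SNP heritability coefficient
τ = 1e-5 in the "active" annotation of a synthetic chromatin-state
segmentation, and recover it:

```r
library(epienrich)
cfg <- simulationConfig(seed = 42, nIndividuals = 500, nVariants = 5000,
                        blockSize = 25, gwasN = 50000,
                        plantedTau = c(active = 1e-5))
panel <- simulateGenotypePanel(cfg)
active <- mergeActiveStates(simulateSegmentation(cfg))
lds    <- partitionedLdScores(panel, list(active = active), windowBp = 1e5)
stats  <- simulateSummaryStats(panel, list(active = active), cfg,
                               mode = "analytic", ldscores = lds)
fitSldsc(stats, lds, modelAnnotations = "active", nBlocks = 100)
#> RegressionResult (WLS): 5000 variants, 100 jackknife blocks
#>   intercept 1.011 (SE 0.0322)
#>  annotation       tau        se     z         p p_adjusted
#>      active 1.042e-05 6.764e-07 15.41 7.078e-54  7.078e-54
```

The planted coefficient (1e-5) is recovered within one standard error,
and the free intercept sits at 1 as the model predicts for confound-free
data. Plant cell-state-specific risk variants and recover the state with
the specificity-rank statistic:

```r
cfgP <- simulationConfig(seed = 42, nVariants = 5000, nPeaks = 1000,
                         nCellStates = 4, plantedEnrichmentPi = 0.8,
                         nLeads = 30)
psm   <- simulatePeakMatrix(cfgP)
leads <- plantRiskVariants(psm, "state2", cfgP)
cheersTest(psm, overlapVariants(psm, leads))
#> CheersResult (normal null): 900 peaks in universe, 25 variant-peak overlaps
#>   state n_peaks mean_rank      z        p p_bonferroni
#>  state1      20   0.10006 -6.205 1.00e+00    1.000e+00
#>  state2      20   0.97511  7.352 9.81e-14    3.924e-13
#>  state3      20   0.08044 -6.508 1.00e+00    1.000e+00
#>  state4      20   0.08922 -6.372 1.00e+00    1.000e+00
```

The 20 unique overlapped peaks have mean normalized state2 rank 0.975
against a null mean of ~0.5 — the planted state is called at
Bonferroni-adjusted p ≈ 4e-13, while the other states sit at p = 1.
Published Spearman correlations reported only as an S statistic can be
reconstructed exactly:

```r
spearmanFromS(16, 9)   # rho = 0.867, exact two-sided p = 0.0045
```

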