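---
title: "Models and methods behind epienrich"
author: "epienrich authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epienrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epienrich)
```

# The scientific question

Genome-wide association studies (GWAS) of complex disorders yield thousands
of risk variants, most of them non-coding. A standard way to interpret them
is to ask *in which cell types* those variants fall into epigenetically
active regulatory DNA — active promoters and enhancers marked by histone
modifications such as H3K27ac. `epienrich` implements two complementary
statistical engines for this question, together with the surrounding
plumbing (annotation building, LD computation, locus clumping,
cross-disorder comparison and pathway over-representation) and a
synthetic-data module that generates inputs with known truth so the whole
pipeline can be validated end to end.

# Stratified LD-score regression

## Model

For variant $j$ with GWAS chi-square statistic $\chi^2_j$, sample size $N$,
and binary annotations $C$ with per-variant membership $a_{jC}$, the
expected association statistic under a polygenic additive model is

$$ E[\chi^2_j] = 1 + N \sum_C \tau_C\, \ell(j, C), \qquad
   \ell(j,C) = \sum_{k \in C,\ |pos_k - pos_j| \le w} r^2(j,k), $$

where $\ell(j,C)$ is the LD score of $j$ with respect to $C$ and $\tau_C$
is the per-SNP contribution of annotation $C$ to SNP heritability. A
variant need not itself be causal to show association: it inherits signal
from everything it tags, which is exactly what the LD score measures.
`fitSldsc()` regresses $\chi^2_j$ on $N\ell(j,C)$ with a free intercept
and reports each $\tau_C$ with a delete-one-block jackknife standard
error, a one-sided $p$ for $\tau_C > 0$, and Benjamini–Hochberg adjusted
$p$ across the model annotations.

## Numerical choices

* **Weights.** The variance of a scaled 1-df chi-square grows with its
  mean, so plain OLS is inefficient. By default one reweighting pass is
  applied: an initial OLS fit yields a crude aggregate coefficient
  $\bar\tau$, weights $1/(2(1 + N\bar\tau\,\ell_{tot}(j))^2)$ are formed,
  and the model is refit once. Weighting affects efficiency only — the
  tests verify that both modes recover planted coefficients.
* **Intercept.** Always free (not constrained to 1); it absorbs
  uncontrolled confounding and the finite-panel noise floor in the LD
  scores.
* **Jackknife.** Contiguous, equal-count variant blocks, 200 by default,
  auto-reduced (with a warning) when fewer than $2\times$ blocks variants
  are available. SEs use the standard delete-one-block formula.
* **Collinearity.** A QR rank check names the offending annotation columns
  instead of silently returning unstable estimates.
* **r².** Plain squared Pearson correlation of allele counts. The
  finite-sample bias adjustment used by the reference software is
  available as a flag (`biasAdjust`), off by default; because the analytic
  simulator and the regression use the *same* estimated LD scores, the
  choice does not affect recovery.
* **Window.** LD scores use a fixed base-pair window (default 1 Mb,
  configurable). The synthetic genome carries no genetic map, so
  map-based windows are out of scope.

`fitConditional()` refits the same model with extra conditioning
annotations, which is how shared regulatory architecture between tissues
(e.g. brain and immune cells) is controlled for: if a target annotation's
apparent signal is only borrowed from a causal annotation it overlaps,
conditioning on the causal annotation attenuates the target coefficient
toward zero. `coefficientDifferenceTest()` compares one annotation's
coefficient between two fits with the two-sample statistic
$Z = (\beta_1-\beta_2)/\sqrt{SE_1^2+SE_2^2}$. `heritabilitySummary()`
aggregates $h^2 = \sum_C \hat\tau_C\,|C|$ with a jackknife SE, giving the
heritability Z-score used as a GWAS power proxy.

# The specificity-rank (CHEERS-style) statistic

Where the regression uses genome-wide signal, the specificity-rank
statistic focuses on genome-wide-significant loci. Peaks are scored for
how *specific* they are to each cell state:

1. quantile-normalize the peak-by-state signal columns;
2. drop the bottom decile of peaks by mean signal (weak peaks carry no
   specificity information);
3. divide each peak's row by its Euclidean norm, so per peak the squared
   scores sum to 1;
4. rank scores within each state and normalize ranks to $(0,1]$.

Each step is a switch in `specificityScores()`, because published
processing chains differ and transparency beats hidden defaults.

Risk loci are expanded to LD neighborhoods ($r^2$ strictly $> 0.8$ against
the lead, within a window) so the statistic is robust to tag-variant
differences between studies; a peak counts once no matter how many
variants hit it. For $n$ unique overlapped peaks out of $N$, the mean
normalized state rank $\bar x$ is tested against the null that overlapped
peaks are $n$ i.i.d. draws from the discrete uniform ranks:
$\mu = (N+1)/2N$, $\sigma_n = \sqrt{(N^2-1)/(12N^2n)}$, one-sided
$p = 1 - \Phi((\bar x - \mu)/\sigma_n)$, Bonferroni-adjusted across the
cell states tested.

**Small-overlap behavior.** The null is discrete, so the default normal
approximation applies a half-rank continuity correction (negligible once
$nN$ is large). Even so, the approximation is only accurate from $n \ge 2$
overlapped peaks upward (max absolute error ~0.016 at $n = 2$, ~0.010 at
$n = 3$); for a single overlapped peak no normal approximation is usable
(max error ~0.06). `cheersTest(method = "exact")` evaluates the exact
convolution null and is recommended whenever only a handful of peaks are
overlapped; a Monte-Carlo mode provides an independent cross-check.
`stimulationContrast()` compares two conditions on the same peak universe
with $Z = (\bar x_1 - \bar x_2)/\sqrt{2\sigma_n^2}$ — valid because peaks
are called on the dataset as a whole, making the SE identical across
conditions.

# Lead-locus identification

`filterMac()` (minor allele count $\ge 10$, derived from frequency when
absent), `filterMafPanel()` (panel MAF strictly $> 0.01$), and
`clumpVariants()` reduce summary statistics to independent leads:
variants with $p < 5\times10^{-8}$ outside the MHC region are greedily
clumped — the smallest-p variant becomes a lead and all significant
variants within $\pm 500$ kb on the same chromosome are discarded.
Because "distance-based clumping" admits conventions, the greedy
ascending-p rule, the strict $>500$ kb separation between retained leads,
and the (chromosome, position) tie-break are explicit, tested decisions;
they make the output independent of input row order. Two MHC constants
are provided (`mhcRegion()`): the GRCh37 extended region chr6:25–34 Mb
for heritability partitioning and the GRCh38 region
chr6:28,510,120–33,480,577 for clumping, matching the builds each stage
conventionally runs on. Disorders with fewer than 3 independent loci are
flagged ineligible for the specificity-rank analysis (`checkMinLoci()`),
since a two-locus enrichment estimate is dominated by single-locus noise.

# Comparisons and pathways

`sharingCounts()` decomposes overlapped peaks into disjoint
disorder-power-set cells (upset-style). `discordantPeaks()` takes peaks
selective for designated states (normalized rank strictly $> 0.9$) and
splits them by which disorder's variants hit them, attaching element
classes and paired per-variant association statistics so apparent
discordance can be distinguished from sub-threshold signal.
`classifyPeakElements()` uses a one-base-pair overlap rule and is
multi-label by default, with an optional priority collapse (promoter >
genic enhancer > enhancer) for single-label summaries.

`spearmanExact()` computes Spearman's $S = \sum d_i^2$ and
$\rho = 1 - 6S/(n(n^2-1))$; for $n \le 10$ without ties the two-sided $p$
is exact from full enumeration of all $n!$ permutations (twice the
smaller tail of $S$, capped at 1 — the convention under which a sample
$\rho$ of 0 yields $p = 1$). Confidence intervals use the percentile
bootstrap (default 10,000 seeded replicates); at $n = 9$ some
undercoverage relative to the nominal 95% is expected and is quantified
in the test suite. `spearmanFromS()` reconstructs $\rho$ and the exact
$p$ from a printed $S$ statistic alone. Ties fall back to the general
rank-correlation formula with a warning.

`peaksToGenes()` assigns a peak to the union of genes whose body overlaps
it and genes whose promoter (TSS $\pm 3$ kb by default — a common
annotation convention; the window is configurable) overlaps it, falling
back to the single nearest TSS within 10 kb (gap distance, as computed by
`GenomicRanges::distanceToNearest()`). `oraTest()` is the upper-tail
hypergeometric test with BH adjustment; the universe defaults to all
genes in the loaded gene model and is recorded in the output, since the
background choice materially affects ORA p-values.

# The synthetic-data generator

The generator produces every input the pipeline consumes, with planted
truth:

* **Genotypes** (`simulateGenotypePanel()`): a latent Gaussian AR-1
  process within fixed-size blocks (independent across blocks),
  thresholded twice per individual at the variant's target MAF, giving
  Hardy–Weinberg allele counts with controllable LD. MAF is drawn
  uniformly per *block* from `[0.05, 0.5]` — variants in strong LD
  necessarily share allele frequency, and per-variant MAFs would
  attenuate within-block $r^2$ far below $\rho_{LD}^2$. The margin above
  the usual 0.01 analysis filter keeps every simulated variant clearly
  polymorphic.
* **Summary statistics** (`simulateSummaryStats()`): *analytic* mode
  draws $\chi^2_j$ directly from the model above (validating the
  regression against its own assumption); *phenotype* mode draws
  per-variant effects with variance $\sum_C \tau_C a_{jC}$, builds a
  phenotype on the panel's individuals with environmental noise scaling
  total variance to 1, and runs marginal regressions (validating against
  the data-generating process). Planted $\tau$ implying $h^2 > 1$ is
  rejected.
* **Peak matrices** (`simulatePeakMatrix()`): log-normal background
  signal over non-overlapping constant-width peaks; per state, a disjoint
  5% of peaks (default) receives an 8-fold boost in that state only.
  Constant width keeps uniformly placed variants exactly uniform over
  peaks, which is what the calibration experiments assume.
* **Risk variants** (`plantRiskVariants()`): with probability $\pi$ a
  lead lands uniformly inside a peak specific to the target state,
  otherwise uniformly on the genome.
* **Segmentations, gene models, gene sets**: IDEAS-style labelled
  segments (active states ~25% of the genome), non-overlapping stranded
  gene bodies, and random GMT sets.

Seeds propagate hierarchically (`stageSeed()`): one master seed plus a
stage label gives every generator stage and Monte-Carlo replicate stream
its own reproducible seed, so identical configurations give bit-identical
outputs.

**What the generator does not emulate:** realistic human LD maps and
recombination hotspots, allele-frequency spectra, imputation artifacts,
sex chromosomes, related individuals, population stratification, or
correlated peak widths and signal. Passing tests therefore demonstrate
that the statistics are implemented correctly and are calibrated under
their stated assumptions — not that those assumptions hold in any given
real dataset.

# Study conditions used in the validation experiments

The replicated experiments (`sldscRecoveryExperiment()`,
`conditioningExperiment()`, `cheersCalibrationExperiment()`,
`cheersRecoveryExperiment()`) use: 20,000 variants at 1 kb spacing
(blocks of 50, $\rho_{LD} = 0.9$), a 1,000-individual panel, GWAS
$N = 50{,}000$, planted $\tau^* = 5\times10^{-6}$, 100 recovery and 200
null replicates; and 5,000 peaks × 6 cell states with 50 lead variants
and $\pi = 0.8$ planted enrichment. The LD-score window is 100 kb there —
ample for 50 kb blocks, and chosen (like the panel size) as a
package-level default for the validation studies; both are arguments.
The bundled demo configuration (`inst/extdata/demo_config.yaml`) is a
deliberately compact study — a 2 Mb genome with 2,000 variants — whose
clumping distance is scaled to 20 kb to match; every other analysis
constant keeps its conventional default ($5\times10^{-8}$, $r^2>0.8$,
MAC ≥ 10, MAF > 0.01, rank > 0.9, 10 kb TSS cap).

# Known limitations

* The normal approximation to the discrete-uniform null is unusable at
  $n = 1$ overlapped peak (error up to ~0.06 even with the continuity
  correction); use `method = "exact"`.
* The jackknife SE assumes independence across blocks; very long-range
  LD (relative to block span) would violate it. Block count is exposed.
* Percentile bootstrap CIs at $n = 9$ undercover slightly; BCa intervals
  are not implemented.
* Cross-dataset peak matching (comparing peak universes called in
  different studies) is out of scope; all comparisons assume one shared
  peak universe.
* Liftover, strand harmonization and imputation are assumed done
  upstream; inputs are taken to be on one build per stage.
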