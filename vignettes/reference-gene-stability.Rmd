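---
title: "Reference-gene stability: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgstab)
```

## The problem

A Ct value is the PCR cycle at which a reaction's fluorescence crosses a
threshold; it is logarithmic in starting template, with one cycle per
doubling at 100 % efficiency. Relative quantification divides a target
gene's signal by that of one or more reference genes (RGs) measured in the
same sample, so that sample-to-sample differences in RNA input, reverse
transcription yield and pipetting cancel. The entire construction stands or
falls with the assumption that the RGs themselves are stably expressed
across the compared conditions. This package implements the standard
tool-chain for testing that assumption: transcriptome-based candidate
screening, four stability algorithms, consensus ranking, the
pairwise-variation rule for how many RGs to use, and target quantification
under competing RG choices.

## Candidate screening from RNA-seq

For each gene in an FPKM compendium we report the mean (MF), standard
deviation (SD, denominator $n-1$) and coefficient of variation
$\mathrm{CV} = 100\,\mathrm{SD}/\mathrm{MF}$ in percent. Candidates must be
adequately expressed (MF ≥ 10) and stable (CV ≤ 20 %), both bounds
inclusive and configurable. The $n-1$ denominator is the spreadsheet
default under which such screens are commonly run; a population-SD option
exists for sensitivity checks. Because annotation credibility cannot be
judged from expression values, `screen_candidates()` accepts an optional
allow-list restricting eligibility.

A two-point reconstruction trick is worth noting: a vector
$(m - s/\sqrt2,\; m + s/\sqrt2)$ has mean exactly $m$ and sample SD exactly
$s$, which lets published (MF, SD) pairs be pushed through the same code
path that processes raw matrices when checking printed CV columns.

## The four stability algorithms

All four consume one Ct value per gene and sample; missing values are
rejected outright because none of the methods defines missing-data
handling. Technical replicates should be collapsed first
(`average_replicates()`), since each method models one value per
biological sample.

**Comparative ΔCt.** For genes $i,k$ the per-sample difference
$\Delta Ct = Ct_i - Ct_k$ has an SD over samples; gene $i$'s stability is
the mean of its $G-1$ pair SDs. Shared per-sample effects cancel exactly
in the difference, so the method measures *relative* instability only.

**BestKeeper.** Descriptive statistics of raw Ct per gene — mean, min,
max, dispersion and CV — plus the Pearson correlation of each gene with
the per-sample geometric-mean Ct index. The published description of this
tool uses the mean absolute deviation; much of the literature reports an
SD. We default to the sample SD (matching the dominant reporting
convention) and expose `deviation = "mad"` for cross-tool comparison.
Because raw Ct is used, a shared loading shift does *not* cancel:
BestKeeper measures absolute variation, and this asymmetry against the
other three methods is asserted on synthetic data where it is exactly
predictable.

**geNorm.** Ct is first transformed to relative quantities
$Q = E^{\,Ct_{\min} - Ct}$ with the per-gene minimum taken *within the
analyzed sample subset*, so each row's maximum is exactly 1 and subset
analyses are self-contained. (A global-minimum variant would only rescale
rows, to which the method is invariant anyway; the per-gene convention is
the one the classic tools use.) For genes $j,k$,
$V_{jk} = \mathrm{SD}\!\left[\log_2 (Q_j/Q_k)\right]$ and
$M_j = \mathrm{mean}_{k\neq j} V_{jk}$. With all efficiencies equal to 2,
$\log_2(Q_j/Q_k)$ reduces to $Ct_k - Ct_j$ plus a constant, so first-round
M values coincide with the ΔCt statistic — a cross-method identity the
test suite asserts to $10^{-10}$ on random matrices. Ranking proceeds by
iteratively removing the highest-M gene until two remain; those two are
inseparable by construction (with two genes $M_A = M_B$) and share rank 1.
Ties at the maximal M remove the lexicographically larger id, and the
final pair is ordered by id — both choices recorded in the exclusion
trace, and both needed to make the ranking invariant to gene input order.

The pairwise variation series uses normalization factors
$NF_n$ = per-sample geometric mean of the top-$n$ genes' quantities, and
$V(n/n{+}1) = \mathrm{SD}\!\left[\log_2 (NF_n/NF_{n+1})\right]$. The
optimal RG count is the smallest $n$ with $V < 0.15$ (strict comparison;
the threshold is exposed). When no $n$ qualifies the count is
`NA` ("undetermined") and `recommend_rgs()` falls back to the full
ranking with a warning rather than inventing a cutoff.

**NormFinder.** A variance-components model on $y = -Ct$ (sign so that
larger = more template; results are sign-invariant). Per sample the gene
mean is subtracted, removing loading effects; per gene and group the
residual variance $s^2_{ig}$ is corrected to an unbiased intra-group
variance
$\hat\sigma^2_{ig} = \max\!\big(0, \tfrac{I}{I-2}\big(s^2_{ig} -
\sum_{i'} s^2_{i'g}/(I(I-1))\big)\big)$ — the correction removes the
contamination introduced by subtracting the per-sample mean and needs
$I \ge 3$ genes. Inter-group differences $d_{ig}$ (which sum to zero over
genes within each group) are shrunken toward zero by an empirical-Bayes
factor $\hat\gamma^2/(\hat\gamma^2 + \hat\sigma^2_{ig}/n_g)$, where
$\hat\gamma^2$ estimates the variance of true group differences. The
stability value is
$\rho_i = \mathrm{mean}_g\big(|\tilde d_{ig}| + \sqrt{\hat\sigma^2_{ig}/n_g}\big)$,
an equal-weight (not $n_g$-weighted) average over groups; with a single
group it reduces to $\sqrt{\hat\sigma^2_i}$. Both variance estimates are
floored at zero: negative variances are meaningless downstream, and the
floor only binds in small samples. Unbiasedness of $\hat\sigma^2$ holds
analytically for equal gene variances and, gene-wise, under unequal
variances too; the benchmark verifies it empirically to within 5 % at
$I = 10$, $n_g = 20$ over 1000 replicates. `normfinder_best_pair()` scores
a pair by $\mathrm{mean}_g\big(|(\tilde d_i + \tilde d_k)/2| +
\sqrt{(\hat\sigma^2_i + \hat\sigma^2_k)/(4 n_g)}\big)$ — the shrunken bias
of the pair average plus the standard error of that average — so genes
with opposite-sign regulation can jointly beat any single gene.

## Consensus and how many genes

The comprehensive ranking is the geometric mean of the four integer ranks
(equal weights). Within-method ties carry the shared minimum rank into the
product. geNorm's tied top pair enters as (1, 1) with the next gene at
rank 3, mirroring the classic tool's output; since the alternative (1, 2)
entry affects only third-decimal geomeans, it is available via
`genorm_pair = "sequential"`. Final ties break lexicographically, making
the whole pipeline deterministic.

## Quantification

Amplification efficiency comes from an OLS standard curve
$Ct = a + b\,\log_{10}(\mathrm{conc})$, with $E = 10^{-1/b}$ and
efficiency $(E-1)\cdot 100\%$; a slope of $-3.32$ is a perfect doubling.
Normalization factors are geometric means of RG quantities; the target's
quantity over NF, rescaled so the calibrator set averages 1, gives the
fold change. The calibrator aggregate is an arithmetic mean of per-sample
ratios by default (a geometric option exists); the classic 2^−ΔΔCt mode
forces all efficiencies to 2, while supplying fitted factors gives the
efficiency-corrected variant. Fold changes are exported per replicate;
significance testing is deliberately out of scope and left to standard
tools.

## The synthetic generator

`simulate_ct_dataset()` draws
$Ct_{igj} = \mathrm{baseline}_i + \mathrm{shift}_{ig} + b_{gj} +
\varepsilon_{igj}$ with $b \sim N(0, \tau^2)$ shared by all genes of a
sample and $\varepsilon \sim N(0, \sigma_i^2)$, all on the Ct (log₂)
scale, consistent with the log-linear PCR model. This emulates exactly the
three ingredients the stability methods disagree about: loading effects
(invisible to ΔCt/geNorm/NormFinder, fully visible to BestKeeper),
condition-dependent regulation (what makes a gene a bad reference), and
assay noise. Presets mirror common validation designs — three growth
stages × 3 replicates, four tissues × 3, control/drought × 3, and their
union — with eight stable genes, one regulated gene (`bTUB_like`, ~2-cycle
drift) and one noisy gene (`EF1A_like`, 1.0-cycle scatter), baselines
spread over 18–28 cycles and $\tau = 0.5$ cycles, values we consider
realistic for plant qPCR panels. Seeds are mandatory and the generator
neither reads nor perturbs the caller's RNG stream; regeneration is
bit-identical.

What the generator does *not* emulate: non-normal noise and outlier
reactions, Ct-dependent heteroscedasticity (late-cycle scatter),
correlated technical replicates, plate/batch effects beyond the shared
loading term, and per-sample efficiency variation. Passing recovery tests
therefore show that the algorithms are implemented correctly and behave as
designed under their own model assumptions — not that any of them is
robust to the full messiness of real runs.

Designed stability truth is scored as
$\sqrt{\sigma_i^2 + \mathrm{Var}_g(\mathrm{shift}_{ig})}$ (population
variance over groups), giving the ordering the recovery benchmark compares
against. In the benchmark scenario prescribed for recovery testing
(10 genes, 3 groups × 6 samples, one gene with centred shifts
(−1.5, 0, +1.5) cycles and noise 0.6 vs 0.2 for the rest), all four
algorithms rank the designed gene last in ≥ 95 % of 200 seeded runs —
in our runs, 100 %.

FPKM compendia are drawn log-normally with
$\mathrm{sdlog}^2 = \log(1 + cv^2)$ and
$\mathrm{meanlog} = \log(m) - \mathrm{sdlog}^2/2$, so the distribution's
true mean and CV equal the targets. A caution established with a
20,000-draw Monte-Carlo oracle: at 42 samples, a gene designed at CV 18 %
passes the 20 % screen only ~85 % of the time — the CV estimator's
scatter is about 2 points there — whereas CV-15 designs pass > 99 % and
CV-60 designs essentially never. Tests of screen recovery use those
oracle-computed rates, and users should not expect near-certain screening
outcomes for genes designed close to a threshold.

## Numerical and interface choices

* All SDs use the $n-1$ denominator unless stated otherwise.
* QC flags: a gene is `high_ct` iff mean Ct ≥ 30 and `low_ct` iff
  mean Ct ≤ 15 (boundaries inclusive on the flagged side); advisory only.
* Zero-variance genes: BestKeeper reports an undefined index correlation
  as `NA` with a warning instead of erroring; all-constant inputs yield
  all-zero stability values and fully tied ranks.
* Efficiencies ≤ 1 are rejected; the default 2.0 corresponds to the
  classic base-2 transform.
* Table round trips are bit-exact: Ct tables are written with 17
  significant digits.
* Replicate averaging is a separate, explicit step rather than a reader
  default, so analyses of replicate-level tables remain possible.
* Group partitions are supplied entirely through sample annotations (a
  group header row or a sample sheet); nothing is inferred from sample
  names.

## Problem sizes

The test suite exercises random matrices up to 8 × 20 (50 draws for the
cross-method identity), 200-run recovery simulations at 10 × 18, and a
1000-replicate variance-recovery study at 10 × 40; the whole suite and the
acceptance script each complete in seconds on a single core. These sizes
give Monte-Carlo standard errors comfortably inside the asserted margins
(binomial SE ≈ 1.5 points at a 95 % rate over 200 runs; ≈ 1 % relative SE
on the variance-recovery ratio).

## Known limitations

Single grouping factor only (no multi-factor designs), no missing-data
handling by design, no BestKeeper SD > 1 exclusion rule, no confidence
intervals on fold changes (replicate-level folds are exported for external
statistics), and no claim that published table values can be reproduced
without the corresponding raw Ct data — the reproduction tests state
exactly which file they need and fail informatively without it.
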