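# rgstab — reference-gene stability analysis for RT-qPCR

RT-qPCR quantifies a target transcript relative to one or more *reference
genes* (RGs, "housekeeping" genes) assumed to be stably expressed. When that
assumption fails — and classic choices such as *β-tubulin* or *EF-1α* often
do fail under specific conditions — every downstream fold change inherits
the reference's own regulation. `rgstab` is an R package plus a small
analysis workflow for choosing and validating reference genes the way this
is done in plant molecular biology: screen candidates from RNA-seq
compendia, score their qPCR stability with the four standard algorithms,
aggregate the verdicts, decide how many RGs are needed, and demonstrate the
consequences of a bad choice on a target gene. It is aimed at wet-lab
groups validating RG panels for a new species or condition, and at
methodologists who want the four algorithms in one tested, scriptable
implementation with a ground-truth simulator.

## What it computes

* **Transcriptome screening** — per gene, mean FPKM (MF), SD, and
  CV = 100·SD/MF; candidates must satisfy MF ≥ 10 and CV ≤ 20 % (inclusive,
  configurable).
* **Comparative ΔCt** — for each gene pair, the SD over samples of
  ΔCt = Ct_i − Ct_k; a gene's stability is its mean pair SD.
* **BestKeeper** — descriptive statistics of raw Ct (mean, min, max,
  SD or MAD, CV) plus Pearson correlation of each gene with the per-sample
  geometric-mean index.
* **geNorm** — relative quantities Q = E^(minCt−Ct); M value = mean SD of
  pairwise log₂ ratios; iterative exclusion ranking; pairwise variation
  V(n/n+1) of consecutive normalization factors, with the conventional
  V < 0.15 rule for the optimal number of RGs.
* **NormFinder** — model-based decomposition into intra-group variances
  σ²(unbiased, floored at 0) and shrunken inter-group differences d̃;
  stability ρ = mean over groups of |d̃| + √(σ²/n); plus best-pair search.
* **Comprehensive ranking** — RefFinder-style geometric mean of the four
  integer ranks.
* **Quantification** — standard-curve efficiency fitting
  (E = 10^(−1/slope)), multi-RG normalization factors, and 2^−ΔΔCt /
  efficiency-corrected fold changes against a calibrator.
* **Synthetic data** — a seeded generator of grouped Ct matrices
  (gene baselines + shared per-sample loading effects + designed
  gene×group shifts + gene noise), log-normal FPKM compendia, and dilution
  series, each with recorded ground truth.

## Worked example

```r
library(rgstab)

sim <- simulate_ct_dataset(synthetic_preset("corm_growth", seed = 42))
sim$ct
#> ct_matrix: 10 genes x 9 samples
#> groups: stage1 (n=3), stage2 (n=3), stage3 (n=3)

res <- genorm_analysis(sim$ct)
res
#> genorm_result: 10 genes; ranking (stable first):
#>   hk07 > hk08 > hk01 > hk05 > hk04 > hk06 > hk02 > hk03 > bTUB_like > EF1A_like
#> pairwise variation: V2/3=0.066, V3/4=0.05, V4/5=0.04, V5/6=0.037, ...
#> optimal number of reference genes: 2

comp <- comprehensive_rank(list(delta_ct_stability(sim$ct),
                                bestkeeper_stats(sim$ct),
                                res$stability,
                                normfinder_stability(sim$ct)))
head(as.data.frame(comp), 2)
#>   gene_id rank_delta_ct rank_bestkeeper rank_genorm rank_normfinder geomean final_rank
#> 1    hk08             1               2           1               3    1.57          1
#> 2    hk07             3               4           1               1    1.86          2

recommend_rgs(comp, res$optimal_n)
#> [1] "hk08" "hk07"
```

The preset plants two bad candidates: `bTUB_like` (systematically regulated
across stages) and `EF1A_like` (noisy assay). Both land at the bottom of
every ranking; the V series says two reference genes suffice (V2/3 = 0.066
< 0.15), and the geometric-mean consensus recommends `hk08` + `hk07`.

The numbered scripts under `analysis/` run the full workflow narrative:
`01` screening (published CV arithmetic + synthetic compendium),
`02` scenario simulation, `03` stability analysis and recommendations,
`04` standard curves and three-strategy target quantification,
`05` recovery benchmark against generator truth. Each writes its tables
under `results/`.

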