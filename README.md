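# consensusMR

Discovery of candidate **master transcriptional regulators** of poorly
differentiated neuroendocrine tumors (NETs) from multi-cohort expression
data, for computational biologists working with NET vs non-NET comparisons
(e.g. neuroendocrine prostate cancer vs castration-resistant
adenocarcinoma, small-cell vs non-small-cell lung cancer).

## What it computes

**Discovery route.** For cohorts *k = 1..D*, each gene is tested NET vs
non-NET with the two-sided Wilcoxon rank-sum test; p-values are
Benjamini–Hochberg adjusted within each cohort and a gene is called up when
FC > 2 and FDR < 0.05, with FC the pseudocounted ratio of linear means. The
cross-cohort intersection of up-calls defines the shared NET program. Over
that program a **consensus co-expression network** is built: for every TF–gene
and TF–TF pair, the per-cohort Pearson r of log2(x+1) expression (NET
samples) is thresholded at r > 0.5 (signed, strict), and the edge weight is
the **correlation count**

&nbsp;&nbsp;&nbsp;&nbsp;w(i,j) = #{ k : r_k(i,j) > 0.5 },&nbsp;&nbsp; 1 ≤ w ≤ D.

Communities are detected by greedy weighted-modularity maximization; TFs in
the largest community are ranked by **weighted degree** (sum of incident
correlation counts), and the top-ranked TF is the candidate master
regulator.

**Co-factor cascade.** Direct targets = upregulated genes with a regulator
binding peak whose midpoint lies within 20 kb (inclusive) of their TSS;
successive intersection with a motif-derived gene list and a protein
interactor list pinpoints candidate co-factors.

**Signature scores.** Per-sample score = Σ over signature genes of
z = (x − μ)/σ with within-cohort μ, σ (e.g. hypoxia score, regulator
activity score), plus score–score Pearson correlation and the tumor-growth
inhibition rate IR = (V_vehicle − V_treated)/V_vehicle.

A synthetic multi-cohort simulator with planted ground truth (shared
upregulated program, TF-driven correlated module, proximal/distal peak
sets, cascade decoys) makes every stage testable end to end.

## Worked example

```r
library(consensusMR)
cfg <- pipelineConfig(simulation = simulationConfig(), seed = 1)
runDiscovery(cfg)
#> DiscoveryReport (seed 1 )
#>   per-cohort up-calls: cohort1=30, cohort2=30, cohort3=29
#>   shared upregulated genes: 29
#>   network: 29 nodes, 27 edges, 13 communities, Q = 0.193
#>   top-ranked TF: TF01 ( weighted degree 33 )
#>   planted master TF TF01 rank: 1 | mean recall 0.989 | mean precision 1.000

runCascade(cfg)
#> CascadeReport (seed 1 )
#>              stage nIn nOut
#>     direct_targets  16   16
#>       motif_filter  16    1
#>  interactor_filter   1    1
#>   survivors: G0001
#>   planted cofactor G0001 recovered exactly: TRUE
```

Reading: of 30 genes planted as upregulated in three simulated cohorts
(20 + 20 samples each, 4-fold effect), 29–30 are called per cohort and 29
survive the intersection. The planted master TF `TF01` — whose 12-gene
module carries pairwise correlation ≈ 0.81 — accumulates weighted degree 33
(11 module partners, each correlated in all 3 cohorts) and ranks first in
the largest community. The cascade narrows 16 direct targets to exactly the
planted co-factor `G0001`.

Real data enter through the same TSV dialect
(`pipelineConfig(cohortFiles = ..., tfs = ...)`, see `?readCohort`), BED
peak files (`readBed()`), GMT signatures (`readGmt()`), and plain-text gene
lists.

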