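---
title: "Consensus co-expression discovery of master regulators: methods and design"
author: "consensusMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus co-expression discovery of master regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusMR)
```

## The scientific problem

Poorly differentiated neuroendocrine tumors (NETs) arising in different
organs — neuroendocrine prostate cancer (NEPC), small-cell lung cancer,
poorly differentiated neuroblastoma — share clinical, genomic and epigenetic
features, which suggests shared master transcriptional regulators. A master
regulator in this sense is a transcription factor (TF) whose expression
co-varies with, and plausibly drives, a program of genes jointly upregulated
in the NET state. This package implements a discovery route for such
regulators from multi-cohort expression data:

1. **Differential expression per cohort.** Each cohort compares a NET arm
   against a non-NET arm gene by gene with the two-sided Wilcoxon rank-sum
   test; p-values are Benjamini–Hochberg adjusted within the cohort, and a
   gene is called upregulated when its fold change exceeds 2 and its FDR is
   below 0.05 (both strict).
2. **Cross-cohort intersection.** Genes called up in *every* cohort form the
   shared NET program.
3. **Consensus co-expression network.** Over the shared program, Pearson
   correlations are computed per cohort between each TF and every other gene
   (TF–TF pairs included; non-TF pairs are never connected, keeping the graph
   anchored on regulators). An edge is kept when r > 0.5 in at least one
   cohort, weighted by the *correlation count* — the number of cohorts
   exceeding the threshold.
4. **Communities and ranking.** Communities are detected by greedy weighted
   modularity maximization; within the largest community, TFs are ranked by
   weighted degree (the sum of incident correlation counts). The top-ranked
   TF is the candidate master regulator.

A second workflow identifies a co-factor downstream of the regulator from
cistrome data: *direct targets* are upregulated genes with a regulator
binding peak within 20 kb of their transcription start site (TSS); these are
filtered by a motif-derived gene list and by a protein-interactor list, and
the survivors of this three-filter cascade are candidate co-factors.

## Statistical components

### Wilcoxon rank-sum p-values

`wilcoxonRankSum()` returns the exact two-sided p-value (twice the smaller
tail of the null rank-sum distribution, capped at 1) whenever the combined
sample size is at most 12 and the pooled values are tie-free; otherwise it
uses the normal approximation with tie correction and continuity correction.
The exact/approximate cutoff at combined n = 12 keeps the exact region small
enough to verify exhaustively against an enumeration oracle (the test suite
sweeps *every* tie-free configuration up to combined n = 10), while cohort
comparisons (typically n ≥ 20 per arm) use the standard large-sample path.
Fully tied inputs return p = 1.

### Fold change

The fold change is the ratio of arithmetic means on the linear (RPKM-like)
scale with a pseudocount, `(mean(case) + c) / (mean(ref) + c)`, default
c = 0.1. RPKM-style values are nonnegative but can be zero; the pseudocount
guards the denominator and is configurable (set `pseudocount = 0` for the
plain ratio). Thresholds are strict inequalities everywhere (FC > 2,
FDR < 0.05, |log2FC| > 1, r > 0.5), and the tumor-vs-normal screen
(`callDysregulatedTumorNormal()`) uses *raw* p < 0.05 with |log2FC| > 1 and
refuses cohorts with fewer than 6 normal samples via a classed condition, so
multi-cancer sweeps can skip them explicitly.

### Consensus network choices

Correlations are computed on `log2(x + 1)`-transformed expression, by
default over the case-arm (NET) samples only: co-expression among NET
samples is what characterizes the regulator–program relationship, and
including the non-NET arm would inflate every correlation through the group
shift. Both the sample selection and the transform are arguments of
`buildConsensus()`. The r > 0.5 rule is applied to the *signed* correlation,
strictly; pairs with undefined correlation (zero variance) contribute no
edge, and weight-0 edges are omitted entirely rather than kept at weight 0,
which would distort modularity.

Community detection uses deterministic greedy modularity maximization
(fast-greedy agglomeration) with nodes in sorted identifier order. The
contract is determinism given the seed plus a partition at least as good as
the trivial one-community partition (modularity 0); if the greedy heuristic
ends below that bound on a pathological graph, the trivial partition is
returned. The "top" community is the largest by node count, with ties broken
by total internal edge weight and then by smallest community label; TFs
within it are ranked by weighted degree, ties broken lexicographically.

### Signature scores

A signature score is the per-sample sum of per-gene z-scores,
`z = (x − μ)/σ`, with μ and σ the within-cohort ("study") mean and standard
deviation of the gene. Scores therefore sum to zero across a cohort's
samples and are invariant under per-gene positive affine rescaling of the
expression values. Two conventions were genuinely open:

* **σ denominator.** The sample convention (n − 1) is the default, treating
  the cohort as a sample of a population; `sdType = "population"` is
  available.
* **Scale of x.** Scoring uses the pre-normalized expression values as
  stored, because the defining identities above (and the worked z-score
  examples) only hold on the scale that is actually z-scored; a
  `log2 = TRUE` option applies `log2(x + 1)` first, which is advisable for
  heavy-tailed RPKM data where a single outlier sample would otherwise
  dominate the sum.

Genes shared between two signatures can bias their score correlation;
`signatureOverlap()` reports the overlap and `signatureScore(exclude = )`
drops it (off by default).

The closed-form expectation under a shared latent factor — two disjoint
signatures of m genes each loading with λ on one factor give score
correlation `m λ² / (1 + (m − 1) λ²)`, reducing to λ² at m = 1 — is exported
as `factorScoreCorrelation()` and verified by Monte Carlo in the test suite;
`simulateCorrelatedSignatures()` generates matching cohorts (score these
with `log2 = TRUE`, since the factor model is planted on the log scale).

### Interval arithmetic

Coordinates are 0-based half-open on disk (BED) and 1-based closed in
`GRanges` in memory; `readBed()`/`writeBed()` perform the conversion and
reject malformed lines with their line numbers. The TSS of a `+`-strand gene
is its interval start, of a `-`-strand gene its interval end (strand-aware
`resize`). Peak-to-gene assignment uses the *peak midpoint* (summits are not
retained after peak calling, which is out of scope) with the distance window
inclusive at exactly 20,000 bp; a midpoint 20,001 bp away is not assigned.
Peak-set overlap uses ≥ 1 bp intersection (configurable `minOverlap`), with
Venn counts reported per input set: a peak overlapping several peaks of the
other set counts once, the appropriate bookkeeping when set cardinalities
differ. Enrichment of a gene set among peak-bearing genes is a 2×2 Fisher
exact test; the odds ratio reported is the sample odds ratio ad/bc (`Inf`
under perfect association), not the conditional MLE.

## The synthetic-cohort generator

`simulateCohorts()` draws log2 expression as
`baseline + shift + noiseSD · z`, exponentiated to an RPKM-like scale:

* per-gene baselines Uniform(3, 8) on the log2 scale (moderate-abundance
  genes);
* `shift = effectLog2FC` for planted upregulated genes in NET samples
  (default 2, i.e. a 4-fold multiplicative effect);
* for the module genes in NET samples, `z = ρ·F + sqrt(1 − ρ²)·ε` with a
  shared per-sample factor F, so pairwise module correlation has expectation
  ρ² (default ρ = 0.9 → r ≈ 0.81, comfortably above the 0.5 edge threshold);
  all other entries are independent standard normals;
* `noiseSD` defaults to 1 on the log2 scale, a typical spread for bulk
  expression data.

Defaults describe the reference study conditions used throughout the tests:
3 cohorts, 500 genes, 30 planted upregulated genes including 9 TFs, a
12-gene module driven by the first TF, and 20 + 20 samples per cohort.
Values are floored at a tiny positive constant and never exactly zero, so
pseudocount handling is exercised by dedicated fixtures rather than by
default. Identical config and seed reproduce the matrices bitwise.

`simulateGenomeFixtures()` places one gene per 100 kb on a synthetic contig
`chrS1` with alternating strands and builds peak sets whose midpoints fall
inside (targets) or 30 kb outside (controls) the 20 kb TSS windows; motif
and interactor decoy lists are drawn outside the planted program so that the
three-filter cascade recovers exactly the planted co-factor. One TSS per
gene is modeled; multi-TSS genes are a documented extension point.

What the generator does **not** emulate: batch effects, count noise
(negative-binomial mean–variance coupling), correlated background genes,
multi-TSS isoforms, or realistic genome annotation. Passing tests therefore
demonstrate correctness of the algorithms under a clean log-normal factor
model, not robustness to real-data pathologies.

## A worked run

```{r discovery}
cfg <- pipelineConfig(simulation = simulationConfig(), seed = 1)
report <- runDiscovery(cfg)
report
```

The planted master TF (`TF01`) is expected at rank 1 with high per-cohort
recall and precision. The cascade workflow recovers the planted co-factor:

```{r cascade}
runCascade(cfg)
```

## Problem sizes and determinism

The validation suite uses the reference configuration above: 20 seeded
studies for regulator recovery, 50 null cohorts (no planted effect) for
false-call control, 100 random interval fixtures of up to ~250 peaks against
quadratic oracles, and 20 replicates of the 200-sample factor-model cohorts
for score-correlation recovery. These sizes give stable seed-averaged rates
while keeping a full run in the order of a minute. All randomness flows
through explicit integer seeds; reports rerun with the same seed are
byte-identical, including their JSON serialization.

## Known limitations

* Fold change is mean-ratio based; no count-model (negative binomial)
  differential testing, covariate adjustment, or paired designs.
* The network is correlation-based and undirected; no partial correlations
  or directed regulatory inference.
* Community detection guarantees determinism and the modularity lower
  bound, not global optimality.
* Real signature gene sets (e.g. a 32-gene hypoxia signature) are inputs in
  GMT-like format, not shipped: published signatures are maintained by their
  respective authors.
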