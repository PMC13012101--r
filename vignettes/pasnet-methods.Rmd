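---
title: "Methods: proteostasis-network activity scoring and perturbation screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteostasis-network activity scoring and perturbation screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasnet)
```

`pasnet` quantifies the activity of the proteostasis subnetwork that
regulates a focal aggregation-prone protein — α-synuclein (*SNCA*) in the
motivating application — and uses that quantification for target
prioritization and drug-response screening. This vignette describes the
model behind each stage, the parameters that matter, the numerical
conventions, and what the synthetic benchmarks do and do not demonstrate.

## Network assembly

The network has two tiers.

**First-degree regulators** are proteostasis-network members with a
functional interaction pointing *into* the focal gene. Directionality comes
from the edge list; undirected edges incident to the focal gene are counted
as inward, because functional-interaction resources mix directed and
undirected rows and an undirected functional link is evidence of regulation
in either direction. Each first-degree gene must carry a curated role —
*promoter* (sign +1) or *attenuator* (sign −1) of aggregation. Role
curation itself is input data, not something the package derives.

**Upstream genes** come from case/control expression cohorts. All analysis
is on *relative* expression, `log2(gene) − log2(SNCA)` within each sample,
because the biology of interest is the balance of the network against the
focal protein rather than absolute transcript abundance. Per cohort and
gene, the case−control difference in mean relative expression is the fold
change (in log2-ratio units) and group separation is tested with a
two-sided Wilcoxon rank-sum test. A gene is a *consensus* gene when it
passes `|fc| > 0.3`, adjusted `p < 0.05`, with the same direction, in at
least `ceiling(n_datasets / 2)` cohorts. Consensus genes that interact with
at least one first-degree gene are integrated as upstream nodes.

Two conventions deserve a note:

- *Multiplicity adjustment.* The method's own description mixes Bonferroni
  language with an FDR cutoff. The package defaults to Benjamini–Hochberg
  (`adjust = "BH"`) — the FDR reading — with Bonferroni selectable. At the
  cohort sizes typical of these datasets (~10 vs ~10), a rank test's
  smallest attainable normal-approximation p-value times several hundred
  genes sits near the Bonferroni boundary, so the choice is consequential
  and is therefore explicit and logged in the output.
- *Signs for unannotated upstream genes.* An annotated role always wins;
  otherwise an upstream gene takes its consensus direction as its sign
  (+1 if up in disease relative to the reference). The rationale: the score
  treats disease-elevated relative expression of network partners as
  aggregation-promoting activity.

**Wilcoxon implementation.** For `min(n, m) <= 8` the p-value is computed
by full enumeration of all `choose(n + m, n)` assignments of the pooled
mid-ranks, which remains exact under ties; the two-sided value is
`2 * min(P(W <= w), P(W >= w))` capped at 1, so identical groups give
exactly 1. Larger groups use the normal approximation with tie and
continuity correction via `stats::wilcox.test`. One stated example for the
large-sample case ("p equals the exact complete-separation value") is
internally inconsistent with the size rule; the size rule wins and the
large-sample branch is the corrected normal approximation.

## The proteostasis activity score

For network genes *i* with signs *aᵢ* and within-sample z-scores *zᵢ*
(standardized across *all* genes of the sample, population-sd convention),

$$\mathrm{PAS} = \frac{1}{K}\sum_{i \in N} a_i z_i .$$

z-scoring is *within sample across genes*, never per gene across samples:
the score asks where the network genes sit inside each sample's own
expression distribution, which makes it comparable across samples and
platforms. Missing network genes renormalize K by default
(`missing_policy = "renormalize"`, with the count reported); a hard-error
mode exists for strict reproducibility runs. ΔPAS applies the same signed
mean to a differential signature and is exactly linear in it.

PAS can be computed from absolute log2 expression or from the relative
(gene:*SNCA*) matrix; the default in the pipeline is absolute log2
expression, and the choice is visible in the code path used.

**Cell-line ranking** follows the same score: lines are kept only when the
reference gene is detectable (nTPM > 2, strict), each gene is divided by
the reference within the line, the ratio is log2-transformed before
z-scoring (the log makes up- and down-deviations symmetric, matching the
microarray arm; a raw-ratio mode is available), PAS is z-scored across
lines, and the two-sided standard-normal tail of that z is attached as a
p-value. The ranking is descending in PAS — lines whose baseline network
state is most aggregation-promoting first.

## Influence scores

The influence stage works on the undirected simple projection of the
network (direction semantics of functional interactions are heterogeneous,
so direction is not trusted for propagation):

- **Heat diffusion**: `H = exp(−tL)` with the combinatorial Laplacian
  `L = D − A`, computed by symmetric eigendecomposition. A node's influence
  is `1 − H_ii`, the share of a unit of heat that has left it at time `t`.
  Default `t = 0.1`; influence is monotone in `t` and the default sits in
  the regime where local structure still dominates.
- **Personalized PageRank**: `r = (1 − α)s + α Wᵀr` with damping
  `α = 0.85` (the standard choice) and the restart vector `s` on the focal
  gene — influence is measured *relative to the focal protein*. Per-node or
  uniform seeding are available; outputs record the mode. Dangling nodes
  teleport their mass to the seed. Iteration stops at an L1 change below
  1e-12, and scores are normalized to sum exactly 1.

The quadrant classification splits each axis at its median (`>=` = high):
high/high master regulators, high-heat/low-PPR signal modulators,
low-heat/high-PPR hubs, low/low peripheral. With a degenerate score
distribution every gene is high by the `>=` convention, which is the
documented tie behaviour rather than an error.

## The digital twin

The twin is a *static, population-level linear surrogate* of the network in
a tissue, fitted on single-cell expression:

1. **Per-cell z-scoring** across all genes, with each cell's mean and sd
   *frozen* in the result. Freezing matters: after perturbing one gene we
   must not silently rescale every other gene, so perturbed values are
   re-standardized with the baseline statistics.
2. **Shrinkage GGM.** The gene–gene correlation matrix across cells is
   estimated with analytic identity-target shrinkage — the
   Schäfer–Strimmer intensity λ is computed from the data, guaranteeing a
   positive-definite estimate — and inverted to partial correlations.
3. **Edge significance.** Observed partial correlations are modelled as a
   two-component mixture: a null density
   `f0(r) ∝ (1 − r²)^((κ−3)/2)` whose effective degrees of freedom κ are
   fitted by matching the median |r| of the bulk (robust to a minority of
   true edges), and an alternative carrying the tails. The null proportion
   η0 is estimated from the p-value distribution (Storey, λ = 0.5) and
   q-values are η0-scaled Benjamini–Hochberg tail areas. Plain BH is
   available behind `qvalue_method = "BH"`.
4. **Linear model.** Each ordered pair with `q < 0.05` carries the OLS
   slope of target z on query z; everything else is exactly zero.
5. **Perturbation.** A query gene's basal linear-scale level is multiplied
   by a factor (knockdown ladder 0.06–0.75, overexpression ladder
   1.25–8); on the log2 scale this adds `log2(factor)`. The query's z is
   recomputed with the frozen stats, every partner's z shifts by
   `slope × Δz_query` — one propagation step, no fixed-point iteration,
   because the fitted object is a single-query predictive model, not a
   dynamical system — PAS is recomputed per cell, and the shift is
   summarized as Cohen's d with pooled sd (n−1 denominators). Thresholds
   d > 0.5 and d > 0.3 are the conventional annotation points. Factor 1 is
   the exact (bitwise) identity.

Whether to perturb on the linear or z scale is genuinely open; the
linear-scale-with-frozen-stats convention is the default because the
experimental analogue (si/shRNA, overexpression constructs) acts on
transcript abundance, and a direct z-shift mode would be a one-line
variant.

## Drug screening

For each treatment signature (drug × cell line × concentration) the ΔPAS is
the signed mean over network genes present. Per drug and line, replicate
signatures at a dose are averaged, and the Pearson correlation `r` of ΔPAS
with log10 concentration is computed with a two-sided t-transform p-value
on `n − 2` df (Spearman selectable; Pearson on the log scale is the
default reading of "correlation with concentration (log scale)"). Constant
ΔPAS is defined as `r = 0, p = 1`; fewer than 3 distinct doses flags the
record as undefined and excludes it downstream.

A drug is an *inhibitor* in a line when `|r| > 0.5`, `p < 0.05` and
`r < 0`; *promoter* with `r > 0`. Across lines, a call requires the same
sign of `r` in every line, `|r| > 0.5` in every line, and `p < 0.05` in at
least one line (the stricter every-line-p variant is a switch). Drugs not
tested in all lines are reported separately and never ranked. Ranking
within a class is by mean |r| across lines, descending, ties broken
lexicographically — classification is exactly invariant to concentration
unit changes, since rescaling shifts log10 by a constant.

## What the synthetic generators emulate

Every pipeline input has a seeded generator with planted truth:

- `gen_edgelist` — a focal-gene interaction neighbourhood with known
  first-degree, upstream and background tiers and role annotations at a
  stated promoter fraction (default 0.5).
- `gen_case_control_sets` — normalized log2 microarray-like cohorts:
  homoscedastic Gaussian noise (default sd 0.2 log2 units) around per-gene
  baselines, with gene:*SNCA* shifts of ±1.0 log2 units planted in the
  case samples of a chosen subset of cohorts, 10 cases and 10 controls per
  cohort by default (the motivating datasets required at least five per
  group).
- `gen_single_cell` — cells drawn from a multivariate normal with a known
  precision matrix, plus independent background genes. The background
  block exists because per-cell standardization imposes a sum-to-zero
  constraint over the gene set: on a matrix containing only the network
  genes the restricted correlation matrix is singular along the all-ones
  direction and its shrunk inverse acquires a spurious uniform offset. Real
  transcriptomes have thousands of genes, making the constraint negligible;
  a few hundred background genes reproduce that regime. The companion
  `planted_precision` builds a cycle with exact partial correlation 0.3 on
  its edges and 0 elsewhere.
- `gen_dose_signatures` — per-condition ΔPAS targets
  `slope × log10(conc) + intercept + noise`, allocated to genes as
  `aᵢ × target` plus *centered* jitter, so the recomputed ΔPAS equals the
  target exactly: the ΔPAS identity, not any particular gene allocation, is
  the generator's contract.
- `gen_cell_line_table` — baseline nTPM with a planted activity gradient
  on the network genes and a stated fraction of lines with detectable
  reference expression; noise defaults to 0 so rank recovery is exact.

Gaussianity is deliberate everywhere: the scoring and GGM stages consume
z-scores, so Gaussian emulation matches the model's assumptions. The
generators do **not** emulate microarray platform artifacts, single-cell
dropout or count noise, batch effects, or cell-type structure. Passing the
synthetic benchmarks therefore demonstrates correctness of the algorithms
and internal consistency of the pipeline — not robustness to the messiness
of real data, which must be assessed on real data.

## Benchmark problem sizes

The shipped tests and the acceptance script use: 1,000 random scoring
instances; 200 enumeration checks of the rank test; consensus recovery on
6 cohorts × (10 planted + 500 background) genes; GGM recovery on a 60-gene
cycle (partial correlation 0.3) from 2,000 cells with 240 background genes,
averaged over 10 seeds; perturbation contracts on 500 cells; a drug screen
of 200 drugs × 2 lines × 6 doses (slopes 0, ±0.2, ±0.5, ±1.0; ΔPAS noise
0.05), averaged over 10 seeds. These sizes give stable recovery statistics
(edge sensitivity and screen sensitivity at 100%, false-edge and
false-call rates a few percent) while keeping a full run in the order of a
minute.

## Numerical conventions and degenerate inputs

- Population sd (divisor n) for all within-sample z-scores; a constant
  sample z-scores to all zeros with a warning.
- Probe collapse keeps the maximum-variance probe per gene; variance ties
  break toward the lexicographically smaller probe id.
- Linear→log2 conversion uses `log2(x + 1)`; the pseudocount is a
  parameter.
- `ceiling()` implements "at least half" for odd cohort counts.
- PageRank iterations converge to L1 < 1e-12; the heat kernel comes from a
  symmetric eigendecomposition, so row sums are conserved to ~1e-15.
- Result tables are written with six significant digits, fixed column
  order and stated sort keys, making pipeline outputs byte-reproducible.

## Known limitations

- The twin is linear, one-step, cross-sectional and not cell-type
  stratified; it is a hypothesis-generating surrogate, not a mechanistic or
  individualized model.
- Gene identity is by exact symbol; no alias resolution across platforms.
- The consensus stage tests the intersection of genes present in all
  cohorts.
- GCTX (HDF5) input is not supported; TSV and GCT 1.2/1.3 text formats
  are. Role curation and external target-database annotations are inputs,
  never derived.
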