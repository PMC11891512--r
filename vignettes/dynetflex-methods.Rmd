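---
title: "Dynamic network reconfiguration with dynetflex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network reconfiguration with dynetflex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`dynetflex` implements a complete analysis chain for time-varying
community structure in functional brain networks: sliding-window dynamic
functional connectivity (dFC), multilayer modularity optimization,
reconfiguration metrics, temporal core–periphery classification, and
covariate-adjusted permutation statistics. Because suitable resting-state
fMRI cohorts are rarely shareable, the package also contains a
first-class synthetic-cohort generator with planted, time-varying
community structure, so that every downstream stage can be validated
against known ground truth.

The pipeline assumes its input is an already-preprocessed region-by-time
signal table (for fMRI: after motion correction, nuisance regression and
band-pass filtering, with mean framewise displacement retained as a
per-subject covariate). Image-level preprocessing and atlas extraction
are out of scope.

# The multilayer model

Each subject's time series (typically 227 regions by 230 time points at
a 2-second sampling interval) is decomposed into overlapping windows of
`width` time points advancing by `step` (defaults 30 and 1, giving
`floor((230 - 30)/1) + 1 = 201` windows). Each window yields a Pearson
correlation matrix with zeroed diagonal; the stack of these matrices is
the dFC tensor `A[i, j, l]`.

Communities of *state nodes* (region–window pairs) are found by
maximizing the multilayer modularity

$$
Q = \frac{1}{2\mu} \sum_{ijlr}
\left[ (A_{ijl} - \gamma_l P_{ijl})\,\delta_{lr}
     + \delta_{ij}\,\omega_{jlr} \right]
\delta(g_{il},\, g_{jr}),
$$

where `P[i, j, l] = k[i, l] k[j, l] / (2 m[l])` is the Newman–Girvan
null within layer `l`, `gamma` scales the null (resolution), and `omega`
couples each node to itself across layers. `2 mu` is the total
intralayer plus interlayer weight. Defaults are `gamma = omega = 1`, the
convention of the temporal-network literature this model comes from.

Design choices a user should know about:

* **Coupling topology.** Ordinal (adjacent windows only) by default,
  matching the temporal-network convention; categorical (all pairs) is
  exposed for completeness.
* **Negative correlations.** Kept by default, entering both `A` and the
  null term, as the widely used generalized-Louvain implementations do
  for correlation input. Policies `"zero"` and `"absolute"` are exposed
  because negative weights can make a layer's total weight `2 m[l]`
  non-positive, in which case the null model is undefined and the
  package raises a degenerate-layer error naming the layer. This arises
  in practice only for small node counts (a few dozen regions); at the
  227-region geometry the within-network positive mass dominates.
* **No Fisher transform** by default (a flag exists): correlations are
  passed to community detection as-is.

## Optimization

The optimizer is the classic two-phase Louvain procedure applied to the
sparse supra-modularity matrix: greedy local moves of state nodes in a
seed-randomized order, then aggregation of communities into super-nodes,
cycling until no move improves `Q` by more than `1e-10` (gains at or
below the tolerance are rejected to avoid label churn from float noise;
ties between equal gains go to the first candidate encountered in the
randomized order). The supra-matrix is sparse by construction — dense
intralayer blocks on the diagonal plus one off-block diagonal per
coupled layer pair — which keeps the 227-region, 201-layer case
(45,627 state nodes, about 10.4 million stored entries) at a few
seconds per run on one core.

Because the greedy optimizer is stochastic, the standard protocol runs
it repeatedly (100 repetitions by default in `runPipeline()`), computes
the metrics per repetition, and averages the metrics. No consensus
partition is formed; metrics are label-free.

Partition labels are canonicalized by first appearance when scanning
layer by layer, so community counts (needed by promiscuity) and
cross-repetition comparisons are well defined. `evaluateQuality()`
recomputes `Q` by direct summation independently of the optimizer and
is tested to agree with it to `1e-10`, and against a brute-force
enumeration of all set partitions on small single-layer graphs.

# Reconfiguration metrics

For an `N x L` assignment matrix `S`:

* **Flexibility** `F_i = m_i / (L - 1)`: the fraction of the `L - 1`
  layer transitions at which node `i` changes community.
* **Promiscuity** `P_i = c_i / C`: the fraction of all `C` detected
  communities the node ever joins. Its attainable minimum is `1/C`
  (a node always belongs to at least one community). Descriptions of
  this metric sometimes state a minimum of `1/N`; with the definition
  `c/C` that is only correct when `C = N`, so the package documents and
  enforces `1/C`.
* **Cohesion / disjointedness** split each change into coordinated
  versus solo: a change at transition `l` is *cohesive* if at least one
  other node moves from the same source community to the same
  destination at that transition, otherwise *disjoint*. Both are
  normalized by `L - 1`, the same denominator as flexibility, so that
  **flexibility = cohesion + disjointedness exactly**, node by node.
  This additive identity is the suite's strongest internal check (it
  holds for every repetition and survives averaging by linearity). Note
  that some toolboxes instead count pairwise co-moves ("cohesion
  strength"); the per-change-opportunity normalization used here is the
  one under which the identity is exact.

Metrics are averaged over optimizer repetitions and aggregated by
unweighted means to the ten functional networks and to the global level.

**Temporal core–periphery:** nodes in the lowest decile of
(group-mean) flexibility form the temporal core, the highest decile the
periphery; `k = round(0.10 N)` nodes per class with halves rounded away
from zero (23 of 227). Boundary ties are broken by stable region order
with a warning; the fraction and the per-subject variant are options.

# Group statistics

Each feature (metric by unit by level) is compared between groups with
the t statistic of the group coefficient in a linear model
`value ~ group + age + gender + mean_fd`; with no covariates this is
exactly the pooled two-sample t. The group is coded so that a negative
t means group 1 sits below group 2 after adjustment. The null
distribution is built by permuting group labels over subjects
(covariates stay attached to their subjects and the model is refit per
permutation), with `p = (1 + #{|t*| >= |t|}) / (1 + B)` at `B = 5000`
permutations by default; when fewer distinct assignments than `B` exist
the null is enumerated exactly. FDR control is Benjamini–Hochberg within
each metric-by-level family (e.g. the ten network means of flexibility,
or all regions for one metric). The same seeded permutation sequence is
reused across the features of one family.

# The synthetic cohort generator

The generator emulates a two-group resting-state study: groups of 13
and 14 subjects, 227 regions, 230 time points at TR = 2 s, labelled
with the ten canonical resting-state networks (proportionally
downsampled when fewer regions are simulated).

Ground truth is piecewise stationary: module labels are constant within
epochs of `epochLength` time points (default 30, matched to the default
window width so ground-truth changes are countable at the detection
granularity) and may change at epoch boundaries. At each boundary every
node switches independently with the group's `switchRate`; a switching
node moves cohesively — together with at least one co-flagged partner
from its module, to a common destination — with probability
`cohesiveFraction` (default 0.5), otherwise solo to a module none of
its co-members chose. A cohesive designee without a partner falls back
to a solo move, which slightly depresses the realized cohesive fraction
at low switch rates. Boundary draws that would empty a module are
re-drawn.

Within an epoch, signals are multivariate normal with correlation
`withinModuleCorr` (default 0.6) inside modules and zero between, unit
diagonal, plus independent Gaussian noise (`noiseSd`, default 0.3), so
the observable within-module correlation is
`withinModuleCorr / (1 + noiseSd^2)`, about 0.55 at the defaults —
values typical of well-synchronized resting-state networks. Covariates
are drawn independently of group (age uniform on 17–28 years, gender
0/1, mean framewise displacement uniform on 0.05–0.25 mm), making them
null confounders; the adjustment machinery is exercised without
injecting bias. Band-pass filtering and hemodynamic forward modelling
are deliberately absent: the sampler already produces the target
correlation structure, and the goal is ground-truth recovery, not
biophysical realism.

Everything derives deterministically from the master seed: per-subject
partition and signal seeds are recorded in the manifest, optimizer
repetitions use consecutive seeds, and the permutation stream is seeded
per test family.

# What the validation suite shows — and its limits

The test suite validates window arithmetic against the printed geometry
(230 TRs, width 30, step 1, hence 201 layers and a 227-by-201 assignment
matrix), region bookkeeping (264 atlas regions minus 37 unaffiliated
gives 227, split 214 cortical and 13 subcortical), exact optimizer
behaviour on exhaustively enumerable graphs, the metric identities, and
three statistical properties on synthetic cohorts:

* groups with planted switch rates 0.05 versus 0.30 (13 vs 14 subjects)
  show a significantly lower global flexibility in the low-switch group
  with a negative t, in at least 8 of 10 cohort seeds;
* equal-rate null cohorts are rejected at about the nominal 5% level
  (200 replicates, band 2–9%);
* the sign of the group effect is stable across the four window
  settings (30, 1), (30, 2), (40, 1) and (20, 1).

These cohort-level experiments run at reduced problem sizes chosen to
keep the whole suite within a desk-scale compute budget: 20 regions
(16 regions and 60 time points for the null calibration) instead of
227, with optimizer repetitions scaled from 100 to 10 (1 for the null
calibration) and permutations from 5000 to 300–1000. At these node
counts occasional windows have non-positive total weight under the
keep-negative-edges default, so these experiments use the
zero-negative-edges policy; the group-difference direction does not
depend on that choice.

**A known ceiling on planted-partition recovery.** With
compound-symmetric module blocks, the latent factors of two modules have
a sample correlation of roughly `1/sqrt(width)` within any single
window (about 0.18 at width 30), and this fluctuation moves *all*
between-module pair correlations coherently. The multilayer quality
function at `gamma = omega = 1` then genuinely prefers transient
module merges during such excursions: the planted partition scores a
*lower* Q than the detected one (verified against the independent
direct-summation oracle), so no optimizer improvement can close the
gap. Median per-layer adjusted Rand index against the planted labels
plateaus around 0.75 at `withinModuleCorr = 0.6` with width-30 windows
(single-layer recovery from the full series is exact). This is a
property of sliding-window dFC itself — window-level factor noise is
real shared signal — and should be kept in mind when interpreting
absolute flexibility values; group *contrasts* survive it, as the
recovery-direction and calibration experiments show.

# Practical notes

* Degenerate inputs: zero-variance regions within a window, label
  matrices with a single layer, rank-deficient designs (e.g. a constant
  covariate) and empty core/periphery classes all raise informative
  errors rather than propagating NaNs.
* `runPipeline()` / `runSweep()` orchestrate the full chain from a
  configuration list or YAML file and write tab-separated tables plus a
  JSON run report with all seeds and parameters; a thin command-line
  wrapper lives in `inst/scripts/dynetflex-cli.R`.
* Reported p-values are never zero by construction (`+1` smoothing);
  exact enumeration takes over for tiny cohorts with a warning.
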