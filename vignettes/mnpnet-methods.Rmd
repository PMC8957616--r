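---
title: "Microbiome co-occurrence networks of populations and individuals: methods"
author: "mnpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbiome co-occurrence networks of populations and individuals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mnpnet` implements a co-occurrence network analysis pipeline for
species-collapsed 16S count tables of the kind produced in longitudinal skin
microbiome studies: compositional preprocessing, sparse network inference
with stability-based regularization selection, population networks (MNP) and
leave-one-out single-sample networks (MNI), targeted-attack robustness
scoring, and resampling-based comparison of network metrics between
timepoints. A synthetic-data module generates count tables from a known
association network so that every stage can be validated against ground
truth without access to cohort data.

# The data model

The input is a samples x taxa matrix of read counts with per-sample metadata
(subject, timepoint). Sequencing counts are compositional: only relative
abundances are observable, and naive correlation of proportions induces
spurious negative dependence. The pipeline therefore works on the centered
log-ratio (CLR) transform,

$$\mathrm{clr}(x)_t = \log(x_t + c) - \frac{1}{p}\sum_{u=1}^{p}\log(x_u + c),$$

with pseudocount $c = 1$ by default. Every transformed row sums to zero; on
strictly positive rows the transform is invariant to the total count in the
pseudocount-free limit, which is what removes the closure constraint.

Before the transform, taxa are filtered on two criteria combined with AND:
mean relative abundance across samples at or above 0.01% and prevalence
(fraction of samples with a nonzero count) at or above 37%. These thresholds
are the package defaults; the abundance summary can be switched from `mean`
to `max`. Rarefaction to a fixed depth (default 50,000 reads, subsampling
without replacement; shallower samples are dropped) is available but is off
by default in the network pipeline: rarefaction primarily serves diversity
analyses, and the CLR works on unrarefied counts. Both orders are supported
through the configuration, and the prevalence filter is applied before
rarefaction by default.

# Network inference

## Neighbourhood selection

The association network is estimated by node-wise L1-penalized regression
(Meinshausen-Buhlmann): each taxon's standardized CLR profile is regressed
on all other taxa,

$$\hat\beta_j(\lambda) = \arg\min_\beta \frac{1}{2n}\lVert x_j - X_{-j}\beta\rVert_2^2 + \lambda\lVert\beta\rVert_1,$$

with standardized predictors and no intercept (CLR rows are centered by
construction; columns are standardized to population unit variance). The
solver is glmnet's coordinate descent with convergence threshold `1e-8` and
up to $10^5$ iterations; with a single predictor the univariate
soft-threshold solution is used in closed form. `lambda_max` is the largest
absolute pairwise correlation of the standardized columns — the smallest
penalty at which every neighbourhood is empty — and the default path spans
20 log-spaced values down to `0.01 * lambda_max`. The stated "lambda
threshold of 0.01" in this family of analyses is ambiguous between a path
floor and a stability threshold; the package reads it as the path floor
(`lambda_min_ratio = 0.01`) and keeps the canonical 0.05 for the stability
threshold, with both exposed in the configuration.

Directed neighbourhoods are symmetrized with the OR rule by default (an edge
exists if either regression selects it; AND available); the edge weight is
the mean of the two directed coefficients, an absent direction counting as
zero. Zero-variance taxa are excluded from regressions with a warning.

## StARS

The penalty is selected by stability: the path is refitted on `n_subsamples
= 50` random subsamples (drawn without replacement at `subsample_fraction =
0.8`, mirroring the 80% resampling level used elsewhere in the pipeline),
and for each penalty the edge instability is

$$\bar D(\lambda) = \binom{p}{2}^{-1}\sum_{i<j} 2\,\hat\theta_{ij}(\lambda)\,(1 - \hat\theta_{ij}(\lambda)),$$

where $\hat\theta_{ij}$ is the fraction of subsamples selecting edge
$(i,j)$. $\bar D$ is monotonized by a running maximum as $\lambda$
decreases, and the selected penalty is the smallest $\lambda$ — the densest
model — whose monotonized instability stays at or below the threshold
(0.05), with ties broken toward the sparser side. This is the canonical
selection direction: because the monotonized instability only grows as the
model densifies, selecting on the other side of the threshold would always
return the empty model at `lambda_max`. Edge stabilities
$\hat\theta_{ij}$ at the selected penalty are attached to the final network.

# Population and single-sample networks

The **MNP** is the full pipeline applied to all samples of a group
(filter, CLR, StARS-selected fit). The **MNI** of sample $i$ subtracts the
network refitted with $i$ left out from the group's MNP: edges present only
in the full network are *gained*, edges present only in the leave-one-out
network are *lost*, and shared edges carry their signed weight difference.
The subtraction is lossless — patching the leave-one-out network with the
MNI reproduces the MNP exactly — and this identity is enforced by tests.

Two design choices deserve emphasis:

* **Pinned penalty.** Leave-one-out refits reuse the full-group selected
  penalty by default, so an MNI reflects the removed sample rather than
  re-selection noise; a free-penalty mode re-runs StARS per parent.
* **MNI metric support.** Summary metrics of an MNI are computed on its
  full signed difference network — gained, lost, and shared edges whose
  weight changed — restricted to incident nodes, with unweighted topology.
  Subtracting two weighted networks leaves exactly these edges behind;
  restricting to presence flips alone (also available, as
  `support = "symmetric_difference"` or `"gained"`) typically yields
  one-to-three-edge graphs whose degree and robustness statistics are
  uninformative.

For two-timepoint tables the comparison pipeline infers one MNP per
timepoint and computes each sample's MNI within its own group — group
differences are then differences between the timepoints' network
structures, which is the design that gives the single-sample comparison its
meaning. Bootstrap ensembles (`bootstrap_mnp`) instead resample one group's
samples without replacement at the 80% level (default 1000 replicates,
point fits at the pinned penalty so ensembles of this size stay tractable;
a free-penalty mode exists) and record each replicate network's metric set.

# Connectivity and robustness

All metrics are computed on the unweighted topology. Besides node count,
edge count and mean degree ($2E/N$), the package scores robustness by
simulated targeted attack: nodes are removed one at a time in decreasing
betweenness centrality with degree as secondary key and lexicographic node
id as final tie-break, the ranking computed once on the intact graph
(static attack; an adaptive mode recomputes it per step). After each
removal the size of the largest connected component and the natural
connectivity

$$\mathrm{NC}(G) = \ln\Big(\frac{1}{n}\sum_{i=1}^{n} e^{\mu_i}\Big),$$

over adjacency eigenvalues $\mu_i$, are recorded. The informal gloss
"average eigenvalue of the adjacency" is read as this standard spectral
measure — the arithmetic mean of adjacency eigenvalues is identically zero
for simple graphs and therefore cannot be meant. NC is computed through a
numerically stable log-sum-exp and strictly increases under edge addition.

The robustness score is the trapezoidal area under the attack trajectory of
the response (natural connectivity by default, LCC fraction available)
normalized by its intact-graph value, so scores live in $[0, 1]$ for
non-increasing curves; *fragility* is reported as one minus robustness, so
a decrease in fragility corresponds to an increase in robustness. A graph
whose intact response is zero cannot be normalized and scores zero with a
flag.

# Cohort statistics

* `bootstrap_mean_test`: two-group difference of means under the
  shift-to-pooled-mean resampling null, resampling with replacement within
  groups, with the $(1+k)/(B+1)$ correction; two-sided by default, with
  directional alternatives. Each group's resampling stream is seeded from
  the group's own values, making the test exactly symmetric under argument
  exchange.
* `paired_wilcoxon`: signed-rank test on `after - before`; zero differences
  dropped (Pratt's variant available), midranks for ties. The null
  distribution of the positive-rank sum is exact up to 25 nonzero pairs —
  including under ties, via a generating-function convolution over doubled
  midranks — and a tie- and continuity-corrected normal approximation is
  used beyond.
* `pearson_correlation`: $r$ with
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom.
* `change_summary`: fold change (follow-up over baseline) and percent
  change, with rounding confined to the print method (two decimals and
  integer percent respectively).

# The synthetic generator

No generative model is prescribed by the analyses the pipeline implements,
so the generator uses the standard benchmark for compositionally-aware
network inference, the logistic-normal-multinomial: a ground-truth
adjacency (band, Erdos-Renyi with an exact edge count so densities are
deterministic, scale-free, or three-block cluster topology) is lifted to a
positive-definite precision matrix by placing magnitude 0.3 on the support,
shifting the diagonal to a target condition number of at most 10 (smallest
eigenvalue at least 0.01) and rescaling to unit diagonal — the support is
preserved exactly. Latent log-abundances are multivariate normal with
covariance the precision inverse and mean the log of a geometrically
decaying base composition (the skewed abundance profile typical of skin
communities); the softmax maps them to a composition and reads are drawn
multinomially.

Per-sample depths follow a log-normal law fitted so the untruncated mean
matches the cohort mean (default 326,333 reads) and the bounds (63,892 and
975,103) sit at the expected extreme order statistics of the cohort size,
then truncated to those bounds. The default cohort is 36 baseline plus 34
post-intervention samples. The two-arm generator draws the baseline truth
at one density and the post truth as a strict superset at a higher density
(shared ecological core plus added links), so the post arm is denser by
construction.

All randomness flows from one integer master seed through a deterministic
per-stage (and per-replicate) splitter, so multi-stage runs are exactly
reproducible and bootstrap replicates are seeded by draw index against
sorted sample ids — independent of input row order.

What the generator does *not* emulate: read-level errors, chimeras,
taxonomy mis-assignment, zero-inflation beyond the multinomial, batch and
subject-level covariance, or contamination episodes. Passing recovery tests
therefore demonstrates correctness of the inference machinery under the
stated model, not performance on real skin data.

# Numerical choices and degenerate inputs

* glmnet convergence threshold `1e-8`, `1e5` iteration cap; if a path tail
  still fails to converge the last converged solution is carried forward
  rather than reporting a spuriously empty model.
* Weight comparisons in the MNI subtraction use a `1e-12` tolerance for
  "changed"; the reconstruction identity is exact on edge sets and `1e-8`
  on weights.
* Degenerate graphs (empty node set, no edges, single node) yield zeroed,
  flagged metric sets; attack curves require at least two nodes.
* Sample depths below the rarefaction depth drop the sample (subsampling
  without replacement is undefined beyond the total); an all-shallow table
  is an error.
* An all-removing taxon filter raises an error naming the stricter
  criterion.

# Problem sizes used by the test suite

The validation suite exercises the pipeline at desk scale: recovery of a
30-taxon band network from 300 samples at 50,000 reads (ten replicate
cohorts), the leave-one-out reconstruction identity on a 20-sample cohort,
bootstrap-test calibration over 500 null replicates, and a two-arm contrast
with 20 samples per arm over 30 taxa with true densities 0.05 and 0.15.
These sizes were chosen to mirror the cohort scale the pipeline targets
while keeping the suite fast.

# Known limitations

* At two-to-three dozen samples per group, StARS-selected models are very
  sparse and their selected density is itself noisy; moreover, a truly
  denser group tends to show *more* edge instability under subsampling and
  can therefore be selected *sparser* than a less connected group. The
  two-arm single-sample contrast at 20 samples per arm is power-limited for
  ratio-type metrics (mean degree, robustness), and a single synthetic
  cohort of that size will not always reach significance on all four
  metrics even though the underlying post-arm truth is three times denser.
  Larger cohorts, or comparisons at a penalty shared between groups,
  stabilize the contrast.
* The neighbourhood method estimates conditional dependence of CLR
  profiles; CLR centering slightly distorts the latent precision structure
  (an $O(1/p)$ projection effect), which is part of why recovery is tested
  against simulated ground truth rather than assumed.
* MNI objects are differences of estimated networks; their edges should be
  read as perturbation support, not as interactions present in one sample.
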