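---
title: "Differential correlation networks, the disparity filter, and network-based PLS-DA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential correlation networks, the disparity filter, and network-based PLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DiffNetBackbone)
```

## The model

DiffNetBackbone compares two phenotype groups of a metabolite abundance
table not by mean differences but by changes in pairwise association. The
workflow has three stages.

**1. Differential network.** After a natural-log transform, Pearson
correlation matrices are computed separately within cases and controls and
every metabolite pair receives the differential weight

$$ w_{ij} \;=\; \bigl|\rho_{case}(i,j) - \rho_{control}(i,j)\bigr|^{\gamma},
\qquad \gamma > 1 . $$

The exponent (default $\gamma = 4$) pushes small correlation differences
towards zero while conserving large ones, producing a heavy-tailed weight
distribution. Significance is assessed by a group-label permutation test:
in each of $B = 1000$ permutations the samples are reallocated to the two
phenotypes *once* (group sizes preserved) and **both** correlation
matrices, hence all pairwise weights, are recomputed from that single
shared shuffle. Pairs are never permuted independently — one shuffle per
permutation is what removes the phenotype–correlation association while
preserving the correlation structure among metabolites, and it is also
what makes $B = 1000$ affordable. Metabolites are linked when the edge
p-value is below 0.05; no multiple-testing correction is applied at this
stage (the disparity filter is the subsequent pruning step), though
Benjamini–Hochberg adjustment is available via `adjust = "BH"`.

The p-value uses the add-one exceedance estimator with ties counted as
exceedances,

$$ p_{ij} = \frac{1 + \#\{b : w^{(b)}_{ij} \ge w^{obs}_{ij}\}}{B + 1}, $$

which is conservative and can never return an exact zero; the raw strict
proportion $\#\{w^{(b)} > w^{obs}\}/B$ is available through
`estimator = "raw"` for compatibility, but a raw proportion of 0 is not a
valid permutation p-value, which is why it is not the default. Correlations
that become non-finite inside a shuffle (a constant column) are treated as
weight 0 with a warning.

**2. Disparity-filter backbone.** For each node $i$ of degree $n_i$ the
incident weights are normalized, $p_{ij} = w_{ij}/\sum_j w_{ij}$, and
local heterogeneity is summarised by the disparity measure
$Y(n_i) = n_i \sum_j p_{ij}^2$, which equals 1 when all edges share the
weight equally and $n_i$ when one edge carries everything. Against the
null hypothesis that a node's weights arise from a uniformly random
partition of the unit interval, the edge-end statistic is
$\alpha_{ij} = (1 - p_{ij})^{n_i - 1}$, and an edge enters the backbone
when $\alpha_{ij} < \alpha$ (strict inequality, default $\alpha = 0.3$)
**for at least one** of its two endpoints. Because the criterion is local,
the filter operates at every scale of the weight distribution at once — a
weak edge can survive if it dominates its own node's neighbourhood — which
is exactly what a global hard threshold cannot do. Degree-1 endpoints are
assigned $\alpha_{ij} = 1$: their single edge carries all the weight by
necessity rather than organisation, so such an endpoint can never justify
its own edge; the edge may still survive through its other end. Backbones
are monotone nested in $\alpha$, and on heterogeneous weight profiles the
kept fraction of total weight exceeds the kept fraction of edges — the
filter's defining behaviour, asserted in the test suite. The scaling
exponent $b$ in $Y(n_i) \propto n_i^{\,b}$ is estimated by OLS on
$\log Y$ vs $\log n_i$ over nodes of degree $\ge 2$, without binning;
values near $1/2$ indicate the skewed local weight regime where the filter
is most useful.

**3. Network-based classification.** The backbone is translated into
classifier features: one column per *connected* backbone metabolite
(autoscaled log abundance) and one interaction column per backbone edge —
the elementwise product of the two autoscaled node columns, itself
autoscaled. A single-response PLS regression (PLS1, NIPALS) is fitted
against the 0/1-encoded phenotype, the class is called by thresholding the
continuous response at 0.5, and the number of latent components is chosen
by 20× repeated, stratified 10-fold cross-validation (selection metric:
mean accuracy; ties broken by AUROC, then by the smaller count). Feature
influence is ranked by VIP with explained-response-variance weighting,
$\mathrm{VIP}_f = \sqrt{p\,\sum_a SS_a (w_{af}/\|w_a\|)^2 / \sum_a SS_a}$,
whose mean square over features is exactly 1. Performance is reported as
accuracy, AUROC (rank statistic / Mann–Whitney, ties at ½), F1 (harmonic
mean of PPV and sensitivity), sensitivity, specificity, PPV, NPV and FNR;
metrics with zero denominators are reported as `NA`, never silently 0.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `gamma` | 4 | weight exponent; larger values suppress small $|\Delta\rho|$ harder (monotone decreasing for $|\Delta\rho|<1$) |
| `nPermutations` | 1000 | permutation-test resolution; smallest attainable p is $1/(B{+}1)$ |
| `pCutoff` | 0.05 | per-edge significance rule |
| `alpha` | 0.3 | disparity threshold; smaller keeps fewer, more locally dominant edges |
| `trainFraction` | 0.7 | stratified split; per-group train size `floor(f·n + 0.5)` clamped to `[1, n−1]` |
| `cvRepeats`, `cvFolds` | 20, 10 | component-selection CV; folds reduced with a warning if they exceed the smallest class |
| `maxComponents` | 10 | capped by `min(#features, #train − 1)` |
| `keyNodeThreshold` | 0.5 | strict `>` on the product of min–max normalized degree and betweenness |
| `seed` | — | one pipeline seed, fanned out to derived split / permutation / CV seeds so stages re-run in isolation |

## Design choices where the design was open

* **Key-node normalization.** A product rule "degree × betweenness > 0.5"
  is only meaningful on a common scale; both centralities are min–max
  rescaled to $[0,1]$ (max = 1) before the product. Betweenness itself is
  computed on the backbone as an *unweighted* graph — the verbal
  definitions of hub and bottleneck mention no weights — with
  `weighted = TRUE` available (distance $1/w$).
* **Interaction-term convention.** "i·j" is the product of the two
  *autoscaled* node columns, re-autoscaled, so interaction features have
  training mean 0 and unit variance like node features; the expected value
  of a product of z-scores is the group correlation, which is precisely
  the differential signal the edge encodes. Products of raw log values
  would be scale-dependent.
* **CV leakage scope.** The network, the backbone and the feature scaling
  are learnt once on the full training set; cross-validation folds only
  the classifier. This matches the protocol of building the enriched
  dataset first, and it makes CV estimates optimistic relative to the
  held-out test set — the vignette's demo and the README example both show
  that gap, and the test cohort is the honest figure. A stricter per-fold
  re-autoscaling is available (`rescale = TRUE` in `selectComponents()`);
  re-inferring the network per fold is out of scope.
* **Class encoding.** Single-response PLS with case = 1, control = 0 and a
  0.5 decision threshold (two classes only). The case level defaults to
  the first group level and flows from the network object to features and
  reports, so the positive class of every metric is the case group.
* **Missing values** are rejected by default; optional within-group
  per-metabolite median imputation (`impute = TRUE`) is deliberately
  opt-in because silent imputation changes correlations invisibly.
  Metabolites with zero variance in either group are dropped with a
  warning (their Pearson correlation is undefined). The log base is
  natural; any fixed base gives identical Pearson correlations, so the
  choice is cosmetic.

## What the synthetic generator emulates — and what it does not

`syntheticSpec()`/`generateTwoGroup()` draw each group independently from
a multivariate normal whose correlation matrix is block-structured:
within-block pairs share a correlation that may differ between groups
(the planted differential edges), off-block pairs sit at a background
level (default 0, matching the mostly weak pairwise correlations of serum
panels). Defaults emulate the shape of a targeted serum study — on the
order of 100 metabolites and two groups of several dozen samples. Planted
effects are defined on the Gaussian (log) scale; the `lognormal` option
exponentiates afterwards so raw intensities are strictly positive and the
planted truth refers to the log-scale data the pipeline actually
correlates. Implied correlation matrices are validated for positive
semi-definiteness (smallest eigenvalue $\ge -10^{-10}$) and rejected
rather than repaired, since projection repair would silently distort the
planted effect sizes.

The generator does **not** imitate LC-MS/MS measurement error, missingness
mechanisms, batch structure, or heavy-tailed biological variation. Tests
passing on this generator therefore demonstrate the statistical behaviour
of the method (calibration, power against planted effects, filter
behaviour), not robustness to instrument artefacts.

## Numerical choices and degenerate inputs

Disparity normalization requires at least one positive incident weight; an
all-zero node is a degenerate-node error. `disparityMeasure` validates
that inputs sum to 1 within $10^{-8}$. Ties in permutation counting are
exceedances (conservative); ties at the $\alpha$ cutoff are excluded
(strict `<`, as the criterion is stated). An empty differential network
yields an empty backbone with zero fractions and a warning; an empty
backbone at the feature stage is an error instructing the caller to relax
$\alpha$ or the p cutoff. PLS components stop early with a warning if the
residual response is exhausted. Exhaustive permutation enumeration
(`exhaustive = TRUE`) replaces random shuffles by all
$\binom{n}{n_{case}}$ assignments and is intended for tiny oracle
problems only.

## Problem sizes used by the shipped checks

The test suite calibrates the permutation test on six replicate null
datasets of 60 + 60 samples × 20 metabolites at $B = 1000$ (1140 pooled
pairs), recovers a planted $\rho_A = 0.9$ vs $\rho_B = 0$ pair at 80 + 80
samples over 40 seeds, verifies betweenness and permutation p-values
against brute-force enumeration on ≤ 8-node graphs and 6-sample tables,
and runs the end-to-end demo at 45 + 45 samples × 25 metabolites with
$B = 300$ — sizes chosen so the full suite completes in a few minutes
while keeping every statistical check at meaningful power.

## Known limitations

Pearson correlation captures only linear association; rank- or
information-based differential measures are not implemented. The
permutation test shares one shuffle across all pairs, so pair p-values
within a dataset are dependent (marginally calibrated, jointly not
independent). Betweenness-based key-node selection depends on the chosen
min–max normalization; other normalizations would select different
borderline nodes. The classifier is PLS1-DA only, and no permutation test
of overall classifier performance is provided.
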