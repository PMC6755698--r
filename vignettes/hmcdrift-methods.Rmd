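---
title: "Models and methods in hmcdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hmcdrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcdrift)
```

This vignette is the package's account of its science: the models it
fits, the conventions it pins down where the field leaves room, and what
its synthetic benchmarks do and do not establish about real data.

## The task and its invariants

Hierarchical multi-label classification (HMC) assigns each instance a
*set* of labels from a partially ordered vocabulary — a tree such as
FunCat, where every function has one parent, or a DAG such as the Gene
Ontology, where terms may have several. The *hierarchy constraint* makes
label sets ancestor-closed: an assigned label implies all its ancestors.
`hmcdrift` enforces closure everywhere: datasets close label sets on
construction and on ARFF read, the synthetic generator and the drift
operator produce closed sets by construction, and the PCT forest's
predictions are hierarchy-monotone (a parent's probability never falls
below a child's), which is the prediction-side image of the constraint.

Levels are always *deepest-path* levels: `1 +` the longest directed root
path to the label, with roots at level 1. In a DAG a label reachable at
several depths gets the deepest, and the recurrence
`level(child) = 1 + max(level(parents))` holds with equality. For
GO-style tables the level-1 roots (present in every instance) can be
dropped via `per_level_stats(..., drop_level1 = TRUE)`; top-level FunCat
categories are treated as level 1, consistent with six-level FunCat
summaries.

## The predictive clustering tree forest

A predictive clustering tree (PCT) views a decision tree as a hierarchy
of clusters and chooses splits minimizing the intra-cluster variance of
the 0/1 label vectors,

$$\mathrm{Var}(S) = \frac{1}{|S|}\sum_{i \in S}\sum_{c} w_c\,
  (v_{ic} - \bar v_c)^2,$$

with per-label weights $w_c = w_0^{\mathrm{level}(c) - 1}$ so deeper,
more specific labels weigh less. The literature names the heuristic but
not the weighting; we adopt the geometric-decay convention with
$w_0 = 0.75$ by default and expose it (`w0` in `pct_config()`).

**Stopping.** A node splits only if the best candidate passes an F-test:
we cast the split as a one-way ANOVA on the weighted variance,
$F = \big(\mathrm{Var}(S) - \mathrm{Var}_w\big) \big/
\big(\mathrm{Var}_w / (n - 2)\big)$ with $\mathrm{Var}_w$ the
size-weighted mean child variance and $k = 2$ groups, accepted when
$p \le$ `ftest_level`. The test's exact form is a design choice — any
monotone significance test of the variance reduction preserves the
contract — so it is config-named and pinned by tests. A pure node
(zero variance) or one with fewer than `2 * min_leaf` instances becomes
a leaf; a perfectly separating split has $p = 0$ and is always accepted.
Degenerate inputs (all features constant) yield a single-leaf tree, not
an error.

**Leaves.** Each leaf stores the mean label vector of its training
instances. With the benchmark setting of at least `min_leaf = 5`
instances per leaf, the smallest strictly positive per-tree probability
is therefore $1/5 = 0.2$ — the analytic fact recomputed by
`scripts/acceptance.R`. Because training sets are ancestor-closed, leaf
prototypes (and hence all tree and forest predictions) are
hierarchy-monotone.

**Missing values.** The yeast-style benchmarks contain missing feature
entries but prescribe no policy, so the splitter evaluates both options
and sends missing values to the side minimizing the resulting variance,
recording that direction for prediction time. Imputation is deliberately
left out of the reader: missingness is the model's problem, not the
parser's.

**Forest.** The ensemble grows `n_trees = 50` trees (the benchmark
setting) on bootstrap resamples with per-node random feature subsets of
size `ceiling(sqrt(n_features))` (the random-forest convention; the
source setting names only "Random Forest"). Both randomizations can be
toggled. The F-test level is selected from
{0.001, 0.005, 0.01, 0.05, 0.1, 0.125} by maximizing pooled AUPRC on the
validation split; to keep selection tractable the six candidate forests
use `n_trees_select = 10` trees and only the winner is retrained at full
size. Every training path is deterministic given its seed.

A per-level multi-layer-perceptron learner in the local-classifier
tradition is not implemented; externally produced prediction matrices
(from rule-based, neural or any other methods) enter all evaluations
through `load_external_predictions()`, which is how methods outside this
package participate in comparisons.

## Pooled precision-recall evaluation

HMC datasets are heavily imbalanced, so evaluation uses the pooled
(micro-averaged) precision-recall curve rather than ROC. At threshold
$t$ a pair is predicted positive iff its probability is $\ge t$
(boundary inclusive — a pinned convention), and tp/fp/fn are summed over
all labels jointly. The curve sweeps $t$ from 0 to 1 in steps of 0.02.

Numerical conventions, each bounded by a test:

* precision at zero predicted positives is defined as 1; such degenerate
  grid points are reported in the curve but excluded from the integral,
  which is anchored at (recall 0, precision of the smallest-recall
  retained point) and evaluated by the trapezoid rule over points sorted
  by recall. Under these rules a constant predictor scores exactly the
  positive-pair prevalence.
* refining the grid from 0.02 to 0.001 moves the area by less than 0.02
  on random matrices (tested), so the coarse grid is not a material
  approximation;
* a truth with no positive pair has no curve and raises an error.
* cross-tool numeric identity with other HMC tooling is not promised:
  interpolation conventions differ between implementations.

The implementation is verified *exactly* (every grid threshold, and the
area) against a brute-force oracle that materializes each
(instance, label) pair in a loop.

## Cross-version change detection

Given two versions of a test set, pairs are compared on the
*intersection* of the label sets — labels existing in only one version
are excluded outright — and each (instance, label) pair falls in exactly
one of four groups by its (old, new) membership: added (0,1), removed
(1,0), unchanged-negative (0,0), unchanged-positive (1,1). The detection
statistic is a median difference over a model's predictions, signed so
larger always means better detection:

* added: `median(added) - median(unchanged_neg)`;
* removed: `median(unchanged_pos) - median(removed)`.

The orientation for the removed direction is a pinned convention (the
natural reading "the model scores wrong annotations below the ones it
keeps"); only the sign, not the magnitude, depends on it. Group sizes
are always reported: changed groups are typically orders of magnitude
smaller than unchanged ones, so their quantiles are noisy and outliers
outside the whiskers should be disregarded.

## Method comparison

`friedman_nemenyi()` ranks methods within each dataset (rank 1 best,
average ranks on ties) and computes the tie-corrected (Conover) Friedman
chi-square with $k - 1$ degrees of freedom; ties arise routinely in
grid-thresholded scores, hence the correction, with the degenerate
all-tied case returning statistic 0 and $p = 1$. The Nemenyi critical
distance is $q_\alpha \sqrt{k(k+1)/(6N)}$. Rather than hard-coding a
$k \le 10$ table, $q_\alpha$ is computed exactly as
`qtukey(1 - alpha, k, Inf) / sqrt(2)`, which reproduces the published
table values (e.g. 2.569 at $k = 4$, $\alpha = 0.05$) and extends to any
$k$; a test pins the agreement. Missing scores are refused — exclude a
dataset a method cannot run rather than imputing. Stochastic methods are
aggregated as the element-wise mean (and sd) of their runs before
scoring, five runs by default.

## The synthetic benchmark and what it shows

The generator emulates the *structure* of the yeast benchmarks, not
their content: a seeded random hierarchy (breadth-first growth, at most
`max_children = 4` children; DAGs add earlier nodes as extra parents with
probability 0.1, acyclic by construction); ancestor-closed label sets
sampled top-down with keep-probability
`root_label_prob * depth_decay^(level-1)`, so annotations thin out with
depth as in the real per-level tables; features equal to the sum of a
unit Gaussian prototype per positive label scaled by `signal_strength`,
plus noise, with a 2% missing rate; and disjoint train/valid/test
splits.

The default study conditions were chosen once, as plausible desk-scale
analogues of the benchmarks: 1000/400/600 train/valid/test instances
(the real splits are roughly 1600/850/1300), 60 labels (the shallow
FunCat subsets carry a few hundred, GO subsets thousands — 60 keeps a
50-tree forest trainable in minutes on one core), 60 features (the real
feature sets range from 27 to 478), prototype separation of 3 noise
standard deviations, and drift rates `p_add = 0.05`,
`p_remove = 0.02` — no quantitative drift rates are published, so these
are explicit configuration, not constants.

Drift adds only *frontier* labels (all parents already positive), so
both versions remain closed exactly as real annotation updates do;
removals drop maximal positive labels, which by maximality have no
positive descendants, again preserving closure. New-version-only labels
are grafted as leaves to exercise the intersection rule. The operator
returns the exact ground-truth pair partition, assembled from its event
log — an independent path from `identify_changed_pairs()`, and the two
are asserted equal over 50 seeded replicates.

What passing tests show: the pipeline's bookkeeping is exact, the
forest recovers planted feature-label signal (its pooled AUPRC exceeds
the mean-rule baseline, and added pairs score above unchanged-negative
ones, both collapsing under label permutation), and all statistics
behave as designed. What they do not show: performance on real
proteomic feature modalities (expression, homology, structure),
real GO semantics (relation types, namespaces), or real — possibly
adversarial — annotation noise; absolute AUPRC values on synthetic data
say nothing about absolute values on yeast.

## Known limitations

* Tree induction is exact greedy search in R; it is comfortable at the
  default scale (a 50-tree forest on 1000 x 60 data trains in about a
  minute) but not tuned for hierarchies with thousands of labels.
* The ARFF dialect reader auto-detects tree-path versus child/parent
  class declarations by path-consistency; pathological vocabularies can
  fool the heuristic, so an explicit `hierarchy_format` override is
  provided.
* Alternate-ID maps are applied to a fixed point with a cycle guard;
  genuinely cyclic synonym tables are refused rather than resolved.
* `run_standard_eval()` / `run_cross_version_eval()` parallelize
  nothing; replicates are sequential and seeded for exact
  reproducibility.
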