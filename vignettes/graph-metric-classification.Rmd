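---
title: "Classifying chronic pain from connectome graph metrics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying chronic pain from connectome graph metrics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphmarker)
```

## The analysis in one paragraph

graphmarker implements a classification analysis for resting-state
functional connectomes: per-subject Pearson correlation matrices over
cortical parcels are Fisher-z transformed, proportionally thresholded
and binarized over a density grid, and summarized as four local graph
metrics per node (degree centrality DC, clustering coefficient CC,
betweenness centrality BC, local efficiency LE), averaged across
densities. The resulting subjects-by-features table feeds a feature
selector — a penalized logistic elastic net, optionally extended by an
optimal-subset wrapper ("Enet-subset") — and a linear support vector
machine evaluated under a repeated stratified 70/30 train/test
protocol. Significance of the classifier is assessed by label
permutation; univariate group differences per node are tested with
rank-sum statistics under Benjamini–Hochberg FDR control; and
per-feature selection frequencies identify the parcels that carry the
discrimination.

## Connectivity and graph metrics

Given a parcel-by-time series matrix, the off-diagonal connectivity is
$z_{ij} = \operatorname{atanh}(r_{ij})$ with $r$ clipped to
$(-1+10^{-12},\,1-10^{-12})$; the diagonal is excluded everywhere
(self-connections are meaningless and atanh(1) is infinite).
Correlations are computed over the full concatenated series; per-run
matrices with averaging are deliberately out of scope (a
`concatenate`-style choice a user can emulate upstream).

Thresholding retains exactly $k = \operatorname{round}(d \cdot
N(N-1)/2)$ strongest edges by signed z (half-up rounding; most positive
first), with ties at the cutoff broken by ascending $(i,j)$
lexicographic edge index so results are identical across platforms.
Signed rather than absolute ranking follows the convention of keeping
the strongest positive couplings; it is the only thresholding the
package offers because the density grid (15%–30% in 2.5% steps, seven
densities) operates far from the negative tail in practice. Metrics per
density are:

* **DC**: binary degree, row sum of the adjacency.
* **CC**: $2 t_i / (k_i (k_i - 1))$, the fraction of a node's neighbor
  pairs that are themselves connected; 0 when $k_i < 2$.
* **BC**: unnormalized shortest-path betweenness with each unordered
  pair counted once (Brandes-style accumulation via igraph); pairs in
  different components contribute 0. Normalization is monotone at fixed
  $N$ and therefore irrelevant to ranking-based downstream use.
* **LE**: the global efficiency of the subgraph induced on the node's
  neighbors — the mean of inverse shortest-path lengths over neighbor
  pairs, with unreachable pairs contributing 0 and LE = 0 when
  $k_i < 2$. Distances here are constrained to the induced neighborhood
  subgraph; paths that detour through non-neighbors do not count. This
  is why local efficiency is computed in-package (a level-synchronous
  BFS per neighborhood) while DC/CC/BC are delegated to igraph, whose
  conventions match the contracts above exactly (verified against
  brute-force enumeration in the test suite).

Per-node metrics are arithmetic means over the seven densities.

## Feature selection

The elastic net is fitted as a penalized **logistic** regression (the
outcome is a binary group) over a grid of penalty strengths
$\lambda \in \{0.1, \dots, 0.9\}$ and mixing weights $\alpha \in
\{0.0001, 0.0011, \dots, 0.0041\}$. The mixing grid sits close to
ridge: correlated parcels share coefficients and only clearly
non-contributing features are zeroed, so the selected set is large
(typically most features survive) — the selector's job at this stage is
ranking more than pruning. The winning grid point maximizes 4-fold
cross-validated AUC on the training split, with ties resolved toward
the larger penalty and then the smaller mixing weight (parsimony).
Grid points whose full-data fit retains no features are never eligible
winners, and if every grid point zeroes everything the run fails with
advice to widen the grids.

**Enet-subset** re-ranks the selected features by descending absolute
coefficient (computed once, never refitted per subset), then scores
growing prefixes of the ranking — sizes 25, 50, 75, ... capped at the
nonzero count, with the full nonzero set always evaluated — by the
nested 4-fold cross-validated AUC of a cost-1 linear SVM inside the
training split. The subset with maximal AUC wins; ties go to the
smaller subset. The chosen subset is therefore always contained in the
elastic-net selection, and its size is at most the elastic-net count.

## Classification protocol

Each protocol iteration draws a stratified split placing
`round(0.7 * class size)` subjects of each group in training, runs
feature selection **on the training rows only**, standardizes features
by training-set statistics, tunes the SVM cost over 1–10 by stratified
4-fold cross-validation repeated 5 times (selection by accuracy; an
AUC criterion is config-exposed), refits at the best cost, and
evaluates on the held-out split: confusion counts with controls as the
positive class, accuracy, sensitivity, specificity, and AUC from the
decision values by the midrank statistic. One hundred iterations are
averaged by default; iteration $i$ derives its seed as `seed + i`, so
the full report is reproducible from a single integer.

Permutation significance shuffles the labels once per permutation and
re-runs the entire protocol — feature selection included, since leaving
selection outside the null would bias p-values optimistically. The
p-value is the add-one estimator $(1 + \#\{null \ge obs\})/(1 + B)$,
never exactly zero. Because a full-iteration protocol per permutation
is rarely affordable, the per-permutation iteration count can be
reduced (it is logged when it is); under the null this widens the null
distribution relative to the observed average and makes the test
conservative, which the calibration tests account for.

## Univariate statistics

Per (node, metric), a two-sided rank-sum test with midranks compares
the groups: the exact Mann–Whitney distribution when both groups have
fewer than 10 subjects and there are no ties, otherwise a
continuity-corrected normal approximation with tie-corrected variance.
Benjamini–Hochberg adjustment is applied jointly across nodes and
metrics by default (a per-metric family is exposed); significance is
declared at q < 0.05. Pearson correlations relate the metrics of
frequently selected parcels to disability scores; in a two-group
design these should be computed within the patient group, since pooling
groups manufactures correlation out of the group separation itself.

## The synthetic cohort model

No empirical connectome data ships with the package, so a generator
provides cohorts with the structure the analysis assumes. A base
correlation matrix with random community structure (compound-symmetric
blocks over a weak global background plus a low-rank random component)
is shared by both groups; in the patient group the off-diagonal
covariances of a chosen set of "affected" nodes are attenuated by
$1/(1 + \text{effect\_size})$ and the matrix is re-projected to the
nearest positive-definite matrix by eigenvalue clipping at a small
floor. `effect_size = 0` therefore yields an exactly null cohort, and
growing values progressively disconnect the affected parcels — the
group difference enters at the covariance level so that graph-metric
differences arise mechanistically, exercising every downstream stage.
Subject series are zero-mean correlated Gaussian draws plus independent
observation noise; there is no autocorrelation or hemodynamic model,
which is immaterial for Pearson-correlation consumers but means the
generator says nothing about temporal confounds in real data. The
"affected nodes" construct is the generator's own ground-truth device
and is labeled as such in its outputs.

Defaults were fixed once at study-like values: 27 controls vs 24
patients, 360 parcels, 2,250 timepoints (six 5-minute runs at a 0.8 s
repetition time), 36 affected nodes (10% of parcels), effect size 1.0,
and unit observation noise (which roughly halves raw correlations).
Disability scores are drawn from group-specific normals truncated to
the instrument's 0–100 range, with the location moment-matched so the
truncated mean equals the requested group mean (5.63 ± 5.60 for
controls, 33.3 ± 15.3 for patients); without the matching, truncation
at 0 would inflate the control mean by about 1.6 points.

One property of the defaults worth knowing: at the full series length
the sampling error of a correlation is tiny (roughly
$1/\sqrt{2250} \approx 0.02$), so the default attenuation moves
within-community edges by several standard errors each and a 360-node
cohort is close to perfectly separable — the full-scale reproduction
run reports near-ceiling accuracy and many FDR-significant nodes. The
partially-separable regime, where selection and calibration behavior
are actually informative, is the short-series, few-node setting the
test suite uses.

What passing tests on these cohorts do show: the pipeline recovers
covariance-level group structure, its null calibration is honest, and
the subset selector behaves as designed. What they cannot show:
performance on real connectomes, where autocorrelation, motion,
site effects and physiological noise shape the correlation structure.

## Numerical choices and edge cases

* Correlations are clipped before atanh; perfectly correlated series
  yield a large finite z rather than infinity.
* Constant node series, NaN inputs, empty parcels, duplicate subject
  ids, out-of-range disability scores, and degenerate densities
  (retaining zero edges) all fail fast with named diagnostics.
* Zero-variance features on a training split are dropped with a
  warning; an all-constant table is an error.
* All tie-breaks are deterministic: thresholding by lexicographic edge
  index, grid winners by larger penalty then smaller mixing weight,
  cost by smaller value, subsets by smaller size.
* One-class test sets report the metrics that remain defined and an
  `NA` AUC.

## Worked example

A small cohort end-to-end (sizes reduced for the vignette):

```{r example, eval = FALSE}
cohort <- cohort_spec(n_hc = 25, n_lbp = 25, n_nodes = 60,
                      n_timepoints = 200, n_affected = 8,
                      effect_size = 2, seed = 11) |>
  generate_cohort() |>
  generate_disability_scores(seed = 11)

metric_tbl <- cohort |> cohort_fc() |> compute_node_metrics()
ft <- feature_table(metric_tbl, cohort$subjects, metrics = c("BC", "CC", "DC"))

report <- run_protocol(ft, "enet_subset",
                       eval_config(n_iterations = 25, seed = 1))
glance(report)
autoplot(report)
plot_selection_frequency(report, 20)
```

## Problem sizes used by the shipped checks

The package's own verification runs at reduced, stated sizes chosen as
a deliberate design point: 60-node cohorts of 50 subjects with 200
timepoints for calibration (20 replicate null cohorts, 25 protocol
iterations, 200 permutations at one iteration each) and signal
recovery (8 affected nodes, effect size 2, 5 replicate cohorts); the
calibration protocol fixes the SVM cost at 1, which removes the
cost-grid cross-validation without changing the split/select/evaluate
structure. The reproduction script (`scripts/acceptance.R`) instead
runs the full-size cohort (360 nodes, 51 subjects, 2,250 timepoints)
with the complete cost grid and 30 protocol iterations per selector.

## Known limitations

* Binary, undirected graphs only; no weighted metric variants, no
  global metrics, and no alternative selectors beyond the elastic-net
  family (a lasso comparison is a degenerate `alpha_grid = 1` call).
* The permutation null at reduced per-permutation iterations is
  conservative, not exact.
* The generator's Gaussian series lack temporal structure, and its
  group effect is a single attenuation mechanism; real cohorts may
  differ in both respects.
* Parcel identities are opaque integer ids; anatomical naming is a
  presentation concern outside the package.
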