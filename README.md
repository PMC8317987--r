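# graphmarker

Graph-theoretic biomarkers from resting-state functional connectomes,
with hybrid elastic-net / optimal-subset feature selection and a
repeated SVM evaluation protocol.

## What problem this addresses

Chronic pain conditions such as low back pain reorganize cortical
functional connectivity, but the signal is multivariate and weak at the
single-region level: univariate node tests routinely find nothing after
FDR correction while a classifier trained on the same features
separates patients from controls well. graphmarker packages that whole
analysis for researchers working with parcellated resting-state fMRI:
from parcel time series to a significance-tested classification report
and a ranking of the cortical regions that carry the discrimination.

The pipeline:

1. **Connectivity** — per subject, Pearson correlations between parcel
   time series, Fisher-z transformed: `z_ij = atanh(r_ij)`, diagonal
   excluded.
2. **Graph metrics** — threshold each matrix to the top *d* fraction of
   edges for *d* ∈ {15%, 17.5%, ..., 30%}, binarize, and compute per
   node: degree centrality (DC), clustering coefficient (CC),
   betweenness centrality (BC), and local efficiency (LE); average each
   metric across the seven densities.
3. **Feature selection** — elastic-net penalized logistic regression
   over a (λ, α) grid picked by cross-validated AUC; optionally the
   **Enet-subset** extension: rank the selected features by
   |coefficient| and keep the top-k prefix (k = 25, 50, ...) with the
   best nested cross-validated SVM AUC.
4. **Classification** — linear SVM, cost tuned over 1–10 by 4-fold
   cross-validation repeated 5 times, evaluated on stratified 70/30
   splits repeated 100 times; accuracy, sensitivity, specificity
   (controls positive) and rank-statistic AUC are averaged across
   iterations.
5. **Statistics** — permutation-test significance of the classifier
   (labels shuffled, the whole pipeline re-run, add-one p-value);
   per-node rank-sum tests with Benjamini–Hochberg FDR; Pearson
   correlation of frequently selected features with disability scores.

Because no empirical cohort ships with the package, a synthetic-cohort
generator produces two-group parcel time series whose covariance
differs at a controllable set of "affected" nodes, with ground truth
attached — every stage is testable end-to-end offline.

## Worked example

```r
library(graphmarker)

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
#> # A tibble: 1 × 6
#>   n_iterations mean_accuracy mean_auc mean_sensitivity mean_specificity mean_feature_count
#>          <int>         <dbl>    <dbl>            <dbl>            <dbl>              <dbl>
#> 1           25         0.954    0.996            0.989             0.92                 76
```

Read: across 25 random 70/30 splits of this 50-subject synthetic
cohort, the Enet-subset-selected SVM classified held-out subjects with
95.4% mean accuracy and 0.996 mean AUC, using on average 76 of the 180
available features. `tidy(report)` returns the per-iteration rows,
`top_selected_features(report, 60)` the most frequently selected
(node, metric) features, and `autoplot(report)` /
`plot_selection_frequency(report)` the standard figures.

`run_pipeline(pipeline_config(cohort = cohort, out_dir = "run1"))`
executes every stage and writes the metric table, selection result,
evaluation report, node tests, permutation summary, frequency table,
config echo and log as delimited text / JSON.

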