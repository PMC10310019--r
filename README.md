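# gutbrainmst

Diet shapes both the gut microbiota and the developing brain. This package
implements an analysis pipeline for asking whether children's animal
**protein and lipid intake** is associated with the **connectivity** of two
very different biological networks measured in the same cohort:

- a **brain cortex activity (BCA) network**, whose five nodes are qEEG
  regions of interest (left/right anterior, left/right posterior, midline)
  and whose edge weights are bias-corrected mutual information (MI) between
  ROI log band powers across the subjects of an intake group, and
- a **gut microbiota (GM) network**, whose nodes are 16S amplicon sequence
  variants (ASVs) and whose edge weights come from a probabilistic
  (hypergeometric) co-occurrence model of presence–absence across the
  group's samples.

Both networks are summarised by the same statistic: the **total weight of
the minimum spanning tree (MST)**,

```
W(T*) = min over spanning trees T of sum_{(i,j) in T} w_ij ,
```

a scale-robust measure of the network's critical backbone of information
flow. Groups are compared by the percent difference
`100 * (W_high - W_low) / W_high`, and a random-subnetwork null model
(repeatedly splitting the cohort into groups of sizes *n* and *m* and
recomputing the statistic) locates the observed difference in the
distribution expected by chance.

The package is aimed at researchers analysing paired
diet/EEG/16S data in small cohorts, and at anyone who wants a tested,
reproducible implementation of the MST-connectivity comparison. Because the
original study's raw recordings are not redistributable, a first-class
synthetic-data module generates EEG, ASV tables and food-frequency records
with controllable planted group effects, so every stage of the pipeline is
testable end to end.

## What is in the box

| Stage | Functions |
|---|---|
| Food-frequency intake | `compute_monthly_intake()`, `mean_split()`, `welch_t()`, `group_overlap()`, `group_compare()` |
| qEEG band power | `bandpass()`, `epoch_and_reject()`, `band_power()`, `roi_log_power()`, `bandpower_table()` |
| MI network | `bcmi()`, `mi_matrix()`, `mi_mst()` |
| MST statistic | `build_network()`, `minimum_spanning_tree()`, `mst_percent_difference()`, `random_split_null()` |
| Microbiota network | `rarefy_counts()`, `alpha_diversity()`, `gini_importance()`, `cooccur_weights()`, `gm_mst()` |
| Synthetic cohorts | `synthetic_config()`, `generate_eeg()`, `generate_asv_table()`, `generate_ffq()` |
| Orchestration | `run_all()` plus `tidy()`/`glance()`/`autoplot()` methods and `plot_*()` helpers |

All user-facing functions take data frames (or simple matrices where the
data are genuinely matrix-shaped) and return tibbles, so stages compose
with the pipe.

## Worked example

```r
library(gutbrainmst)

cfg <- synthetic_config(seed = 1, fs = 128, duration = 20)
run <- run_all(cfg, null_band = "alpha", null_condition = "open_eyes",
               null_k = 199, min_clean_seconds = 0)
run
#> <gutbrain_run: 31 children, nutrient split = protein>
#>   GM MST percent difference: 35.53%
#>   EEG MST percent difference (mean over bands): 96.00%

run$eeg_pct[run$eeg_pct$condition == "open_eyes", ]
#> # A tibble: 4 x 5
#>   band  condition     H       L percent_difference
#>   <chr> <chr>     <dbl>   <dbl>              <dbl>
#> 1 delta open_eyes 1.20   0.178                85.2
#> 2 theta open_eyes 0.757  0.0484               93.6
#> 3 alpha open_eyes 0.874  0.0628               92.8
#> 4 beta  open_eyes 0.390 -0.0130              103.

glance(run$null)
#> # A tibble: 1 x 5
#>   observed p_value     k     n     m
#>      <dbl>   <dbl> <dbl> <int> <int>
#> 1    0.811   0.045   199    11    20
```

Here the synthetic cohort has a planted effect (stronger inter-ROI coupling
and stronger ASV co-occurrence in the high-intake group), and the pipeline
recovers it: each band's high-group MST outweighs the low group's, the GM
MST of the smaller high-intake group is 35.5% heavier than the low-intake
group's despite that group having almost twice the samples, and the
random-split null puts the observed alpha-band difference at p = 0.045.
With `coupling_high = coupling_low` the percent differences collapse toward
zero and the observed difference lands inside the null's central mass.

Single stages work standalone, e.g. reproducing a Welch t test from
published group summaries:

```r
welch_t_summary(11, 407.48, 67.58, 20, 211.94, 59.25)$statistic
#> [1] 8.04538
```

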