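# dfcstates

Dynamic functional connectivity (dFC) state analysis for
region-of-interest (ROI) time series, in R.

Resting-state brain connectivity reorganises over the course of a scan:
the correlation structure among regional signals switches between a
small number of recurring **connectivity states**. Characterising those
states — how strongly connected they are, how much time each subject
spends in them, how long visits last, and how the topology of each
state's network differs between clinical groups — is a standard
analysis in clinical fMRI studies of chronic pain, psychiatric and
neurological conditions. dfcstates implements that analysis end to end
for anyone starting from extracted ROI time courses (one `T × N` table
per subject) plus a subject manifest with group labels and covariates.

## What it computes

1. **Sliding-window connectivity** — windows of width `w` TR stepped by
   `s` TR (defaults 30/1; `W = ⌊(T−w)/s⌋ + 1` windows), Pearson
   correlation per window, Fisher `z = artanh(r)` off-diagonal, and the
   dFC variability map (entrywise SD of z across windows).
2. **Connectivity states** — all subjects' windows pooled and clustered
   by true L1 (Manhattan) K-means: minimum-L1 assignment,
   coordinate-wise **median** centroid update, k-means++ seeding, best
   of 20 restarts. K is selected by the elbow criterion (maximal second
   difference of the cost curve over K = 2..8); a solution is valid only
   if every state holds ≥ 10 pooled windows; states are numbered by
   descending connectivity strength (state 1 = strongest).
3. **Temporal metrics** — per subject: fractional windows (FW), mean
   dwell time (MDT, window units), number of transitions.
4. **Graph metrics** — each subject's per-state mean network is
   binarized over a sparsity sweep (0.10–0.40, step 0.01); global
   efficiency, local efficiency and small-world σ = γ/λ against
   degree-preserving nulls, plus nodal efficiency, clustering, degree
   and betweenness; aggregated by area under the metric-vs-sparsity
   curve.
5. **Statistics** — Freedman–Lane covariate-adjusted permutation tests
   (age/gender; 5,000 permutations by default), Benjamini–Hochberg FDR,
   the network-based statistic (edge p < 0.001, component p < 0.05,
   1,000 permutations) for edge-level contrasts, Spearman partial
   correlations with clinical scores, and the usual demographics tests.
6. **Synthetic cohorts** — a seeded Markov-switching multivariate-normal
   generator with known ground-truth state sequences, used to validate
   every stage (state recovery, dwell/occupancy calibration, statistical
   calibration).

## Worked example

```r
library(dfcstates)

# a seeded synthetic three-group cohort: 12 subjects x 230 TP x 30 ROIs
run <- run_dfc_pipeline(dfc_config(n_perm = 500, run_graph_stats = FALSE,
                                   seed = 20240401))
print(run)
#> <dfc_run> 12 subjects, K = 3 (elbow-selected)
#> pooled windows per state: 968, 235, 1209

glance(run)
#> # A tibble: 1 × 7
#>   n_subjects n_windows selected_k min_state_windows all_states_valid total_cost
#>        <int>     <int>      <int>             <int> <lgl>                 <dbl>
#> 1         12      2412          3               235 TRUE                165925.
#> # i 1 more variable: seed <int>

head(run$temporal, 3)
#> # A tibble: 3 × 11
#>   subject_id group   age gender  fw_1  fw_2  fw_3 mdt_1 mdt_2 mdt_3
#>   <chr>      <chr> <dbl>  <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 HC_01      HC     47.9      0 0.731 0     0.269   147     0    54
#> 2 HC_02      HC     35.3      0 0.647 0.224 0.129   130    45    26
#> 3 HC_03      HC     41.9      0 0     0     1         0     0   201
#> # i 1 more variable: n_transitions <int>
```

The elbow selects **K = 3** states; state 1 is the strongly connected
modular pattern, state 2 the sparse pattern, state 3 the intermediate
pattern (ranking is by mean |centroid|). Each subject's row in
`run$temporal` gives the proportion of windows in each state (`fw_*`),
the mean dwell per visit in windows (`mdt_*`), and how often they
switched; `run$temporal_contrasts` holds the covariate-adjusted
permutation contrasts with FDR-adjusted p-values. `autoplot(run$elbow)`
and `autoplot(run)` draw the cost curve and the group-wise occupancy
boxplots.

With real data, replace the synthetic input by a manifest:

```r
cohort <- load_roi_tables("cohort/manifest.tsv")  # subject_id, group,
                                                  # age, gender, path
run <- run_dfc_pipeline(dfc_config(input = "cohort/manifest.tsv",
                                   seed = 1))
```

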