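---
title: "Dynamic functional connectivity state analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity state analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dfcstates)
```

## The analysis in one paragraph

Resting-state brain connectivity is not static: over a scan of a few
hundred volumes, the correlation structure among regional signals moves
through a small repertoire of recurring *connectivity states*. dfcstates
implements the standard sliding-window pipeline for characterising that
repertoire from region-of-interest (ROI) time series: windowed Pearson
correlation with Fisher z transformation, pooling of all subjects'
windows, Manhattan-distance K-means to identify states, per-subject
temporal metrics of the resulting state sequence, sparsity-thresholded
graph-theory metrics of each subject's per-state mean network, and
covariate-adjusted permutation inference on the group contrasts. Because
clinical resting-state cohorts are rarely shareable, the package also
ships a Markov-switching multivariate-normal cohort simulator with known
ground truth, which is what the test suite and the reproduction script
exercise.

## Sliding-window connectivity

Each subject contributes a $T \times N$ matrix of ROI time courses
(default protocol: $T = 230$ retained volumes, window width 30 TR, step
1 TR, giving $W = \lfloor (T - w)/s \rfloor + 1 = 201$ windows).
Windows are rectangular (boxcar): the protocol this package follows
names only a width and step, so no taper is applied. Within each
window we compute the $N \times N$ Pearson correlation matrix and apply
the Fisher transformation $z = \operatorname{artanh}(r)$ off-diagonal,
clipping $|r|$ at $1 - 10^{-7}$ so perfect correlations stay finite;
the diagonal is zeroed by convention. The entrywise standard deviation
of $z$ across windows (denominator $W-1$) is the dFC variability map.

Numerical edge cases are resolved deterministically: a zero-variance
ROI within a window gets correlation 0 to all others (with a warning)
rather than NaN; window indexing is 0-based half-open throughout.
Detrending of the input series is available behind a flag but off by
default — bandpass filtering and nuisance regression are treated as
upstream preprocessing, outside this package's scope.

## State clustering

All subjects' windows are pooled: each window becomes one row of a
feature matrix whose columns are the row-major strict upper triangle of
the z-matrix ($N(N-1)/2$ features). Clustering uses true L1 K-means:
assignment by minimum Manhattan distance and centroid update by the
coordinate-wise *median* (the L1-optimal centre) — a mean update under
L1 assignment would not be a descent method for the L1 objective. The
total cost is nonincreasing across iterations within a restart, which
the test suite asserts on every trace. Iteration stops at label
convergence; empty clusters are reseeded from the point farthest from
its assigned centroid.

Restarts are seeded k-means++ style under the L1 metric (first centroid
uniform, subsequent ones with probability proportional to distance from
the nearest chosen centroid); 20 restarts by default, best by total
cost. Uniform-random seeding is available (`init = "random"`) but finds
poor local optima often enough to make the cost-versus-K curve
non-monotone in practice, which destabilises elbow selection — that
observation is why ++ seeding is the default.

The number of states is chosen by the elbow criterion, read here as a
parameter-free rule: over candidate $K$ (default 2..8), select the
interior $K$ maximising the discrete second difference
$\mathrm{cost}(K-1) - 2\,\mathrm{cost}(K) + \mathrm{cost}(K+1)$, i.e.,
the point of largest curvature of the cost curve; ties go to the
smallest $K$. A partition is considered valid only when every state
holds at least 10 pooled windows — the pipeline aborts otherwise.
States are finally renumbered by descending mean absolute centroid
connectivity, so "state 1"/"state I" is always the most strongly
connected pattern, followed by the intermediate and sparse patterns.

Whether clustering should consume z-values or raw correlations is not
universally agreed; this package clusters z-values, matching the order
of operations of the windowing stage (correlate, transform, cluster).

## Temporal metrics

For each subject's ordered window labels we report, per state: the
fractional windows (FW, proportion of windows in the state), the mean
dwell time (MDT, mean length of maximal runs in window units;
boundary-truncated runs count; never-visited states contribute 0, not
NA — which is why group means of a rarely visited state can fall below
one window), and the total number of transitions. Two identities hold
by construction and are enforced in the tests:
$\sum_s \mathrm{MDT}_s \cdot \mathrm{runs}_s = W$ and
$\mathrm{transitions} = \mathrm{runs} - 1$. MDT is reported in window
units, with an optional TR-seconds column; FW is computed per subject
and compared across groups, not pooled.

## Graph metrics

Per subject and state, the mean z-matrix over that subject's windows in
the state is thresholded into binary undirected graphs over a sparsity
sweep (default 0.10–0.40 in steps of 0.01): at sparsity $s$, the
$\lfloor s\,N(N-1)/2 \rfloor$ largest-valued edges are kept. Ranking is
by signed value by default (negative edges are effectively excluded at
these sparsities), with absolute-value ranking behind a flag; ties at
the cutoff break deterministically by value then row-major edge index.

On each binary graph we compute global efficiency (mean inverse
shortest-path length over ordered pairs, $1/\infty = 0$), local
efficiency (mean over nodes of the global efficiency of the
neighbour-induced subgraph), nodal clustering
($2\,\mathrm{triangles}/k(k-1)$), degree, unnormalized betweenness
(Brandes accumulation; each unordered pair counted once), and
small-world coefficients $\gamma = C/C_{\mathrm{null}}$,
$\lambda = L/L_{\mathrm{null}}$, $\sigma = \gamma/\lambda$ against
degree-preserving rewired nulls (10×|E| swap attempts each).
Characteristic path length is the mean finite distance on the largest
connected component, avoiding infinities at sparse thresholds; the
component coverage is reported alongside. The igraph library provides
the graph engine; every metric is checked against independent
brute-force enumeration oracles in the test suite (exhaustively over
all labeled 4-node graphs, and over seeded random graphs up to 12
nodes).

Metrics are aggregated across the sweep by trapezoidal area under the
curve (AUC; a constant metric of 1 has AUC 0.30 over the default
range) before group testing. Whether such metrics should be computed
per window, per state-mean network, or per subject-mean network is
genuinely ambiguous in the field; this package's primary output is the
state-mean network reading, which keeps one network per subject and
state and makes the permutation tests straightforward.

## Group statistics

Group contrasts use Freedman–Lane style permutation: the outcome is
residualized on an intercept plus covariates (age, gender), the
statistic is the difference of group means of residuals, and the null
is built by permuting the residuals (5,000 permutations by default,
two-sided add-one p-values, so $p \ge 1/(n_{\mathrm{perm}}+1)$).
Residual permutation is the standard way to honour nuisance covariates
in a permutation framework when only "with age and gender as
covariates" is specified. Multiple comparisons are corrected by
Benjamini–Hochberg FDR within explicit families (all states × pairwise
contrasts of one metric kind for temporal metrics; all nodes within one
metric/state/contrast for nodal metrics); the family definition is
recorded in the output. The three-group design is tested pairwise with
FDR rather than omnibus-then-pairwise; both readings are defensible and
the pairwise one matches how such results are typically reported.

Edge-level network contrasts use the network-based statistic: each
edge's two-sample t statistic on covariate-adjusted values is converted
to a parametric p and thresholded (default edge $p < 0.001$); connected
components of suprathreshold edges are the candidate effects, and their
familywise-corrected p comes from a permutation null of the maximum
component size (default 1,000 iterations, one shared permutation
schedule across edges). The primary threshold is parametric by design:
a permutation-estimated edge p cannot fall below
$1/(n_{\mathrm{iter}}+1)$, so thresholds as strict as 0.001 would be
unattainable at practical iteration counts.

Clinical correlations use Spearman partial correlation — rank
transform, residualize both variables on the covariates, Pearson
correlation of residuals, t-distribution p with
$n - 2 - \#\mathrm{covariates}$ degrees of freedom — and are labelled
exploratory (uncorrected p). Cohort description uses the conventional
Kruskal–Wallis (age), chi-square without continuity correction
(gender), and Mann–Whitney U (clinical score) tests via their stats
implementations.

## The synthetic cohort generator

No public dataset accompanies the clinical protocol this pipeline
targets, so validation runs on simulated cohorts with known ground
truth. The generative model is a Markov-switching multivariate normal:
a latent state sequence evolves at the *time-point* level (not the
window level, so windows near switches are genuinely mixed — the
clustering must tolerate them), and each time point is drawn zero-mean
with its state's covariance.

The default configuration, chosen once as the package's study
conditions:

* 30 ROIs, 3 states. State 1: three within-module blocks at correlation
  0.7 with between-module anticorrelation −0.2 (strong, modular);
  state 2: uniform 0.05 (sparse); state 3: a different two-block layout
  at 0.5 with −0.1 between (intermediate strength, distinct pattern).
  Anticorrelated modules are a realistic feature of resting-state
  connectivity and keep the intermediate state geometrically distinct
  rather than merely "between" the other two. Mean absolute
  off-diagonal strength ranks 1 > 3 > 2.
* A reversible transition matrix with stationary occupancy
  (0.365, 0.572, 0.063) and mean dwell times (100, 135, 35) time
  points. The occupancy split mirrors the strong/sparse/intermediate
  prevalence typical of three-state solutions (roughly 36/57/6 percent);
  the short-dwell rare state makes its visits frequent enough to appear
  in every 12-subject cohort while keeping its overall share at ~6%.
* 12 subjects (4 per group analogue) × 230 time points for desk-scale
  runs; group specs scale to larger designs (e.g., 27/37/18). The
  patient-analogue group inflates the self-transition of state 3 and
  perturbs one node's connectivity in state 1, emulating longer dwell /
  higher occupancy of the intermediate state and a nodal centrality
  shift.
* Age is normal, clipped to 30–80 years; gender is Bernoulli. Subject
  seeds derive deterministically from the master seed; regeneration is
  byte-identical at the file level.

What the simulator does *not* emulate: hemodynamic convolution,
scanner noise spectra, head motion, physiological confounds, spatial
structure within ROIs, or any voxel-level process. Passing tests on
synthetic cohorts therefore demonstrate correctness of the pipeline's
computations and its ability to recover planted dynamics of this kind —
not robustness to the full noise structure of real fMRI.

```{r, fig.width = 6, fig.height = 3.5, eval = FALSE}
# a desk-scale end-to-end run (about a minute of compute)
run <- run_dfc_pipeline(dfc_config(n_perm = 500, run_graph_stats = FALSE,
                                   seed = 20240401))
autoplot(run$elbow)
autoplot(run)
```

## Problem sizes and determinism

The package's own validation runs use deliberately modest sizes: the
default synthetic cohort is 12 × 230 × 30 (2,412 pooled windows, 435
features), permutation calibration uses 500–1,000 permutations per
test, and NBS recovery studies use 200-iteration nulls on 12-node
networks. These sizes make the full suite reproducible on a laptop
while leaving every algorithmic path identical to a full-scale run
(5,000 permutations, 116 ROIs) — only counts change, not code.

Every stochastic step takes an explicit integer seed; a single master
seed fans out per-stage and per-subject seeds through one documented
derivation, so independent stages have independent streams and any
stage can be re-run bit-identically. K-means ties (equal distances,
equal strengths) and threshold ties all break by fixed deterministic
rules rather than platform order.

## Known limitations

* The elbow rule is one reading of "elbow criterion"; a
  distortion-ratio alternative would occasionally choose differently on
  flat curves.
* MDT in window units inherits the window-overlap autocorrelation of
  step-1 sliding windows; dwell times are not independent samples.
* Graph metrics are binary-graph metrics only; weighted variants,
  modularity and rich-club analyses are out of scope.
* The local-efficiency of a thresholded graph is not monotone in
  sparsity (neighbour sets change as edges are added), so only global
  efficiency carries a monotonicity guarantee across nested thresholds.
* With 12-subject desk-scale cohorts the group-contrast stage has
  little power; it demonstrates machinery, not effect detection, at
  that size.
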