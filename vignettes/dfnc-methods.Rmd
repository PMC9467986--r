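---
title: "Dynamic connectivity states: models, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states: models, choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dynconn)
```

## The analysis in one paragraph

Resting-state component time courses (one matrix per subject, time by
components, typically 23 components over 230 time points at TR = 2 s) are
scanned with a sliding window of 50 TRs stepping by 1 TR. In each window a
tapered sample covariance is regularized by the graphical LASSO, converted
to a correlation matrix, and Fisher-z transformed: the window's functional
network connectivity (FNC) matrix. All subjects' windows, vectorized to
their 253 unique edges, are pooled and clustered by K-means
(squared-Euclidean, best of many k-means++ restarts) into recurring
connectivity states. Per subject, the state sequence yields mean dwell time
(DT), fraction time (FT), and the number of transitions (NT). Groups are
compared edge-by-edge within each state (two-sample t, per-state
Benjamini-Hochberg FDR over the 253 edges) and on the dynamics metrics.
Finally, a per-state SVM with F-score feature ranking, LOOCV grid search
over (N, C, gamma), and a label-permutation test asks whether a subject's
per-state connectivity predicts group membership — here, suicidality level
in depression (healthy controls HC and patient groups NS / SI / SA: no
risk, suicidal ideation, suicide attempt).

## The generative model behind the synthetic cohort

Every stage is testable without scan data because the package carries its
own generator. A cohort design fixes, per group, a K-state Markov chain
(row-stochastic transition matrix; the initial state is drawn from the
chain's stationary distribution) and a set of K symmetric positive-definite
state covariances with unit diagonal. At each time point the observation is
a zero-mean Gaussian draw with the current state's covariance (plus any
group-specific additive edge perturbation), plus isotropic Gaussian noise;
each component is standardized to zero mean and unit variance before
export, mirroring z-scored IC time courses. There is no haemodynamic
convolution: the analysis operates on component time courses and estimates
covariance structure, so a covariance-faithful emission model is the
minimal model that exercises every downstream contract.

Defaults follow the reference study conditions: C = 23, T = 230, TR = 2 s,
K = 6 states, groups HC/NS/SI/SA of 38/48/74/51 subjects. The planted group
contrasts sit where the clinical findings sit: the SA chain dwells longer
in weakly connected state 4 (stay probability 0.96 vs 0.90) and shorter in
strongly connected state 5 (0.78), the NS chain dwells longer in state 6,
and SA carries additive hypoconnectivity (delta = -0.25) on five designated
state-4 edges. Baseline stay probability 0.90 gives mean dwell times of
about 10 TRs (20 s), a realistic resting-state scale. The observation
noise default (`noise_sd = 1`, equal to the signal's unit scale) halves
every observed correlation — deliberately conservative.

What the generator does **not** emulate: scanner drift, head motion,
physiological confounds, spatial structure (the voxel generator is a plain
linear mixing model), and haemodynamic smoothing. Passing tests therefore
certify the estimation and inference machinery under the model the methods
themselves assume — not robustness to fMRI artifacts.

### Two regimes: realistic vs. benchmark

With 20-second dwell times, a 100-second window inevitably straddles
several state visits; a large share of windows are blends, and no windowed
method can assign them cleanly — in particular, a visit shorter than half
the window can never win the majority of any window, so windowed
assignment has a hard visibility floor near w/2 TRs. Recovery contracts
therefore use `benchmark_block_spec()` designs: one strong block per state
(within-block correlation 0.8), making the K centroids mutually
equidistant and far apart relative to window estimation noise. Elbow
selection and window-label agreement additionally use degenerate
one-state-per-subject chains (every window pure, occupancy balanced);
dwell-time sign recovery uses a two-state switching cohort whose group
dwell times (33 vs 100 TRs) both clear the visibility floor. The
realistic default regime remains the reference condition for everything
that does not require unambiguous window-level ground truth. All regimes
are first-class cohort designs; tests state which they use.

## Numerical and algorithmic choices

**Windowing.** Windows start at 0, step, 2·step, ... and a start at
exactly T − w is excluded, reproducing the printed 180 windows for
T = 230, w = 50, step = 1. The taper defaults to rectangular; a Gaussian
convolved rectangle (sigma = 3 TR) is available in `dfnc_params()`.

**Graphical LASSO.** Implemented as block coordinate descent over columns
with a coordinate-descent lasso inner solve; only precision off-diagonals
are penalized, so the lambda = 0 limit returns the sample correlation
exactly and the 2-by-2 case has a soft-thresholding closed form the tests
pin down. Short windows (w = 50) against C = 23 components are exactly the
regime where this shrinkage beats the raw sample correlation, and a test
verifies that inequality on planted covariances. Lambda defaults to 0.1 per
subject; `lambda = "cv"` selects it by held-out Gaussian log-likelihood
over ten evenly spaced windows split into folds, a single lambda per
subject (bounded compute, deterministic given the seed).

**Fisher z.** Correlations are clipped at |r| = 1 − 1e−7 before atanh to
keep perfectly correlated degenerate windows finite. Components with zero
variance inside a window are flagged and their correlations set to 0 with
a warning rather than an error, keeping batch runs alive and auditable.

**K-means.** Replicates are seeded k-means++ from a documented RNG stream
and refined by Lloyd iterations; the lowest within-cluster sum of squares
wins, ties prefer the earlier replicate, and the final assignment is the
deterministic nearest-centroid rule with ties to the lowest state index.
States are relabeled in decreasing occupancy order. The reference analysis
uses 500 restarts; tests use 8–50, which suffices at their problem sizes
(a test asserts best-of-replicates WCSS is monotone in the budget).

**Choosing k.** The within/between validity index is computed for every
candidate k and returned for audit, but the elbow is detected on the
normalized within-cluster dispersion (wcss/totss): for well-separated
equal-occupancy states that curve falls linearly until the true k and then
flattens, so its discrete second difference spikes exactly there, whereas
the within/between *ratio* is convexified by its growing denominator and
its maximum curvature always sits at the left end of the k-range — it
cannot select an interior k even in the ideal case. An elbow must be at
least `elbow_strength` (default 3) times sharper than the runner-up
curvature; isotropic blobs measure about 1–1.5 and raise an error advising
manual k. This is one defensible operationalization of an under-specified
step; `kmeans_states()` accepts an explicit k to bypass it.

**Dynamics metrics.** DT is the mean length of maximal runs, in windows
(multiply by step × TR for seconds); FT sums to 1 across states; NT counts
adjacent unequal pairs. DT is undefined (NA) for states never entered.

**Group statistics.** Equal-variance two-sample t by default (Welch
selectable). The FDR family is the 253 edges within one state — correction
is per state, not pooled — and each pairwise comparison carries its own
family. For the dynamics metrics, DT and FT are tested per state (DT only
over subjects who entered) and NT once per subject, FDR over that
comparison's whole metric family.

**Classifier.** The SVM defaults to an RBF kernel with C, gamma in
2^{−5..5}, honoring the tuned "kernel width" in the protocol even though
the reference text also says "linear SVM"; a linear mode is available and
is what the weight maps use exactly (w = coefs' SV). `leakage_mode`
defaults to `"nested"` — F-scores recomputed inside each training fold —
because scoring features on the full sample before LOOCV leaks labels;
`"full_sample"` reproduces the described procedure, and a test
demonstrates its optimism on null data. Model-selection ties prefer
smaller N, then smaller C, then smaller gamma. The reported LOOCV accuracy
is the selected maximum over the grid and is therefore optimistically
biased on null data; the permutation test (full re-run of selection and
search per permuted label set, add-one p estimator) is the calibrated
significance measure. AUC is the rank statistic over pooled LOOCV decision
values (ties count one half) and the cut-off is the Youden-optimal pooled
decision threshold — one defensible reading of an under-specified step.
Per-state classification requires at least three entered subjects per
group (leave-one-out must keep two same-class training subjects).

**Decomposition.** The pipeline consumes pre-extracted time courses;
the decomposition module exists for completeness and is exercised on
synthetic voxel fixtures (linear mixing, super-Gaussian spatial maps).
Infomax uses the natural gradient with a logistic nonlinearity,
learning-rate annealing on gradient-direction reversals, and
divergence-triggered restarts at halved rates; reaching `max_iter`
returns the current solution with `converged = FALSE` rather than
failing. Stability resampling clusters components from repeated runs by
absolute correlation with average linkage — a simplification of ICASSO's
similarity machinery — and scores each cluster by mean intra- minus mean
extra-cluster similarity. Noise screening uses the periodogram power
below vs. above a 0.1 Hz split; the threshold, split, and subject-level
PCA dimension are configuration, not asserted constants, because the
reference analysis does not state them.

**Seeds.** Every randomized stage takes a seed; cohort, replicate,
permutation, and run seeds are derived from it by a fixed integer hash so
streams are decoupled and every result is bit-reproducible.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own trade-off between statistical resolution and
a test suite that runs in minutes: recovery cohorts of 16–18 subjects
(C = 23, T = 230), a two-state dwell-contrast cohort of 12 + 12, 500 null replicates
for FDR calibration at m = 253 edges and n = 15 + 15, BH oracle checks on
1000 random p-vectors, classifier calibration at n = 40 / m = 50 (chance
level, 10 seeds), n = 16 / m = 12 with 19 permutations (p uniformity,
60 seeds), and a planted-effect scenario with 5 elevated edges among 66 at
n = 15 + 15. The generator defaults themselves stay at the full study
conditions.

## Known limitations

- Windowed estimation cannot resolve states whose dwell times are shorter
  than the window; blended windows are assigned to the nearest centroid.
- The elbow criterion needs a genuinely separated state geometry; on
  gradual curves it deliberately refuses to choose.
- The permutation test re-runs the full search and is the compute
  bottleneck; `permutation_mode = "fixed"` is cheaper but slightly
  anti-conservative.
- Edgewise inference assumes exchangeable subjects within group; no
  covariate adjustment is provided.
- The decomposition module is validated on linear synthetic mixtures only,
  and component-to-network labeling is the user's responsibility (a label
  map can be supplied to the reporting helpers).
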