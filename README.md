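# dynconn

Dynamic functional network connectivity (dFNC) asks how the correlation
structure between brain networks reorganizes over minutes of resting-state
recording, rather than averaging it away. `dynconn` implements a complete,
tested dFNC pipeline for component time courses — the kind of data produced
by group ICA of resting-state fMRI — aimed at studies that relate
connectivity dynamics to clinical group membership, such as stratifying
depressed patients by suicide risk (healthy controls HC and patient groups
NS / SI / SA: no risk, suicidal ideation, suicide attempt).

The pipeline, end to end:

1. **Decomposition** (optional; the pipeline consumes time courses
   directly): two-stage PCA, natural-gradient Infomax ICA with stability
   resampling, back-reconstruction of subject time courses, and
   low/high-frequency noise screening.
2. **Windowed connectivity**: sliding windows of *w* = 50 TRs, step 1 TR
   (180 windows for *T* = 230); per window a tapered covariance is
   regularized by the graphical LASSO (L1-penalized inverse covariance,
   solved by block coordinate descent), converted to correlation, and
   Fisher-z transformed. With *C* = 23 components each window vectorizes
   to *C*(*C* − 1)/2 = 253 edges.
3. **Connectivity states**: all subjects' windows pooled and clustered by
   best-of-replicates K-means (squared Euclidean, k-means++ seeding); the
   number of states is chosen by an elbow criterion on the dispersion
   curve, and per subject the assignment sequence yields mean dwell time
   (DT), fraction time (FT), and number of transitions (NT).
4. **Group statistics**: per-state edgewise two-sample t-tests with
   Benjamini–Hochberg FDR over each state's 253 edges, plus tests on
   DT / FT / NT.
5. **Classification**: per state and group pair, F-score feature ranking,
   leave-one-out cross-validated grid search over the subset size *N* and
   SVM hyperparameters (C, γ), rank-statistic AUC, and a label-permutation
   test of the selected accuracy.

A synthetic cohort generator (hidden-Markov state switching over planted
SPD covariance states, with group-specific transition matrices and edge
perturbations) provides ground truth for every stage, so the whole
pipeline is verifiable without scan data.

## Worked example

```r
library(dynconn)

design  <- suicidality_design(n_per_group = c(HC = 6, SA = 6), C = 10,
                              T = 230, seed = 7)
cohort  <- simulate_cohort(design)
fnc     <- cohort_dfnc(cohort$time_courses,
                       dfnc_params(window_length = 50, lambda = 0.1))
model   <- kmeans_states(fnc, k = 6, n_replicates = 20, seed = 7)
glance(model)
#> # A tibble: 1 × 7
#>       k n_windows n_subjects  wcss totss n_replicates  seed
#>   <dbl>     <int>      <int> <dbl> <dbl>        <dbl> <dbl>
#> 1     6      2160         12  544.  672.           20     7
```

Each of the 12 subjects contributes 180 windows; six centroids absorb
about a fifth of the pooled dispersion at this small demo scale. Dwell
times and occupancies per subject:

```r
dynamics <- cohort_dynamics(model, cohort$manifest)
head(dynamics, 4)
#> # A tibble: 4 × 7
#>   subject_id group state dwell_time fraction_time entered n_transitions
#>   <chr>      <chr> <int>      <dbl>         <dbl> <lgl>           <int>
#> 1 sub-001    HC        1       27.5       0.306   TRUE                5
#> 2 sub-001    HC        2       41.3       0.689   TRUE                5
#> 3 sub-001    HC        3        1         0.00556 TRUE                5
#> 4 sub-001    HC        4       NA         0       FALSE               5
```

Subject `sub-001` splits its run between states 1 and 2 (mean runs of 27.5
and 41.3 windows), never enters state 4, and switches five times. How many
subjects of each group enter each state:

```r
state_membership_table(model, cohort$manifest) |>
  tidyr::pivot_wider(names_from = state, values_from = n_entered)
#> # A tibble: 2 × 7
#>   group   `1`   `2`   `3`   `4`   `5`   `6`
#> 1 HC        6     4     5     4     2     2
#> 2 SA        6     5     4     4     5     1
```

Per-state classification (linear kernel, permutation test with 49
shuffles) uses only the subjects who entered the state:

```r
sfnc <- cohort_state_fnc(model, fnc, cohort$manifest)
cfg  <- classifier_config(kernel = "linear", C_grid = c(0.1, 1, 10),
                          gamma_grid = 0.1, N_grid = c(1, 3, 5, 10),
                          n_permutations = 49, seed = 7)
classify_all_states(sfnc, list(c("SA", "HC")), states = 1:2, config = cfg)
#>   state group_a group_b   n_a   n_b best_n accuracy    auc sensitivity
#> 1     1 SA      HC          6     6      5     25   0.0833       0
#> 2     2 SA      HC          5     4      1     55.6 0.4          0.6
```

At this demo scale, and in states where no group effect was planted, the
classifier sits at or below chance with non-significant permutation p —
exactly what a calibrated protocol should report. The planted effects of
the default design (SA hypoconnectivity and longer dwell in state 4,
shorter dwell in state 5) emerge at realistic cohort sizes; the test suite
exercises them under well-powered scenarios.

`run_pipeline()` chains all stages from one (YAML-able) config and writes
every table as tab-separated text with a provenance sidecar;
`inst/cli/dfnc-pipeline.R` is a thin command-line wrapper over it.

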