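# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small switching cohort: 2 groups x 5 subjects, C = 8, K = 3, with a
# planted dwell-time contrast (group B stickier in state 2) and a planted
# hypoconnectivity delta on one state-3 edge for group B.
small_cohort <- function() {
  cached("small_cohort", function() {
    covs <- make_state_covariances(8, 3, seed = 11)
    trans <- list(
      A = markov_transition(3, 0.9),
      B = markov_transition(3, 0.9, overrides = c("2" = 0.97))
    )
    pert <- tibble::tibble(group = "B", state = 3L, i = 1L, j = 2L,
                           delta = -0.3)
    design <- group_design(
      tibble::tibble(group = c("A", "B"), n = c(5, 5)),
      covs, trans, perturbations = pert,
      T = 150, TR = 2, noise_sd = 0.5, seed = 77
    )
    list(design = design, cohort = simulate_cohort(design), covs = covs)
  })
}

small_fnc <- function() {
  cached("small_fnc", function() {
    cohort_dfnc(small_cohort()$cohort$time_courses,
                dfnc_params(window_length = 40, step = 2, lambda = 0.05))
  })
}

small_model <- function() {
  cached("small_model", function() {
    kmeans_states(small_fnc(), k = 3, n_replicates = 10, seed = 5)
  })
}

# Pure balanced benchmark cohort: equidistant states, one-hot absorbing
# chains, used for unambiguous recovery checks.
pure_cohort <- function(C = 16, K = 4, n_per_state = 3, T = 150) {
  covs <- make_state_covariances(C, K,
                                 block_spec = benchmark_block_spec(C, K),
                                 seed = 9)
  onehot <- function(s) {
    P <- matrix(0, K, K)
    P[, s] <- 1
    P
  }
  trans <- setNames(lapply(seq_len(K), onehot), paste0("S", seq_len(K)))
  design <- group_design(
    tibble::tibble(group = paste0("S", seq_len(K)), n = n_per_state),
    covs, trans, T = T, TR = 2, noise_sd = 0.2, seed = 31
  )
  list(design = design, cohort = simulate_cohort(design), covs = covs)
}

# Brute-force BH step-up used as the independent multiple-testing oracle.
bh_stepup_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- alpha * seq_len(m) / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  sig <- logical(m)
  if (is.finite(k)) sig[o[seq_len(k)]] <- TRUE
  # adjusted values by the step-up recursion
  q <- numeric(m)
  q[m] <- ps[m] * m / m
  if (m >= 2) {
    for (i in (m - 1):1) q[i] <- min(q[i + 1], ps[i] * m / i)
  }
  list(significant = sig, q = q[order(o)])
}

# Pairwise-concordance AUC oracle (ties count one half).
auc_concordance_oracle <- function(dec_pos, dec_neg) {
  tot <- 0
  for (a in dec_pos) {
    for (b in dec_neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(dec_pos) * length(dec_neg))
}

# Match estimated states to planted ones by centroid correlation.
match_states <- function(centroids, planted_vectors) {
  cmat <- cor(t(centroids), planted_vectors)
  apply(cmat, 1, which.max)
}

planted_state_vectors <- function(covs) {
  sapply(seq_len(covs$K), function(s) {
    vectorize_fnc(atanh(pmin(pmax(
      cov2cor(covs$covariances[[s]]), -1 + 1e-7), 1 - 1e-7)) *
        ifelse(diag(covs$C) == 1, 0, 1))
  })
}
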