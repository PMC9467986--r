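#' Build a set of state covariance matrices with block structure
#'
#' Constructs `K` distinct symmetric positive-definite correlation-scale
#' matrices over `C` components. Components are partitioned into blocks
#' ("networks"); each state assigns its own within-block and between-block
#' connectivity strengths, emulating recurring connectivity states that range
#' from strongly connected (high within-network correlation) to weakly
#' connected (low correlation everywhere).
#'
#' Requested strengths that leave a matrix indefinite are repaired by
#' jitter-and-project: eigenvalues are floored at a small positive value and
#' the result is rescaled to unit diagonal. A request that cannot be repaired
#' (|strength| >= 1) fails, naming the offending state.
#'
#' @param C Number of components (>= 2).
#' @param K Number of states (>= 1).
#' @param block_spec A list of length `K`; element `s` is a list with fields
#'   `blocks` (list of integer vectors partitioning `1:C`), `within` (scalar
#'   or per-block within-block correlation), and `between` (scalar
#'   between-block correlation). Defaults to [default_block_spec()].
#' @param seed Integer seed for the small random jitter that keeps states
#'   distinct.
#' @return An object of class `state_covariances`: a list with `K`, `C`, and
#'   `covariances` (list of C x C unit-diagonal SPD matrices).
#' @examples
#' sc <- make_state_covariances(C = 10, K = 3, seed = 1)
#' sapply(sc$covariances, function(m) min(eigen(m, symmetric = TRUE)$values))
#' @export
make_state_covariances <- function(C, K, block_spec = default_block_spec(C, K),
                                   seed = 1L) {
  stopifnot(C >= 2, K >= 1, length(block_spec) == K)
  set.seed(seed)
  covs <- vector("list", K)
  for (s in seq_len(K)) {
    spec <- block_spec[[s]]
    blocks <- spec$blocks
    ids <- sort(unlist(blocks))
    if (!identical(ids, seq_len(C))) {
      abort(sprintf("block_spec for state %d does not partition 1:%d", s, C))
    }
    within <- rep_len(spec$within, length(blocks))
    between <- spec$between
    if (any(abs(c(within, between)) >= 1)) {
      abort(sprintf(
        "state %d requests |correlation| >= 1; not repairable", s
      ))
    }
    m <- matrix(between, C, C)
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      m[idx, idx] <- within[b]
    }
    # tiny asymmetric-free jitter keeps same-spec states distinguishable
    jit <- matrix(rnorm(C * C, sd = 0.02), C, C)
    m <- m + (jit + t(jit)) / 2
    diag(m) <- 1
    m <- repair_spd(m, state = s)
    covs[[s]] <- m
  }
  d <- outer(seq_len(K), seq_len(K), Vectorize(function(a, b) {
    if (a >= b) return(1) else norm(covs[[a]] - covs[[b]], "F")
  }))
  if (any(d <= 0)) abort("two states collapsed onto identical covariances")
  structure(list(K = K, C = C, covariances = covs),
            class = "state_covariances")
}

# Floor eigenvalues and rescale to unit diagonal; error if hopeless.
repair_spd <- function(m, state = NA, floor_ev = 1e-3, max_pass = 5) {
  for (i in seq_len(max_pass)) {
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    if (min(e$values) > 0 && max(abs(diag(m) - 1)) < 1e-12) {
      return((m + t(m)) / 2)
    }
    v <- pmax(e$values, floor_ev)
    m <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(m))
    m <- m / outer(d, d)
    diag(m) <- 1
  }
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0) {
    abort(sprintf("state %s: covariance not repairable to SPD", state))
  }
  (m + t(m)) / 2
}

#' Default block specification for synthetic states
#'
#' Splits the components into up to four equal blocks. Odd-numbered states
#' are "strongly connected" (high within-block correlation), even-numbered
#' states are "weakly connected" (low correlation among all blocks), with the
#' dominant block rotating across states so all `K` states are distinct.
#'
#' @inheritParams make_state_covariances
#' @return A list of length `K` suitable for `block_spec`.
#' @export
default_block_spec <- function(C, K) {
  n_blocks <- max(2L, min(4L, C %/% 2L))
  blocks <- split(seq_len(C), sort(rep_len(seq_len(n_blocks), C)))
  blocks <- unname(blocks)
  lapply(seq_len(K), function(s) {
    strong <- s %% 2L == 1L
    cycle <- (s - 1L) %/% n_blocks # distinguishes states reusing a block
    within <- if (strong) rep(0.35, n_blocks) else rep(0.10, n_blocks)
    within[(s - 1L) %% n_blocks + 1L] <- if (strong) 0.65 else 0.25
    list(blocks = blocks,
         within = within,
         between = max((if (strong) 0.15 else 0.02) - 0.13 * cycle, -0.2))
  })
}

#' Maximally distinguishable block specification for validation studies
#'
#' One component block per state: in state `s`, block `s` carries strong
#' within-block correlation and every other block stays near independence.
#' The `K` states are therefore mutually equidistant and far apart against
#' sliding-window estimation noise — the regime in which state recovery and
#' model selection are unambiguous. Use it to validate the clustering
#' stages, not to emulate realistic effect sizes.
#'
#' @inheritParams make_state_covariances
#' @param strong Within-block correlation of the state's own block.
#' @param weak Within-block correlation of the remaining blocks.
#' @return A list of length `K` suitable for `block_spec`; requires
#'   `C >= 2 * K` so every state owns a block of at least two components.
#' @export
benchmark_block_spec <- function(C, K, strong = 0.8, weak = 0.05) {
  if (C < 2 * K) abort("benchmark spec needs C >= 2 * K")
  blocks <- unname(split(seq_len(C), sort(rep_len(seq_len(K), C))))
  lapply(seq_len(K), function(s) {
    within <- rep(weak, K)
    within[s] <- strong
    list(blocks = blocks, within = within, between = 0)
  })
}

#' Construct a row-stochastic Markov transition matrix
#'
#' Uniform off-diagonal mass with a common stay probability, optionally
#' overridden per state. This is the generator's model of state persistence:
#' dwell times are geometric with mean `1 / (1 - stay)`.
#'
#' @param K Number of states.
#' @param stay Common diagonal (stay) probability in (0, 1).
#' @param overrides Named numeric vector: names are state indices (as
#'   characters), values replace that state's stay probability.
#' @return A K x K row-stochastic matrix.
#' @examples
#' markov_transition(3, 0.9, overrides = c("2" = 0.95))
#' @export
markov_transition <- function(K, stay = 0.9, overrides = NULL) {
  stopifnot(K >= 1, stay > 0, stay <= 1)
  stays <- rep(stay, K)
  if (!is.null(overrides)) {
    idx <- as.integer(names(overrides))
    stopifnot(all(idx >= 1 & idx <= K))
    stays[idx] <- overrides
  }
  P <- matrix(0, K, K)
  for (i in seq_len(K)) {
    if (K == 1L) {
      P[i, i] <- 1
    } else {
      P[i, ] <- (1 - stays[i]) / (K - 1)
      P[i, i] <- stays[i]
    }
  }
  P
}

#' Specify a synthetic state-switching cohort design
#'
#' A design bundles everything the generator needs: the group sizes, one
#' transition matrix per group (this is where dwell-time group differences
#' are planted), per-group additive edge perturbations of the state
#' covariances (this is where hypo-/hyper-connectivity effects are planted),
#' and the observation model (time points, TR, isotropic noise).
#'
#' @param groups A data frame with columns `group` (label) and `n` (subjects).
#' @param covariances A [make_state_covariances()] object.
#' @param transition Either one K x K row-stochastic matrix shared by all
#'   groups or a named list of such matrices keyed by group label.
#' @param perturbations Optional data frame with columns `group`, `state`,
#'   `i`, `j`, `delta`: additive change to covariance entry (i, j) of that
#'   state for that group. `NULL` for none.
#' @param T Time points per subject.
#' @param TR Repetition time in seconds (sampling interval of the series).
#' @param noise_sd Standard deviation of isotropic Gaussian observation noise.
#' @param seed Cohort master seed; per-subject seeds are derived from it.
#' @return A validated object of class `group_design`.
#' @export
group_design <- function(groups, covariances, transition,
                         perturbations = NULL,
                         T = 230L, TR = 2, noise_sd = 1, seed = 1L) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("group", "n") %in% names(groups)))
  if (anyDuplicated(groups$group)) abort("duplicate group labels in design")
  if (any(groups$n < 1)) abort("each group needs n_subjects >= 1")
  stopifnot(inherits(covariances, "state_covariances"), T >= 2, TR > 0,
            noise_sd >= 0)
  K <- covariances$K
  if (is.matrix(transition)) {
    transition <- setNames(rep(list(transition), nrow(groups)), groups$group)
  }
  if (!setequal(names(transition), groups$group)) {
    abort("transition list must be keyed by the group labels")
  }
  for (g in names(transition)) {
    P <- transition[[g]]
    stopifnot(is.matrix(P), nrow(P) == K, ncol(P) == K, all(P >= 0))
    if (max(abs(rowSums(P) - 1)) > 1e-12) {
      abort(sprintf("transition rows for group '%s' must sum to 1", g))
    }
  }
  if (!is.null(perturbations)) {
    perturbations <- tibble::as_tibble(perturbations)
    stopifnot(all(c("group", "state", "i", "j", "delta") %in%
                    names(perturbations)))
  }
  design <- structure(
    list(groups = groups, covariances = covariances, transition = transition,
         perturbations = perturbations, T = as.integer(T), TR = TR,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "group_design"
  )
  # validate that every perturbed state covariance stays positive definite
  for (g in groups$group) {
    covs <- group_covariances(design, g)
    ev <- vapply(covs, function(m) min(eigen(m, symmetric = TRUE)$values), 0)
    if (any(ev <= 0)) {
      abort(sprintf(
        "perturbations for group '%s' break positive definiteness in state %d",
        g, which(ev <= 0)[1]
      ))
    }
  }
  design
}

# State covariances with a group's perturbations applied.
group_covariances <- function(design, group) {
  covs <- design$covariances$covariances
  pert <- design$perturbations
  if (!is.null(pert)) {
    pert <- pert[pert$group == group, , drop = FALSE]
    for (r in seq_len(nrow(pert))) {
      s <- pert$state[r]
      i <- pert$i[r]; j <- pert$j[r]
      covs[[s]][i, j] <- covs[[s]][i, j] + pert$delta[r]
      covs[[s]][j, i] <- covs[[s]][i, j]
    }
  }
  covs
}

#' Reference cohort design: four suicidality groups
#'
#' The generator's default study conditions: C = 23 components, T = 230 time
#' points at TR = 2 s, K = 6 recurring states, and four groups — healthy
#' controls (HC, n = 38) and depressed patients with no suicide risk
#' (NS, n = 48), suicidal ideation (SI, n = 74), or a suicide attempt
#' (SA, n = 51). Group contrasts are planted where the clinical findings
#' sit: the SA chain dwells longer in weakly connected state 4 and shorter
#' in strongly connected state 5 than the SI/NS chains, the NS chain dwells
#' longer in state 6 than HC, and the SA group carries additive
#' hypoconnectivity (delta = -0.25) on five designated edges of state 4.
#'
#' @param n_per_group Optional named integer vector overriding the group
#'   sizes (e.g. `c(HC = 10, SA = 10)` for a scaled-down two-group cohort);
#'   groups absent from the vector are dropped.
#' @param C,T,TR,K,noise_sd,seed Observation-model settings; defaults are the
#'   reference conditions.
#' @return A `group_design`.
#' @examples
#' d <- suicidality_design(n_per_group = c(HC = 4, SA = 4), C = 8, T = 120)
#' d$groups
#' @export
suicidality_design <- function(n_per_group = NULL, C = 23L, T = 230L, TR = 2,
                               K = 6L, noise_sd = 1, seed = 1L) {
  groups <- tibble::tibble(group = c("HC", "NS", "SI", "SA"),
                           n = c(38L, 48L, 74L, 51L))
  if (!is.null(n_per_group)) {
    groups <- groups[groups$group %in% names(n_per_group), , drop = FALSE]
    groups$n <- as.integer(n_per_group[groups$group])
  }
  covs <- make_state_covariances(C, K, seed = derive_seed(seed, 0L, 1L))
  base_stay <- 0.90
  trans <- list(
    HC = markov_transition(K, base_stay),
    NS = markov_transition(K, base_stay,
                           overrides = stay_override(K, 6L, 0.95)),
    SI = markov_transition(K, base_stay),
    SA = markov_transition(K, base_stay,
                           overrides = c(stay_override(K, 4L, 0.96),
                                         stay_override(K, 5L, 0.78)))
  )[groups$group]
  pert <- NULL
  if ("SA" %in% groups$group && K >= 4L && C >= 6L) {
    edges <- utils::combn(6L, 2L)[, 1:5]
    pert <- tibble::tibble(group = "SA", state = 4L,
                           i = edges[1, ], j = edges[2, ], delta = -0.25)
  }
  group_design(groups, covs, trans, perturbations = pert,
               T = T, TR = TR, noise_sd = noise_sd, seed = seed)
}

stay_override <- function(K, state, stay) {
  if (state > K) return(NULL)
  setNames(stay, as.character(state))
}

# Stationary distribution of a row-stochastic matrix; uniform fallback for
# reducible chains (e.g. the identity), where any distribution is stationary.
stationary_distribution <- function(P) {
  K <- nrow(P)
  if (K == 1L) return(1)
  A <- rbind(t(P) - diag(K), rep(1, K))
  b <- c(rep(0, K), 1)
  pi <- tryCatch(as.numeric(qr.solve(A, b)), error = function(e) NULL)
  if (is.null(pi) || any(!is.finite(pi)) || any(pi < -1e-8)) {
    return(rep(1 / K, K))
  }
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Simulate one subject's state-switching time courses
#'
#' Draws a hidden state sequence from the subject's group Markov chain
#' (initial state from the chain's stationary distribution), then emits each
#' time point from the zero-mean Gaussian of the current state (with the
#' group's edge perturbations applied) plus isotropic observation noise.
#' Columns are standardized to zero mean and unit variance before return,
#' mirroring z-scored component time courses.
#'
#' @param design A [group_design()].
#' @param group Group label (must exist in the design).
#' @param subject_seed Integer seed for this subject.
#' @return A list with `tc` (T x C standardized matrix), `states` (length-T
#'   integer ground-truth sequence), `group`, and `TR`.
#' @export
simulate_subject <- function(design, group, subject_seed) {
  stopifnot(inherits(design, "group_design"),
            group %in% design$groups$group)
  set.seed(subject_seed)
  K <- design$covariances$K
  C <- design$covariances$C
  Tn <- design$T
  P <- design$transition[[group]]
  covs <- group_covariances(design, group)
  chols <- lapply(covs, chol)
  states <- integer(Tn)
  states[1] <- sample.int(K, 1, prob = stationary_distribution(P))
  if (Tn > 1) {
    for (t in 2:Tn) {
      states[t] <- sample.int(K, 1, prob = P[states[t - 1], ])
    }
  }
  z <- matrix(rnorm(Tn * C), Tn, C)
  tc <- matrix(0, Tn, C)
  for (s in unique(states)) {
    idx <- which(states == s)
    tc[idx, ] <- z[idx, , drop = FALSE] %*% chols[[s]]
  }
  if (design$noise_sd > 0) {
    tc <- tc + matrix(rnorm(Tn * C, sd = design$noise_sd), Tn, C)
  }
  tc <- scale(tc)
  attr(tc, "scaled:center") <- NULL
  attr(tc, "scaled:scale") <- NULL
  colnames(tc) <- sprintf("IC%02d", seq_len(C))
  list(tc = tc, states = states, group = group, TR = design$TR)
}

#' Simulate a full cohort with ground truth
#'
#' Runs [simulate_subject()] for every subject in the design, with
#' per-subject seeds derived deterministically from the cohort seed, so the
#' whole cohort is reproducible and subjects are decoupled.
#'
#' @param design A [group_design()].
#' @param dir Optional directory: when given, per-subject time courses, the
#'   manifest and the ground truth are written there as delimited text via
#'   [write_cohort()].
#' @return An object of class `cohort`: list with `manifest` (tibble:
#'   subject_id, group, TR, path), `time_courses` (named list of T x C
#'   matrices), and `ground_truth` (list: `states` named list of sequences,
#'   `transition` per-group matrices, `perturbations` ledger).
#' @examples
#' d <- suicidality_design(n_per_group = c(HC = 3, SA = 3), C = 6, T = 60)
#' coh <- simulate_cohort(d)
#' coh$manifest
#' @export
simulate_cohort <- function(design, dir = NULL) {
  stopifnot(inherits(design, "group_design"))
  labels <- rep(design$groups$group, design$groups$n)
  ids <- sprintf("sub-%03d", seq_along(labels))
  sims <- lapply(seq_along(labels), function(i) {
    simulate_subject(design, labels[i], derive_seed(design$seed, i))
  })
  manifest <- tibble::tibble(
    subject_id = ids,
    group = labels,
    TR = design$TR,
    path = NA_character_
  )
  cohort <- structure(
    list(
      manifest = manifest,
      time_courses = setNames(lapply(sims, `[[`, "tc"), ids),
      ground_truth = list(
        states = setNames(lapply(sims, `[[`, "states"), ids),
        transition = design$transition,
        perturbations = design$perturbations
      )
    ),
    class = "cohort"
  )
  if (!is.null(dir)) cohort <- write_cohort(cohort, dir)
  cohort
}

#' Simulate voxel-level data from spatial maps and time courses
#'
#' Linear mixing model: `maps %*% t(time_courses)` plus isotropic Gaussian
#' noise; the fixture for exercising the decomposition stage.
#'
#' @param spatial_maps voxels x C matrix.
#' @param time_courses T x C matrix.
#' @param noise_sd Observation noise standard deviation.
#' @param seed Integer seed.
#' @return A voxels x T matrix.
#' @export
simulate_voxel_data <- function(spatial_maps, time_courses, noise_sd = 0,
                                seed = 1L) {
  spatial_maps <- as.matrix(spatial_maps)
  time_courses <- as.matrix(time_courses)
  if (ncol(spatial_maps) != ncol(time_courses)) {
    abort("spatial_maps and time_courses disagree on component count")
  }
  set.seed(seed)
  x <- spatial_maps %*% t(time_courses)
  if (noise_sd > 0) {
    x <- x + matrix(rnorm(length(x), sd = noise_sd), nrow(x), ncol(x))
  }
  x
}
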