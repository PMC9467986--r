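#' Pool windowed FNC stacks into a window-by-feature matrix
#'
#' @param fnc_list Named list of `windowed_fnc` objects.
#' @return List with `x` (rows = windows of all subjects, cols = vectorized
#'   edges), `subject_id` (row labels), `window` (within-subject indices).
#' @export
pool_windows <- function(fnc_list) {
  stopifnot(length(fnc_list) > 0)
  xs <- lapply(fnc_list, function(wf) {
    t(apply(wf$z, 3, vectorize_fnc))
  })
  x <- do.call(rbind, xs)
  list(
    x = x,
    subject_id = rep(names(fnc_list), vapply(xs, nrow, 0L)),
    window = unlist(lapply(xs, function(m) seq_len(nrow(m))), use.names = FALSE)
  )
}

# k-means++ seeding: first centre uniform, then distance-squared weighted.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

# Deterministic nearest-centroid assignment; ties go to the lowest index.
assign_nearest <- function(x, centers) {
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * cross + outer(rep(1, nrow(x)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Cluster pooled dFNC windows into connectivity states
#'
#' Best-of-`n_replicates` K-means on the vectorized Fisher-z windows of all
#' subjects pooled, squared-Euclidean objective. Each replicate is seeded by
#' k-means++ from the documented RNG and refined by Lloyd iterations; the
#' solution with the lowest within-cluster sum of squares wins. States are
#' relabeled in decreasing occupancy order, and the final assignment is the
#' deterministic nearest-centroid rule (ties to the lowest state index).
#'
#' @param fnc_list Named list of `windowed_fnc` objects, or a precomputed
#'   numeric matrix of window feature vectors (rows = windows).
#' @param k Number of states.
#' @param n_replicates Number of random restarts (the reference analysis uses
#'   500; scale down for small problems).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param iter_max Lloyd iteration cap per replicate.
#' @return An object of class `state_model`: `k`, `centroids` (k x m matrix),
#'   `centroid_matrices` (list of C x C z-matrices when C is known),
#'   `assignments` (named list of per-subject state sequences, or a single
#'   vector for matrix input), `wcss`, `n_replicates`, `seed`.
#' @export
kmeans_states <- function(fnc_list, k, n_replicates = 50L, seed = 1L,
                          iter_max = 100L) {
  if (is.matrix(fnc_list)) {
    pooled <- list(x = fnc_list,
                   subject_id = rep("all", nrow(fnc_list)),
                   window = seq_len(nrow(fnc_list)))
    C <- NULL
  } else {
    pooled <- pool_windows(fnc_list)
    C <- fnc_list[[1]]$C
  }
  x <- pooled$x
  if (k > nrow(x)) abort("k exceeds the number of pooled windows")
  best <- NULL
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, r, salt = 17L))
    init <- kmeanspp_init(x, k)
    km <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = iter_max,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  centers <- best$centers
  assign <- assign_nearest(x, centers)
  ord <- order(tabulate(assign, nbins = k), decreasing = TRUE)
  centers <- centers[ord, , drop = FALSE]
  assign <- match(assign, ord)
  rownames(centers) <- NULL
  split_assign <- split(assign, factor(pooled$subject_id,
                                       levels = unique(pooled$subject_id)))
  structure(list(
    k = k,
    centroids = centers,
    centroid_matrices = if (!is.null(C)) {
      lapply(seq_len(k), function(s) devectorize_fnc(centers[s, ], C))
    },
    assignments = lapply(split_assign, as.integer),
    wcss = best$tot.withinss,
    totss = best$totss,
    n_replicates = n_replicates,
    seed = seed
  ), class = "state_model")
}

#' Select the number of states by the elbow criterion
#'
#' For each candidate `k` the cluster validity index (within-cluster over
#' between-cluster sum of squared distances) is reported, and the selected
#' `k` is the point of maximum curvature — the interior candidate with the
#' largest positive discrete second difference — of the normalized
#' within-cluster dispersion curve `wcss / totss`. The curvature is taken on
#' the within term rather than on the ratio because for well-separated
#' equal-occupancy states the within curve falls linearly to `k*` and then
#' flattens (a clean spike in its second difference), whereas dividing by
#' the growing between term bends the curve convex at small `k` and buries
#' the knee. A curve with no discernible elbow (maximum curvature not
#' standing out from the rest) is an error advising manual `k`.
#'
#' @inheritParams kmeans_states
#' @param k_range Contiguous integer range of candidate k (>= 3 values, all
#'   >= 2).
#' @param elbow_strength Minimum ratio of the largest to the second-largest
#'   curvature for the elbow to count as real; smooth convex curves without
#'   a knee stay well below it.
#' @return List with `k` (selected) and `curve` (tibble: k, wcss, bcss,
#'   validity, curvature).
#' @export
select_k_elbow <- function(fnc_list, k_range = 2:10, n_replicates = 20L,
                           seed = 1L, elbow_strength = 3) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3 || any(diff(k_range) != 1L)) {
    abort("k_range must be a contiguous range with at least 3 values")
  }
  if (min(k_range) < 2) abort("k_range must start at k >= 2")
  fits <- lapply(k_range, function(k) {
    kmeans_states(fnc_list, k, n_replicates = n_replicates,
                  seed = derive_seed(seed, k, salt = 23L))
  })
  wcss <- vapply(fits, `[[`, 0, "wcss")
  totss <- fits[[1]]$totss
  bcss <- pmax(totss - wcss, .Machine$double.eps)
  validity <- wcss / bcss
  wfrac <- wcss / totss
  curvature <- rep(NA_real_, length(k_range))
  interior <- 2:(length(k_range) - 1)
  curvature[interior] <- wfrac[interior - 1] - 2 * wfrac[interior] +
    wfrac[interior + 1]
  curve <- tibble::tibble(k = k_range, wcss = wcss, bcss = bcss,
                          validity = validity, wfrac = wfrac,
                          curvature = curvature)
  cs <- sort(curvature[interior], decreasing = TRUE)
  strength <- cs[1] / max(cs[2], 1e-3 * diff(range(wfrac)),
                          .Machine$double.eps)
  if (!is.finite(strength) || strength < elbow_strength ||
      max(curvature[interior]) <= 0) {
    abort(paste0(
      "no clear elbow in the validity curve (strength ",
      sprintf("%.2f", strength), " < ", elbow_strength,
      "); inspect the curve and set k manually"
    ))
  }
  list(k = k_range[interior][which.max(curvature[interior])], curve = curve)
}

#' Temporal dynamics metrics of one assignment sequence
#'
#' Mean dwell time (DT, mean length of maximal consecutive runs, in
#' windows), fraction time (FT, occupancy proportion) and the number of
#' transitions (NT, adjacent unequal pairs). DT is `NA` for states the
#' subject never enters; FT sums to 1 across states.
#'
#' @param states Integer assignment sequence (values in 1..k).
#' @param k Number of states.
#' @return Tibble with one row per state: `state`, `dwell_time`,
#'   `fraction_time`, `entered`, plus the subject-level `n_transitions`
#'   repeated on every row.
#' @examples
#' dynamics_metrics(c(1, 1, 1, 2, 2), k = 2)
#' @export
dynamics_metrics <- function(states, k) {
  states <- as.integer(states)
  if (length(states) == 0) abort("empty assignment sequence")
  if (any(states < 1 | states > k)) abort("state index outside 1..k")
  r <- rle(states)
  dt <- vapply(seq_len(k), function(s) {
    runs <- r$lengths[r$values == s]
    if (length(runs) == 0) NA_real_ else mean(runs)
  }, 0)
  ft <- tabulate(states, nbins = k) / length(states)
  tibble::tibble(state = seq_len(k), dwell_time = dt, fraction_time = ft,
                 entered = !is.na(dt),
                 n_transitions = sum(diff(states) != 0L))
}

#' Dynamics metrics for every subject in a state model
#'
#' @param model A [kmeans_states()] `state_model`.
#' @param manifest Cohort manifest tibble (subject_id, group) for labels.
#' @return Long tibble: subject_id, group, state, dwell_time, fraction_time,
#'   entered, n_transitions.
#' @export
cohort_dynamics <- function(model, manifest) {
  purrr::imap_dfr(model$assignments, function(seqn, id) {
    dplyr::mutate(dynamics_metrics(seqn, model$k),
                  subject_id = id, .before = 1)
  }) |>
    dplyr::left_join(manifest[, c("subject_id", "group")], by = "subject_id") |>
    dplyr::relocate("group", .after = "subject_id")
}

#' Per-state mean FNC of one subject
#'
#' Elementwise mean of the subject's Fisher-z windows assigned to each state;
#' states the subject never enters are flagged absent.
#'
#' @param wfnc A `windowed_fnc` for one subject.
#' @param assignment That subject's state sequence (length = window count).
#' @param k Number of states.
#' @return Tibble: state, entered, fnc (list-column of C x C matrices, `NULL`
#'   when not entered).
#' @export
subject_state_fnc <- function(wfnc, assignment, k) {
  stopifnot(length(assignment) == dim(wfnc$z)[3])
  tibble::tibble(
    state = seq_len(k),
    entered = vapply(seq_len(k), function(s) any(assignment == s), TRUE),
    fnc = lapply(seq_len(k), function(s) {
      idx <- which(assignment == s)
      if (length(idx) == 0) return(NULL)
      apply(wfnc$z[, , idx, drop = FALSE], c(1, 2), mean)
    })
  )
}

#' Per-state mean FNC for the whole cohort
#'
#' @param model A `state_model`.
#' @param fnc_list The named list of `windowed_fnc` the model was fit on.
#' @param manifest Cohort manifest (subject_id, group).
#' @return Tibble: subject_id, group, state, entered, fnc_vec (list-column of
#'   vectorized edge vectors; `NULL` when not entered).
#' @export
cohort_state_fnc <- function(model, fnc_list, manifest) {
  purrr::imap_dfr(model$assignments, function(seqn, id) {
    sf <- subject_state_fnc(fnc_list[[id]], seqn, model$k)
    tibble::tibble(
      subject_id = id, state = sf$state, entered = sf$entered,
      fnc_vec = lapply(sf$fnc, function(m) {
        if (is.null(m)) NULL else vectorize_fnc(m)
      })
    )
  }) |>
    dplyr::left_join(manifest[, c("subject_id", "group")], by = "subject_id") |>
    dplyr::relocate("group", .after = "subject_id")
}

#' Per-group counts of subjects entering each state
#'
#' @param model A `state_model`.
#' @param manifest Cohort manifest (subject_id, group).
#' @return Tibble: group, state, n_entered.
#' @export
state_membership_table <- function(model, manifest) {
  entered <- purrr::imap_dfr(model$assignments, function(seqn, id) {
    tibble::tibble(subject_id = id, state = seq_len(model$k),
                   entered = seq_len(model$k) %in% seqn)
  })
  entered |>
    dplyr::left_join(manifest[, c("subject_id", "group")], by = "subject_id") |>
    dplyr::group_by(.data$group, .data$state) |>
    dplyr::summarise(n_entered = sum(.data$entered), .groups = "drop")
}
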