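#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a state model into a long centroid-edge table
#'
#' @param x A `state_model` from [kmeans_states()].
#' @param ... Unused.
#' @return Tibble: state, edge, i, j, z (centroid Fisher-z value).
#' @export
tidy.state_model <- function(x, ...) {
  m <- ncol(x$centroids)
  C <- (1 + sqrt(1 + 8 * m)) / 2
  em <- edge_index_map(as.integer(C))
  purrr::map_dfr(seq_len(x$k), function(s) {
    tibble::tibble(state = s, edge = em$edge, i = em$i, j = em$j,
                   z = x$centroids[s, ])
  })
}

#' One-row summary of a state model
#'
#' @param x A `state_model`.
#' @param ... Unused.
#' @return Tibble: k, n_windows, n_subjects, wcss, totss, n_replicates, seed.
#' @export
glance.state_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_windows = sum(lengths(x$assignments)),
    n_subjects = length(x$assignments),
    wcss = x$wcss,
    totss = x$totss,
    n_replicates = x$n_replicates,
    seed = x$seed
  )
}

#' Tidy a subject's windowed FNC stack
#'
#' @param x A `windowed_fnc` from [compute_dfnc()].
#' @param ... Unused.
#' @return Tibble: window, edge, i, j, z.
#' @export
tidy.windowed_fnc <- function(x, ...) {
  em <- edge_index_map(x$C)
  W <- dim(x$z)[3]
  purrr::map_dfr(seq_len(W), function(w) {
    tibble::tibble(window = w, edge = em$edge, i = em$i, j = em$j,
                   z = vectorize_fnc(x$z[, , w]))
  })
}

#' One-row summary of a windowed FNC stack
#'
#' @param x A `windowed_fnc`.
#' @param ... Unused.
#' @return Tibble: subject_id, n_windows, n_components, n_edges,
#'   window_length, step, lambda.
#' @export
glance.windowed_fnc <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id %||% NA_character_,
    n_windows = dim(x$z)[3],
    n_components = x$C,
    n_edges = x$C * (x$C - 1) / 2,
    window_length = x$params$window_length,
    step = x$params$step,
    lambda = x$lambda
  )
}

#' Tidy a classifier result into its weight map
#'
#' @param x A `classifier_result` from [classify_state()].
#' @param ... Unused.
#' @return Tibble: edge, weight (empty when not evaluable).
#' @export
tidy.classifier_result <- function(x, ...) {
  x$weights %||% tibble::tibble(edge = integer(0), weight = numeric(0))
}

#' One-row performance summary of a classifier result
#'
#' @param x A `classifier_result`.
#' @param ... Unused.
#' @return The summary tibble (state, group pair, best N / C / gamma,
#'   accuracy, AUC, sensitivity, specificity, cutoff, permutation p).
#' @export
glance.classifier_result <- function(x, ...) {
  x$summary
}
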