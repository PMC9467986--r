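# Vectorized two-sample t over columns; stats::t.test is the test oracle.
t2_columns <- function(XA, XB, var_equal = TRUE) {
  nA <- nrow(XA); nB <- nrow(XB)
  mA <- colMeans(XA); mB <- colMeans(XB)
  vA <- apply(XA, 2, var); vB <- apply(XB, 2, var)
  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, length(mA))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- se^4 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  t <- (mA - mB) / se
  t[se == 0 & mA == mB] <- 0
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  p[se == 0 & mA == mB] <- 1
  list(t = t, df = df, p = p)
}

#' Edgewise two-sample t-tests between two groups
#'
#' Two-sided two-sample t-test (equal-variance by default) on every edge of
#' the vectorized per-state FNC, group A minus group B.
#'
#' @param XA,XB Subjects x edges matrices for the two groups (>= 2 rows
#'   each).
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return Tibble: edge, i, j, t, df, p (edge order as [vectorize_fnc()]).
#' @export
edgewise_ttest <- function(XA, XB, var_equal = TRUE) {
  XA <- as.matrix(XA); XB <- as.matrix(XB)
  if (nrow(XA) < 2 || nrow(XB) < 2) {
    abort("each group needs at least 2 subjects")
  }
  stopifnot(ncol(XA) == ncol(XB))
  res <- t2_columns(XA, XB, var_equal)
  m <- ncol(XA)
  C <- (1 + sqrt(1 + 8 * m)) / 2
  em <- if (C == round(C)) edge_index_map(as.integer(C))[, c("i", "j")] else
    tibble::tibble(i = NA_integer_, j = NA_integer_)[rep(1, m), ]
  tibble::tibble(edge = seq_len(m), i = em$i, j = em$j,
                 t = res$t, df = res$df, p = res$p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjusted values with a significance mask at `alpha`.
#'
#' @param p Vector of p-values between 0 and 1.
#' @param alpha FDR level (default 0.05).
#' @return Tibble: p, q, significant. Empty input gives an empty tibble.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (length(p) == 0) {
    return(tibble::tibble(p = numeric(0), q = numeric(0),
                          significant = logical(0)))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, significant = !is.na(q) & q <= alpha)
}

#' Edgewise group comparison within each state
#'
#' For every state in which both groups have at least two entered subjects,
#' runs [edgewise_ttest()] on the per-state mean FNC and applies
#' [fdr_bh()] over that state's edge family (253 edges when C = 23; the
#' correction is per state, not pooled across states).
#'
#' @param state_fnc Tibble from [cohort_state_fnc()].
#' @param pair Character vector of two group labels, compared as
#'   `pair[1] - pair[2]`.
#' @param alpha FDR level.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return Long tibble: state, group_a, group_b, edge, i, j, t, df, p, q,
#'   significant. States skipped for want of subjects are reported via a
#'   message and omitted.
#' @export
compare_state_fnc <- function(state_fnc, pair, alpha = 0.05,
                              var_equal = TRUE) {
  stopifnot(length(pair) == 2)
  purrr::map_dfr(sort(unique(state_fnc$state)), function(s) {
    sub <- state_fnc[state_fnc$state == s & state_fnc$entered, ]
    XA <- do.call(rbind, sub$fnc_vec[sub$group == pair[1]])
    XB <- do.call(rbind, sub$fnc_vec[sub$group == pair[2]])
    if (is.null(XA) || is.null(XB) || nrow(XA) < 2 || nrow(XB) < 2) {
      inform(sprintf(
        "state %d skipped: fewer than 2 entered subjects in a group", s))
      return(NULL)
    }
    tt <- edgewise_ttest(XA, XB, var_equal)
    adj <- fdr_bh(tt$p, alpha)
    dplyr::mutate(tt, state = s, group_a = pair[1], group_b = pair[2],
                  q = adj$q, significant = adj$significant,
                  .before = 1)
  })
}

#' Group comparison of temporal dynamics metrics
#'
#' Two-sample t-tests for mean dwell time and fraction time per state
#' (restricted, for dwell time, to subjects who entered the state) and for
#' the subject-level number of transitions, with BH correction across the
#' whole metric family of this comparison.
#'
#' @param dynamics Tibble from [cohort_dynamics()].
#' @param pair Two group labels, compared as `pair[1] - pair[2]`.
#' @param alpha FDR level.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return Tibble: metric, state (NA for the transition count), group means,
#'   t, df, p, q, significant.
#' @export
metrics_tests <- function(dynamics, pair, alpha = 0.05, var_equal = TRUE) {
  stopifnot(length(pair) == 2)
  one_test <- function(a, b, metric, state) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    res <- t2_columns(matrix(a, ncol = 1), matrix(b, ncol = 1), var_equal)
    tibble::tibble(metric = metric, state = state,
                   mean_a = mean(a), mean_b = mean(b),
                   t = res$t, df = res$df, p = res$p)
  }
  rows <- purrr::map_dfr(sort(unique(dynamics$state)), function(s) {
    d <- dynamics[dynamics$state == s, ]
    dplyr::bind_rows(
      one_test(d$dwell_time[d$group == pair[1] & d$entered],
               d$dwell_time[d$group == pair[2] & d$entered],
               "dwell_time", s),
      one_test(d$fraction_time[d$group == pair[1]],
               d$fraction_time[d$group == pair[2]],
               "fraction_time", s)
    )
  })
  nt <- dynamics |>
    dplyr::distinct(.data$subject_id, .data$group, .data$n_transitions)
  rows <- dplyr::bind_rows(
    rows,
    one_test(nt$n_transitions[nt$group == pair[1]],
             nt$n_transitions[nt$group == pair[2]],
             "n_transitions", NA_integer_)
  )
  if (nrow(rows) == 0) return(rows)
  adj <- fdr_bh(rows$p, alpha)
  dplyr::mutate(rows, group_a = pair[1], group_b = pair[2],
                q = adj$q, significant = adj$significant)
}
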