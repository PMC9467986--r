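#' Sliding-window parameters for dFNC estimation
#'
#' @param window_length Window length in TRs (default 50, i.e. 100 s at
#'   TR = 2 s).
#' @param step Step between window starts in TRs (default 1).
#' @param taper `"rectangular"` (default) or `"gaussian"` — a rectangle
#'   convolved with a Gaussian of `taper_sigma` TRs.
#' @param taper_sigma Gaussian taper width in TRs.
#' @param lambda L1 penalty for the graphical LASSO (>= 0), or `"cv"` to
#'   select it by cross-validated Gaussian log-likelihood over a subsample of
#'   windows.
#' @param lambda_grid Candidate penalties for `lambda = "cv"`.
#' @param cv_folds Folds for the lambda search.
#' @param n_lambda_windows Number of evenly spaced windows used in the
#'   lambda search.
#' @param seed Seed for the (deterministic) fold assignment.
#' @return A list of class `dfnc_params`.
#' @export
dfnc_params <- function(window_length = 50L, step = 1L,
                        taper = c("rectangular", "gaussian"),
                        taper_sigma = 3,
                        lambda = 0.1,
                        lambda_grid = c(0.01, 0.03, 0.1, 0.3),
                        cv_folds = 3L, n_lambda_windows = 10L, seed = 1L) {
  taper <- match.arg(taper)
  stopifnot(window_length >= 2, step >= 1, cv_folds >= 2)
  if (!identical(lambda, "cv")) stopifnot(is.numeric(lambda), lambda >= 0)
  structure(list(window_length = as.integer(window_length),
                 step = as.integer(step), taper = taper,
                 taper_sigma = taper_sigma, lambda = lambda,
                 lambda_grid = lambda_grid, cv_folds = as.integer(cv_folds),
                 n_lambda_windows = as.integer(n_lambda_windows),
                 seed = as.integer(seed)),
            class = "dfnc_params")
}

#' Enumerate sliding windows
#'
#' Windows start at 0, step, 2*step, ... (0-based) and must start strictly
#' before `T - w` (a start at exactly `T - w` is excluded), giving
#' `(T - w) / step` windows at unit step — 180 for T = 230, w = 50,
#' step = 1 — and `ceiling((T - w) / step)` in general. Returned as a
#' tibble of 1-based inclusive index ranges.
#'
#' @param T Number of time points.
#' @param w Window length in TRs.
#' @param step Step in TRs.
#' @return Tibble with columns `window`, `start`, `end` (1-based, inclusive).
#' @examples
#' nrow(sliding_windows(230, 50, 1)) # 180
#' @export
sliding_windows <- function(T, w, step = 1L) {
  stopifnot(step >= 1)
  if (w > T) abort(sprintf("window length %d exceeds T = %d", w, T))
  n <- as.integer(ceiling((T - w) / step))
  if (n < 1) abort("no complete window starts strictly before T - w")
  starts0 <- (seq_len(n) - 1L) * step
  tibble::tibble(window = seq_len(n), start = starts0 + 1L,
                 end = starts0 + as.integer(w))
}

# Taper weights over a window, normalized to sum to 1.
taper_weights <- function(w, taper = "rectangular", sigma = 3) {
  if (taper == "rectangular") return(rep(1 / w, w))
  t <- seq_len(w)
  # rectangle spanning the window convolved with N(0, sigma^2)
  raw <- stats::pnorm((t - 0.5) / sigma) - stats::pnorm((t - w - 0.5) / sigma)
  raw / sum(raw)
}

#' Weighted covariance of one window
#'
#' Weighted sample covariance with taper weights normalized to sum to 1 and
#' the reliability-weights denominator `1 - sum(w^2)` (the usual `n - 1`
#' denominator for a rectangular taper).
#'
#' @param tc T x C time-course matrix.
#' @param start,end 1-based inclusive window bounds.
#' @param weights Taper weights of length `end - start + 1` (any scale; they
#'   are renormalized), or `NULL` for rectangular.
#' @return C x C symmetric covariance; zero-variance components are flagged
#'   via attribute `degenerate` (integer indices).
#' @export
window_covariance <- function(tc, start, end, weights = NULL) {
  stopifnot(start >= 1, end <= nrow(tc), end > start)
  x <- tc[start:end, , drop = FALSE]
  n <- nrow(x)
  w <- if (is.null(weights)) rep(1 / n, n) else weights / sum(weights)
  stopifnot(length(w) == n)
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu)
  S <- crossprod(xc, xc * w) / (1 - sum(w^2))
  S <- (S + t(S)) / 2
  degen <- which(diag(S) <= 1e-12)
  attr(S, "degenerate") <- degen
  S
}

#' Graphical LASSO estimate of a sparse-precision covariance
#'
#' Solves the L1-penalized Gaussian maximum-likelihood problem
#' (off-diagonals of the precision penalized by `lambda`) by block
#' coordinate descent and returns both the covariance estimate and the
#' precision.
#'
#' @param S Symmetric covariance matrix (PSD up to jitter).
#' @param lambda Penalty >= 0.
#' @param max_iter,tol Outer-loop budget and relative convergence tolerance.
#' @return List with `w` (covariance estimate), `theta` (precision),
#'   `iterations`, `converged`.
#' @export
graphical_lasso <- function(S, lambda, max_iter = 100L, tol = 1e-4) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S), lambda >= 0)
  if (max(abs(S - t(S))) > 1e-8) abort("covariance must be symmetric")
  fit <- .glasso_cpp(S, lambda, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    gap <- max(abs(fit$w - S)) # crude primal-change proxy reported on failure
    abort(sprintf(
      "graphical lasso did not converge in %d iterations (last change %.3g)",
      max_iter, gap
    ))
  }
  fit
}

#' Regularized correlation matrix from the graphical LASSO
#'
#' Runs [graphical_lasso()] and rescales the penalized covariance estimate
#' to a correlation matrix (unit diagonal). At `lambda = 0` this is the
#' sample correlation; as `lambda` grows, off-diagonals shrink to zero.
#'
#' @inheritParams graphical_lasso
#' @return C x C correlation matrix.
#' @export
graphical_lasso_fnc <- function(S, lambda, max_iter = 100L, tol = 1e-4) {
  degen <- attr(S, "degenerate") %||% integer(0)
  if (length(degen) > 0) {
    # keep the solver well-posed: give flat components unit variance, then
    # zero their correlations afterwards
    diag(S)[degen] <- 1
    S[degen, -degen] <- 0
    S[-degen, degen] <- 0
  }
  fit <- graphical_lasso(S, lambda, max_iter = max_iter, tol = tol)
  R <- stats::cov2cor(fit$w)
  if (length(degen) > 0) {
    warn(sprintf("zero-variance component(s) %s: correlations set to 0",
                 paste(degen, collapse = ", ")))
    R[degen, ] <- 0
    R[, degen] <- 0
    diag(R) <- 1
  }
  (R + t(R)) / 2
}

#' Select the graphical-LASSO penalty by cross-validated likelihood
#'
#' Computes covariances for `n_lambda_windows` evenly spaced windows, splits
#' them into `cv_folds` folds (deterministically from the seed), and for each
#' candidate penalty fits the graphical LASSO to the pooled training
#' covariance of each fold, scoring the held-out windows by the Gaussian
#' log-likelihood `log det(Theta) - tr(S_test Theta)`. Returns the penalty
#' with the highest mean held-out log-likelihood (ties: smaller penalty).
#'
#' @param tc T x C time-course matrix.
#' @param params A [dfnc_params()] (its `lambda_grid`, `cv_folds`,
#'   `n_lambda_windows` and `seed` are used).
#' @return The selected penalty (scalar), with the score table in attribute
#'   `scores`.
#' @export
select_lambda <- function(tc, params = dfnc_params()) {
  grid <- params$lambda_grid
  if (length(grid) == 0) abort("empty lambda grid")
  wins <- sliding_windows(nrow(tc), params$window_length, params$step)
  take <- unique(round(seq(1, nrow(wins),
                           length.out = min(params$n_lambda_windows,
                                            nrow(wins)))))
  wts <- taper_weights(params$window_length, params$taper, params$taper_sigma)
  covs <- lapply(take, function(i) {
    window_covariance(tc, wins$start[i], wins$end[i], wts)
  })
  set.seed(params$seed)
  folds <- sample(rep_len(seq_len(params$cv_folds), length(covs)))
  score <- vapply(grid, function(lam) {
    ll <- vapply(seq_len(params$cv_folds), function(f) {
      tr_idx <- which(folds != f)
      te_idx <- which(folds == f)
      if (length(tr_idx) == 0 || length(te_idx) == 0) return(NA_real_)
      S_train <- Reduce(`+`, covs[tr_idx]) / length(tr_idx)
      Theta <- graphical_lasso(S_train, lam)$theta
      ld <- determinant(Theta, logarithm = TRUE)$modulus
      mean(vapply(covs[te_idx], function(St) {
        as.numeric(ld) - sum(St * Theta)
      }, 0))
    }, 0)
    mean(ll, na.rm = TRUE)
  }, 0)
  lam <- grid[which.max(score)] # which.max takes the first (smallest) on ties
  attr(lam, "scores") <- tibble::tibble(lambda = grid, cv_loglik = score)
  lam
}

#' Compute a subject's windowed dFNC stack
#'
#' The full per-subject dFNC stage: for each sliding window, tapered
#' covariance, graphical-LASSO regularization, conversion to correlation,
#' Fisher z transform (clipped at |r| = 1 - 1e-7), and a zeroed diagonal.
#'
#' @param tc T x C time-course matrix.
#' @param params A [dfnc_params()].
#' @param subject_id Optional identifier carried in the result.
#' @return An object of class `windowed_fnc`: list with `z` (C x C x W
#'   array), `windows` (tibble from [sliding_windows()]), `lambda` (the
#'   penalty actually used), `params`, `subject_id`.
#' @examples
#' tc <- matrix(rnorm(230 * 5), 230, 5)
#' wf <- compute_dfnc(tc, dfnc_params(lambda = 0.1))
#' dim(wf$z) # 5 5 180
#' @export
compute_dfnc <- function(tc, params = dfnc_params(), subject_id = NULL) {
  tc <- as.matrix(tc)
  Tn <- nrow(tc)
  C <- ncol(tc)
  if (Tn < params$window_length) abort("T shorter than the window length")
  lam <- if (identical(params$lambda, "cv")) {
    as.numeric(select_lambda(tc, params))
  } else {
    params$lambda
  }
  wins <- sliding_windows(Tn, params$window_length, params$step)
  wts <- taper_weights(params$window_length, params$taper, params$taper_sigma)
  z <- array(0, dim = c(C, C, nrow(wins)))
  for (i in seq_len(nrow(wins))) {
    S <- window_covariance(tc, wins$start[i], wins$end[i], wts)
    R <- graphical_lasso_fnc(S, lam)
    zi <- fisher_z(R)
    diag(zi) <- 0
    z[, , i] <- zi
  }
  structure(list(z = z, windows = wins, lambda = lam, params = params,
                 subject_id = subject_id, C = C),
            class = "windowed_fnc")
}

#' Run the dFNC stage over a whole cohort
#'
#' @param time_courses Named list of T x C matrices (e.g. from
#'   [simulate_cohort()] or [read_time_courses()]).
#' @param params A [dfnc_params()].
#' @return Named list of `windowed_fnc` objects.
#' @export
cohort_dfnc <- function(time_courses, params = dfnc_params()) {
  out <- lapply(names(time_courses), function(id) {
    compute_dfnc(time_courses[[id]], params, subject_id = id)
  })
  setNames(out, names(time_courses))
}

#' Vectorize a symmetric connectivity matrix
#'
#' Flattens the strict lower triangle in row-major order — row 2: (2,1);
#' row 3: (3,1), (3,2); ... — the documented, invertible edge ordering used
#' everywhere in the package. With C = 23 this gives the 253 = 23 * 22 / 2
#' connection features.
#'
#' @param m C x C symmetric matrix (asymmetry beyond 1e-9 is an error).
#' @return Numeric vector of length C(C-1)/2.
#' @seealso [devectorize_fnc()], [edge_index_map()]
#' @export
vectorize_fnc <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-9) abort("matrix is not symmetric")
  t(m)[upper.tri(m)] # row-major strict lower triangle
}

#' Restore a symmetric matrix from its vectorized edges
#'
#' @param v Vector of length C(C-1)/2 in [vectorize_fnc()] order.
#' @param C Matrix dimension.
#' @param diagonal Value placed on the diagonal (default 0, Fisher-z
#'   convention).
#' @return C x C symmetric matrix.
#' @export
devectorize_fnc <- function(v, C, diagonal = 0) {
  stopifnot(length(v) == C * (C - 1) / 2)
  m <- matrix(0, C, C)
  mt <- t(m)
  mt[upper.tri(mt)] <- v
  m <- t(mt)
  m <- m + t(m)
  diag(m) <- diagonal
  m
}

#' Edge index to component-pair map
#'
#' @param C Number of components.
#' @param labels Optional component labels (default IC01, IC02, ...).
#' @return Tibble with columns `edge`, `i`, `j` (i > j), `component_i`,
#'   `component_j`, in [vectorize_fnc()] order.
#' @export
edge_index_map <- function(C, labels = sprintf("IC%02d", seq_len(C))) {
  idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE) # (j, i) row-major
  tibble::tibble(edge = seq_len(nrow(idx)),
                 i = as.integer(idx[, 2]), j = as.integer(idx[, 1]),
                 component_i = labels[idx[, 2]],
                 component_j = labels[idx[, 1]])
}
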