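#' F-score of each feature for a binary contrast
#'
#' The Chen-Lin feature-selection F-score: squared separation of each class
#' mean from the overall mean, over the summed within-class scatter (with
#' n - 1 denominators). Scale-invariant; larger means more discriminative.
#' A feature with zero pooled within-class variance but separated means gets
#' an `Inf` sentinel (ranked first).
#'
#' @param X Subjects x features numeric matrix.
#' @param y Binary labels (factor, character or logical); both classes must
#'   have >= 2 subjects.
#' @return Numeric vector of scores, one per feature.
#' @examples
#' f_score(matrix(c(2, 4, 0, 2), ncol = 1), c("a", "a", "b", "b")) # 0.5
#' @export
f_score <- function(X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) != 2) abort("y must have exactly two classes")
  if (any(table(y) < 2)) abort("each class needs >= 2 subjects")
  a <- y == levels(y)[1]
  m <- colMeans(X)
  mp <- colMeans(X[a, , drop = FALSE])
  mn <- colMeans(X[!a, , drop = FALSE])
  vp <- apply(X[a, , drop = FALSE], 2, var)
  vn <- apply(X[!a, , drop = FALSE], 2, var)
  num <- (mp - m)^2 + (mn - m)^2
  den <- vp + vn
  s <- num / den
  s[den == 0 & num > 0] <- Inf
  s[den == 0 & num == 0] <- 0
  if (any(is.infinite(s))) {
    warn("feature(s) with zero within-class variance: Inf F-score sentinel")
  }
  s
}

#' Rank features by descending score
#'
#' Stable, deterministic order: ties (and equal `Inf` sentinels) go to the
#' lower feature index.
#'
#' @param scores Numeric scores (finite or `Inf`).
#' @return Integer permutation: feature indices in descending score order.
#' @export
rank_features <- function(scores) {
  order(-scores, seq_along(scores))
}

#' Configuration for the per-state SVM protocol
#'
#' @param kernel `"rbf"` (default: the grid tunes both the penalty C and the
#'   kernel width gamma) or `"linear"` (gamma ignored).
#' @param C_grid Penalty-parameter candidates.
#' @param gamma_grid Kernel-width candidates.
#' @param N_grid Feature-subset sizes to scan (top-N by F-score); capped at
#'   the feature count at run time. `NULL` means 1..m.
#' @param n_permutations Label permutations for the significance test
#'   (0 disables it).
#' @param leakage_mode `"nested"` (default; F-scores recomputed inside each
#'   training fold) or `"full_sample"` (F-scores from the full sample
#'   before LOOCV — the optimistic variant, kept for fidelity).
#' @param permutation_mode `"full"` (default; the whole selection + grid
#'   search is re-run per permutation) or `"fixed"` (the observed (N, C,
#'   gamma) are reused — cheaper, slightly anti-conservative).
#' @param seed Master seed.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(kernel = c("rbf", "linear"),
                              C_grid = 2^seq(-5, 5, by = 2),
                              gamma_grid = 2^seq(-5, 5, by = 2),
                              N_grid = NULL,
                              n_permutations = 100L,
                              leakage_mode = c("nested", "full_sample"),
                              permutation_mode = c("full", "fixed"),
                              seed = 1L) {
  kernel <- match.arg(kernel)
  leakage_mode <- match.arg(leakage_mode)
  permutation_mode <- match.arg(permutation_mode)
  if (length(C_grid) == 0 || length(gamma_grid) == 0) {
    abort("C_grid and gamma_grid must be nonempty")
  }
  structure(list(kernel = kernel, C_grid = sort(C_grid),
                 gamma_grid = sort(gamma_grid), N_grid = N_grid,
                 n_permutations = as.integer(n_permutations),
                 leakage_mode = leakage_mode,
                 permutation_mode = permutation_mode,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# One SVM fit + prediction with decision values aligned so that larger
# values favor the positive class (the first factor level).
svm_kernel <- function(kernel) {
  switch(kernel, rbf = "radial", linear = "linear", kernel)
}

svm_predict <- function(Xtr, ytr, Xte, kernel, cost, gamma) {
  fit <- e1071::svm(Xtr, ytr, kernel = svm_kernel(kernel), cost = cost,
                    gamma = gamma, scale = FALSE)
  pr <- predict(fit, Xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  sgn <- if (identical(first, levels(ytr)[1])) 1 else -1
  list(pred = pr, dv = sgn * as.numeric(dv))
}

#' LOOCV grid search over feature-subset size and SVM hyperparameters
#'
#' For every (N, C, gamma) on the grids, leave-one-out cross-validation over
#' subjects using the top-N features by F-score. In `nested` mode the
#' F-scores (and hence the selected subset) are recomputed inside each
#' training fold; in `full_sample` mode they come from the full sample.
#' The winning triple maximizes LOOCV accuracy; ties prefer smaller N, then
#' smaller C, then smaller gamma.
#'
#' @param X Subjects x features matrix (columns are standardized internally).
#' @param y Binary labels; the first factor level is the positive class.
#' @param config A [classifier_config()].
#' @return List of class `loocv_fit`: `best_n`, `best_cost`, `best_gamma`,
#'   `accuracy` (percent), `predictions` and `decision_values` (held-out, for
#'   the winning triple, subject order preserved), `y`, `accuracy_table`
#'   (tibble over the whole grid), `config`.
#' @export
loocv_search <- function(X, y, config = classifier_config()) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) abort("y must have exactly two classes")
  if (any(table(y) < 2)) abort("each class needs >= 2 subjects")
  n <- nrow(X)
  m <- ncol(X)
  X <- scale(X)
  X[, !is.finite(colSums(X))] <- 0
  N_grid <- sort(unique(pmin(config$N_grid %||% seq_len(m), m)))
  gam_grid <- if (config$kernel == "linear") config$gamma_grid[1] else
    config$gamma_grid
  full_rank <- if (config$leakage_mode == "full_sample") {
    rank_features(f_score(X, y))
  }
  dims <- c(length(N_grid), length(config$C_grid), length(gam_grid))
  correct <- array(0L, dim = c(n, dims))
  dvals <- array(NA_real_, dim = c(n, dims))
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (nlevels(droplevels(ytr)) < 2) abort("degenerate single-class fold")
    ranked <- if (config$leakage_mode == "nested") {
      rank_features(f_score(X[-i, , drop = FALSE], ytr))
    } else {
      full_rank
    }
    for (a in seq_along(N_grid)) {
      feats <- ranked[seq_len(N_grid[a])]
      Xtr <- X[-i, feats, drop = FALSE]
      Xte <- X[i, feats, drop = FALSE]
      for (b in seq_along(config$C_grid)) {
        for (g in seq_along(gam_grid)) {
          out <- svm_predict(Xtr, ytr, Xte, config$kernel,
                             config$C_grid[b], gam_grid[g])
          correct[i, a, b, g] <- as.integer(out$pred == y[i])
          dvals[i, a, b, g] <- out$dv
        }
      }
    }
  }
  acc <- apply(correct, c(2, 3, 4), mean)
  # ties -> smallest N, then C, then gamma: first index in this array order
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2], best[, 3])[1], , drop = FALSE]
  tab <- tidyr::expand_grid(gamma = gam_grid, cost = config$C_grid,
                            n_features = N_grid)[, 3:1]
  tab$accuracy <- 100 * as.numeric(acc)
  structure(list(
    best_n = N_grid[best[1]],
    best_cost = config$C_grid[best[2]],
    best_gamma = gam_grid[best[3]],
    accuracy = 100 * acc[best],
    predictions = factor(levels(y)[ifelse(
      correct[, best[1], best[2], best[3]] == 1L, as.integer(y),
      3L - as.integer(y))], levels = levels(y)),
    decision_values = dvals[, best[1], best[2], best[3]],
    y = y,
    accuracy_table = tab,
    config = config
  ), class = "loocv_fit")
}

#' Classifier performance from pooled held-out predictions
#'
#' Accuracy (percent) from the 0-threshold predictions, sensitivity and
#' specificity with respect to the positive class (first level of `truth`),
#' rank-statistic AUC over the pooled LOOCV decision values (ties count
#' half), and the Youden-optimal cut-off on the pooled ROC.
#'
#' @param predictions Factor of held-out predicted labels.
#' @param decision_values Held-out decision values (larger = more positive).
#' @param truth Factor of true labels (two classes present).
#' @return One-row tibble: accuracy, sensitivity, specificity, auc, cutoff.
#' @export
evaluate_classifier <- function(predictions, decision_values, truth) {
  truth <- droplevels(as.factor(truth))
  if (nlevels(truth) != 2) abort("AUC undefined for single-class truth")
  pos <- levels(truth)[1]
  is_pos <- truth == pos
  acc <- 100 * mean(predictions == truth)
  sens <- mean(predictions[is_pos] == pos)
  spec <- mean(predictions[!is_pos] != pos)
  r <- rank(decision_values)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(decision_values))
  youden <- vapply(cuts, function(t) {
    mean(decision_values[is_pos] >= t) + mean(decision_values[!is_pos] < t) - 1
  }, 0)
  tibble::tibble(accuracy = acc, sensitivity = sens, specificity = spec,
                 auc = auc, cutoff = cuts[which.max(youden)])
}

#' Permutation test of classification accuracy
#'
#' Re-runs the protocol on label-shuffled data `n_permutations` times and
#' returns the add-one permutation p-value
#' `(1 + #(permuted >= observed)) / (1 + n_permutations)`.
#'
#' @param X,y As in [loocv_search()].
#' @param config A [classifier_config()]; `permutation_mode = "full"` re-runs
#'   the whole selection + grid search per permutation, `"fixed"` reuses
#'   `fixed_triple`.
#' @param observed Observed LOOCV accuracy (percent).
#' @param fixed_triple For `"fixed"` mode: list(n, cost, gamma) to reuse.
#' @return List: `p`, `permuted` (accuracies, percent).
#' @export
permutation_test <- function(X, y, config, observed, fixed_triple = NULL) {
  B <- config$n_permutations
  stopifnot(B >= 1)
  cfg <- config
  if (cfg$permutation_mode == "fixed") {
    if (is.null(fixed_triple)) abort("fixed mode needs fixed_triple")
    cfg$N_grid <- fixed_triple$n
    cfg$C_grid <- fixed_triple$cost
    cfg$gamma_grid <- fixed_triple$gamma
  }
  perm <- vapply(seq_len(B), function(b) {
    set.seed(derive_seed(config$seed, b, salt = 29L))
    yp <- sample(y)
    if (min(table(yp)) < 2) return(NA_real_)
    loocv_search(X, yp, cfg)$accuracy
  }, 0)
  perm <- perm[is.finite(perm)]
  list(p = (1 + sum(perm >= observed)) / (1 + length(perm)), permuted = perm)
}

# Signed per-feature weights of the winning model, refit on all subjects.
# Linear kernel: w = t(coefs) %*% SV exactly. RBF: permutation-importance
# proxy (drop in refit training accuracy when the feature is shuffled),
# signed by the direction of the class-mean difference.
weight_map <- function(X, y, feats, config, best_cost, best_gamma,
                       n_shuffles = 5L) {
  Xs <- X[, feats, drop = FALSE]
  fit <- e1071::svm(Xs, y, kernel = svm_kernel(config$kernel),
                    cost = best_cost, gamma = best_gamma, scale = FALSE)
  if (config$kernel == "linear") {
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    # e1071's coefs are oriented toward its internal first class
    first <- strsplit(colnames(attr(
      predict(fit, Xs[1, , drop = FALSE], decision.values = TRUE),
      "decision.values"))[1], "/", fixed = TRUE)[[1]][1]
    if (!identical(first, levels(y)[1])) w <- -w
  } else {
    base <- mean(predict(fit, Xs) == y)
    sgn <- sign(colMeans(Xs[y == levels(y)[1], , drop = FALSE]) -
                  colMeans(Xs[y != levels(y)[1], , drop = FALSE]))
    w <- vapply(seq_along(feats), function(k) {
      drop <- vapply(seq_len(n_shuffles), function(s) {
        set.seed(derive_seed(config$seed, k, salt = 31L + s))
        Xp <- Xs
        Xp[, k] <- sample(Xp[, k])
        base - mean(predict(fit, Xp) == y)
      }, 0)
      mean(drop)
    }, 0) * sgn
  }
  tibble::tibble(edge = feats, weight = w)
}

#' Full per-state classification protocol
#'
#' Assembles the feature matrix from the entered subjects' vectorized
#' per-state mean FNC for one group pair and one state, then runs F-score
#' ranking, the LOOCV grid search, performance evaluation, the permutation
#' test, and the signed weight map of the winning model.
#'
#' @param state_fnc Tibble from [cohort_state_fnc()].
#' @param pair Two group labels; `pair[1]` is the positive class.
#' @param state State index.
#' @param config A [classifier_config()].
#' @return An object of class `classifier_result`: list with `summary` (one-
#'   row tibble mirroring a performance-table row: state, group pair, n per
#'   group, best N / C / gamma, accuracy, AUC, sensitivity, specificity,
#'   cutoff, permutation p, evaluable) and `weights` (tibble: edge, weight),
#'   plus the underlying `fit`.
#' @export
classify_state <- function(state_fnc, pair, state,
                           config = classifier_config()) {
  stopifnot(length(pair) == 2)
  sub <- state_fnc[state_fnc$state == state & state_fnc$entered &
                     state_fnc$group %in% pair, ]
  n_a <- sum(sub$group == pair[1])
  n_b <- sum(sub$group == pair[2])
  not_eval <- function(reason) {
    structure(list(summary = tibble::tibble(
      state = state, group_a = pair[1], group_b = pair[2],
      n_a = n_a, n_b = n_b, best_n = NA_integer_, best_cost = NA_real_,
      best_gamma = NA_real_, accuracy = NA_real_, auc = NA_real_,
      sensitivity = NA_real_, specificity = NA_real_, cutoff = NA_real_,
      perm_p = NA_real_, evaluable = FALSE, reason = reason
    ), weights = NULL, fit = NULL), class = "classifier_result")
  }
  # leave-one-out needs two same-class training subjects after holdout
  if (n_a < 3 || n_b < 3) {
    return(not_eval("a group has fewer than 3 entered subjects in this state"))
  }
  X <- do.call(rbind, sub$fnc_vec)
  y <- factor(sub$group, levels = pair)
  fit <- loocv_search(X, y, config)
  perf <- evaluate_classifier(fit$predictions, fit$decision_values, y)
  pp <- if (config$n_permutations > 0) {
    permutation_test(X, y, config, fit$accuracy,
                     fixed_triple = list(n = fit$best_n, cost = fit$best_cost,
                                         gamma = fit$best_gamma))$p
  } else {
    NA_real_
  }
  Xs <- scale(X)
  Xs[, !is.finite(colSums(Xs))] <- 0
  feats <- rank_features(f_score(Xs, y))[seq_len(fit$best_n)]
  wmap <- weight_map(Xs, y, feats, config, fit$best_cost, fit$best_gamma)
  structure(list(summary = tibble::tibble(
    state = state, group_a = pair[1], group_b = pair[2],
    n_a = n_a, n_b = n_b, best_n = fit$best_n, best_cost = fit$best_cost,
    best_gamma = fit$best_gamma, accuracy = perf$accuracy, auc = perf$auc,
    sensitivity = perf$sensitivity, specificity = perf$specificity,
    cutoff = perf$cutoff, perm_p = pp, evaluable = TRUE, reason = NA_character_
  ), weights = wmap, fit = fit), class = "classifier_result")
}

#' Classification table over states and group pairs
#'
#' Runs [classify_state()] for every requested state and group pair and
#' stacks the summary rows into one performance table.
#'
#' @param state_fnc Tibble from [cohort_state_fnc()].
#' @param pairs List of 2-vectors of group labels.
#' @param states Integer vector of states (default: all present).
#' @param config A [classifier_config()].
#' @return Tibble of summary rows (one per pair x state).
#' @export
classify_all_states <- function(state_fnc, pairs,
                                states = sort(unique(state_fnc$state)),
                                config = classifier_config()) {
  purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(states, function(s) {
      classify_state(state_fnc, pr, s, config)$summary
    })
  })
}
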