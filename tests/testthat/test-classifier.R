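test_that("F-score matches the hand formula and its invariances", {
  X <- matrix(c(2, 4, 0, 2), ncol = 1)
  y <- factor(c("pos", "pos", "neg", "neg"), levels = c("pos", "neg"))
  expect_equal(f_score(X, y), 0.5)
  # equal means and spreads: no separation
  X0 <- matrix(c(1, 3, 1, 3), ncol = 1)
  expect_equal(f_score(X0, y), 0)
  # scale invariance
  set.seed(1)
  X2 <- matrix(rnorm(20), ncol = 2)
  y2 <- rep(c("a", "b"), each = 5)
  expect_equal(f_score(X2 * 10, y2), f_score(X2, y2))
  # zero within-class variance with separated means: Inf sentinel
  Xc <- matrix(c(1, 1, 0, 0), ncol = 1)
  expect_warning(s <- f_score(Xc, y), "sentinel")
  expect_equal(s, Inf)
})

test_that("feature ranking is descending with deterministic ties", {
  expect_equal(rank_features(c(0.1, 0.5, 0.3)), c(2, 3, 1))
  expect_equal(rank_features(c(0.2, 0.2)), c(1, 2))
  expect_equal(rank_features(c(0.3, Inf, 0.9))[1], 2)
})

test_that("a separable single feature yields a perfect small model", {
  y <- rep(c("a", "b"), each = 5)
  X <- cbind(ifelse(y == "a", 1, -1), matrix(rnorm(10 * 4), 10, 4))
  cfg <- classifier_config(kernel = "linear", C_grid = c(0.1, 1),
                           gamma_grid = 0.1, N_grid = c(1, 3),
                           n_permutations = 0, seed = 2)
  # the separable feature has zero within-class variance: sentinel warning
  fit <- suppressWarnings(loocv_search(X, y, cfg))
  expect_equal(fit$accuracy, 100)
  expect_equal(fit$best_n, 1)
  expect_equal(levels(fit$predictions), c("a", "b"))
})

test_that("null features stay within binomial noise of chance accuracy", {
  accs <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(40 * 50), 40, 50)
    y <- rep(c("a", "b"), each = 20)
    cfg <- classifier_config(C_grid = c(0.1, 1, 10), gamma_grid = c(0.01, 0.1),
                             N_grid = c(1, 2, 5, 10), n_permutations = 0,
                             seed = s)
    loocv_search(X, y, cfg)$accuracy
  }, 0)
  se <- sqrt(0.25 / 40) * 100
  expect_lt(abs(mean(accs) - 50), 3 * se)
})

test_that("full-sample feature scoring is more optimistic than nested", {
  diff_by_seed <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    X <- matrix(rnorm(16 * 30), 16, 30)
    y <- rep(c("a", "b"), each = 8)
    base <- classifier_config(C_grid = 1, gamma_grid = 0.1, N_grid = c(1, 3),
                              n_permutations = 0, seed = s)
    faith <- base
    faith$leakage_mode <- "full_sample"
    loocv_search(X, y, faith)$accuracy - loocv_search(X, y, base)$accuracy
  }, 0)
  expect_gte(mean(diff_by_seed), 0)
})

test_that("evaluation metrics match enumerations and the concordance oracle", {
  y <- factor(c("p", "p", "n", "n"), levels = c("p", "n"))
  pred <- factor(c("p", "n", "n", "n"), levels = c("p", "n"))
  perf <- evaluate_classifier(pred, c(1.0, 0.2, 0.4, 0.1), y)
  expect_equal(perf$accuracy, 75)
  expect_equal(perf$sensitivity, 0.5)
  expect_equal(perf$specificity, 1.0)
  expect_equal(perf$auc, 0.75)
  expect_equal(perf$auc, auc_concordance_oracle(c(1.0, 0.2), c(0.4, 0.1)))

  perfect <- evaluate_classifier(
    factor(c("p", "p", "n"), levels = c("p", "n")),
    c(2, 1.5, -1),
    factor(c("p", "p", "n"), levels = c("p", "n"))
  )
  expect_equal(perfect$auc, 1)
  expect_error(
    evaluate_classifier(pred[1:2], c(1, 2), factor(c("p", "p"))),
    "single-class"
  )
})

test_that("rank AUC equals brute-force concordance counting with ties", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    y <- factor(sample(c("p", "n"), n, replace = TRUE, prob = c(.5, .5)),
                levels = c("p", "n"))
    if (length(unique(y)) < 2) next
    dec <- round(rnorm(n), 1) # rounding forces ties
    perf <- evaluate_classifier(y, dec, y)
    oracle <- auc_concordance_oracle(dec[y == "p"], dec[y == "n"])
    expect_equal(perf$auc, oracle)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  y <- factor(rep(c("p", "n"), each = 15), levels = c("p", "n"))
  dec <- rnorm(30) + (y == "p")
  perf <- evaluate_classifier(y, dec, y)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = dec, levels = c("n", "p"), direction = "<",
    quiet = TRUE)))
  expect_equal(perf$auc, ref, tolerance = 1e-12)
})

test_that("permutation p follows the add-one formula", {
  set.seed(5)
  X <- matrix(rnorm(12 * 4), 12, 4)
  X[1:6, 1] <- X[1:6, 1] + 4
  y <- rep(c("a", "b"), each = 6)
  cfg <- classifier_config(kernel = "linear", C_grid = 1, gamma_grid = 0.1,
                           N_grid = 1, n_permutations = 19, seed = 6)
  fit <- loocv_search(X, y, cfg)
  pt <- permutation_test(X, y, cfg, fit$accuracy)
  expect_equal(pt$p, (1 + sum(pt$permuted >= fit$accuracy)) /
                 (1 + length(pt$permuted)))
  expect_gt(pt$p, 0)
  expect_lte(pt$p, 1)
  # observed at floor: every permutation ties or beats it
  pt_floor <- permutation_test(X, y, cfg, 0)
  expect_equal(pt_floor$p, 1)
})

test_that("classify_state recovers planted edges and flags absent groups", {
  set.seed(7)
  n_half <- 15
  m <- 66 # C = 12
  planted <- c(3, 11, 25, 40, 58)
  base <- matrix(rnorm(2 * n_half * m), 2 * n_half, m)
  base[seq_len(n_half), planted] <- base[seq_len(n_half), planted] + 1.6
  sfnc <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:(2 * n_half)),
    group = rep(c("SA", "NS"), each = n_half),
    state = 1L, entered = TRUE,
    fnc_vec = lapply(seq_len(2 * n_half), function(i) base[i, ])
  )
  cfg <- classifier_config(kernel = "linear", C_grid = c(0.1, 1),
                           gamma_grid = 0.1, N_grid = c(5, 10, 20),
                           n_permutations = 0, seed = 8)
  res <- classify_state(sfnc, c("SA", "NS"), 1, cfg)
  expect_true(res$summary$evaluable)
  expect_gte(res$summary$auc, 0.9)
  top10 <- res$weights$edge[order(-abs(res$weights$weight))][1:10]
  expect_gte(length(intersect(top10, planted)), 3)
  # determinism of the full result
  res2 <- classify_state(sfnc, c("SA", "NS"), 1, cfg)
  expect_identical(res$summary, res2$summary)
  expect_identical(res$weights, res2$weights)

  # a group entirely absent from the state
  sfnc_absent <- sfnc
  sfnc_absent$entered[sfnc_absent$group == "NS"] <- FALSE
  flag <- classify_state(sfnc_absent, c("SA", "NS"), 1, cfg)
  expect_false(flag$summary$evaluable)
  expect_match(flag$summary$reason, "fewer than")
  expect_equal(nrow(tidy(flag)), 0)
})

test_that("identical generative groups rarely reach permutation significance", {
  ps <- vapply(1:10, function(s) {
    set.seed(3000 + s)
    X <- matrix(rnorm(16 * 12), 16, 12)
    y <- rep(c("a", "b"), each = 8)
    cfg <- classifier_config(C_grid = 1, gamma_grid = 0.1, N_grid = c(1, 3),
                             n_permutations = 19, seed = s)
    fit <- loocv_search(X, y, cfg)
    permutation_test(X, y, cfg, fit$accuracy)$p
  }, 0)
  expect_gte(mean(ps > 0.05), 0.8)
})
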