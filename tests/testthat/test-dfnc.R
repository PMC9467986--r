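test_that("window counts follow the floor((T - w) / step) convention", {
  expect_equal(nrow(sliding_windows(230, 50, 1)), 180)
  w1 <- sliding_windows(51, 50, 1)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(1, 50))
  w3 <- sliding_windows(10, 4, 2)
  expect_equal(w3$start, c(1, 3, 5))
  expect_equal(w3$end, c(4, 6, 8))
  expect_error(sliding_windows(40, 50), "exceeds")
})

test_that("window counts match brute-force enumeration over a random sweep", {
  set.seed(1)
  for (case in 1:200) {
    T <- sample(10:400, 1)
    w <- sample(2:min(T, 80), 1)
    step <- sample(1:5, 1)
    n_brute <- sum(seq(0, T, by = step) < T - w)
    if (n_brute < 1) {
      expect_error(sliding_windows(T, w, step))
    } else {
      expect_equal(nrow(sliding_windows(T, w, step)), n_brute)
    }
  }
})

test_that("window covariance honors tapers and flags degenerate columns", {
  set.seed(2)
  x <- cbind(a = rnorm(60), b = 0)
  x[, 2] <- 2 * x[, 1]
  S <- window_covariance(x, 1, 60)
  expect_equal(S[1, 2], sd(x[1:60, 1]) * sd(x[1:60, 2]), tolerance = 1e-12)
  expect_equal(cov2cor(S)[1, 2], 1, tolerance = 1e-12)

  y <- matrix(rnorm(5000 * 3), 5000, 3)
  S2 <- window_covariance(y, 1, 5000)
  expect_lt(max(abs(cov2cor(S2)[upper.tri(S2)])), 0.05)

  S3 <- window_covariance(y, 1, 100, weights = rep(7, 100))
  S4 <- window_covariance(y, 1, 100)
  expect_equal(S3, S4, tolerance = 1e-12)

  z <- cbind(rnorm(50), 1)
  expect_equal(attr(window_covariance(z, 1, 50), "degenerate"), 2L)
})

test_that("graphical lasso matches the 2x2 soft-threshold closed form", {
  # closed form for the penalized covariance of a standardized 2x2 problem:
  # off-diagonal soft-thresholded at lambda, diagonal kept
  for (r in c(-0.8, -0.3, 0, 0.25, 0.6, 0.95)) {
    for (lam in c(0, 0.05, 0.2, 0.5, 1)) {
      S <- matrix(c(1, r, r, 1), 2)
      R <- graphical_lasso_fnc(S, lam)
      expect_equal(R[1, 2], sign(r) * max(abs(r) - lam, 0),
                   tolerance = 1e-6)
      expect_equal(diag(R), c(1, 1))
    }
  }
})

test_that("graphical lasso limits: unpenalized and full shrinkage", {
  set.seed(3)
  x <- matrix(rnorm(500 * 6), 500, 6)
  x[, 2] <- x[, 1] * 0.6 + rnorm(500, sd = 0.6)
  S <- cov(x)
  expect_equal(graphical_lasso_fnc(S, 0), cov2cor(S), tolerance = 1e-5)
  expect_equal(graphical_lasso_fnc(S, 50), diag(6), tolerance = 1e-8)
})

test_that("graphical lasso recovers a sparse precision's zeros", {
  set.seed(4)
  Theta <- diag(5)
  Theta[1, 2] <- Theta[2, 1] <- 0.4
  Sigma <- solve(Theta)
  x <- matrix(rnorm(2000 * 5), 2000, 5) %*% chol(Sigma)
  fit <- graphical_lasso(cov(x), 0.05)
  # penalized precision keeps the planted edge and thins true zeros
  expect_gt(abs(fit$theta[1, 2]), 0.1)
  off_true_zero <- abs(fit$theta[upper.tri(Theta) & Theta == 0])
  expect_lt(max(off_true_zero), 0.1)
})

test_that("cross-validated lambda selection is deterministic and exhaustive", {
  set.seed(5)
  Theta <- diag(6) * 2
  Theta[1, 2] <- Theta[2, 1] <- 0.8
  Sigma <- solve(Theta)
  tc <- matrix(rnorm(160 * 6), 160, 6) %*% chol(Sigma)
  p1 <- dfnc_params(window_length = 40, lambda = "cv",
                    lambda_grid = 0.07, seed = 2)
  expect_equal(as.numeric(select_lambda(tc, p1)), 0.07)

  p <- dfnc_params(window_length = 40, lambda = "cv",
                   lambda_grid = c(0.01, 0.05, 0.1, 0.3), seed = 2)
  lam1 <- select_lambda(tc, p)
  lam2 <- select_lambda(tc, p)
  expect_identical(as.numeric(lam1), as.numeric(lam2))
  # selected value attains the optimum of the scored grid (exhaustive check)
  scores <- attr(lam1, "scores")
  expect_equal(as.numeric(lam1), scores$lambda[which.max(scores$cv_loglik)])
  expect_gte(scores$cv_loglik[scores$lambda == as.numeric(lam1)],
             max(scores$cv_loglik) - abs(max(scores$cv_loglik)) * 0.01)
  expect_error(select_lambda(tc, dfnc_params(lambda = "cv",
                                             lambda_grid = numeric(0),
                                             window_length = 40)),
               "empty")
})

test_that("compute_dfnc yields the documented stack shape and values", {
  set.seed(6)
  tc <- matrix(rnorm(230 * 23), 230, 23)
  wf <- compute_dfnc(tc, dfnc_params(lambda = 0.15))
  expect_s3_class(wf, "windowed_fnc")
  expect_equal(dim(wf$z), c(23, 23, 180))
  expect_true(all(is.finite(wf$z)))
  expect_equal(max(abs(apply(wf$z, 3, diag))), 0)
})

test_that("long windows converge to the planted Fisher-z correlation", {
  set.seed(7)
  r <- 0.5
  Sigma <- matrix(c(1, r, r, 1), 2)
  tc <- matrix(rnorm(3000 * 2), 3000, 2) %*% chol(Sigma)
  wf <- compute_dfnc(tc, dfnc_params(window_length = 1000, step = 500,
                                     lambda = 0))
  expect_lt(max(abs(wf$z[1, 2, ] - atanh(r))), 0.1)
  # uncorrelated pair: z stays near 0, and exact 0 maps to exact 0
  expect_equal(fisher_z(0), 0)
})

test_that("edge vectorization is the documented row-major lower triangle", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  expect_equal(vectorize_fnc(m), c(1, 2, 3))
  expect_length(vectorize_fnc(matrix(0, 23, 23)), 253)
  set.seed(8)
  z <- matrix(rnorm(100), 10, 10)
  z <- z + t(z)
  diag(z) <- 0
  expect_equal(devectorize_fnc(vectorize_fnc(z), 10), z)
  bad <- z
  bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(vectorize_fnc(bad), "symmetric")
  em <- edge_index_map(4)
  expect_equal(em$i, c(2, 3, 3, 4, 4, 4))
  expect_equal(em$j, c(1, 1, 2, 1, 2, 3))
})

test_that("Fisher z is odd and strictly increasing", {
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_true(is.finite(fisher_z(1)) && is.finite(fisher_z(-1)))
})

test_that("regularization beats the raw covariance in the short-window regime", {
  set.seed(9)
  covs <- make_state_covariances(23, 1, seed = 2)
  Sigma <- covs$covariances[[1]]
  R <- chol(Sigma)
  err <- function(est) norm(est - Sigma, "F")
  raw <- numeric(20)
  reg <- numeric(20)
  for (i in 1:20) {
    x <- matrix(rnorm(50 * 23), 50, 23) %*% R
    S <- cov(x)
    raw[i] <- err(cov2cor(S))
    reg[i] <- err(graphical_lasso_fnc(S, 0.1))
  }
  expect_lt(mean(reg), mean(raw))
})
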