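test_that("state covariances are SPD with unit diagonal and distinct", {
  sc <- make_state_covariances(23, 6, seed = 1)
  expect_equal(sc$K, 6)
  for (m in sc$covariances) {
    expect_equal(dim(m), c(23, 23))
    expect_equal(max(abs(m - t(m))), 0)
    expect_equal(unname(diag(m)), rep(1, 23))
    expect_gt(min(eigen(m, symmetric = TRUE)$values), 0)
  }
  d <- utils::combn(6, 2, function(ij) {
    norm(sc$covariances[[ij[1]]] - sc$covariances[[ij[2]]], "F")
  })
  expect_gt(min(d), 0)
})

test_that("independence request gives the identity matrix", {
  spec <- list(list(blocks = list(1L, 2L, 3L), within = 0, between = 0))
  sc <- make_state_covariances(3, 1, block_spec = spec, seed = 1)
  # zero off-diagonal request: only the symmetric jitter separates it from
  # the identity, and SPD repair keeps the diagonal exactly 1
  expect_equal(sc$covariances[[1]], diag(3), tolerance = 0.1)
  expect_equal(unname(diag(sc$covariances[[1]])), rep(1, 3))
})

test_that("mixed-sign strengths survive the eigendecomposition oracle", {
  spec <- list(
    list(blocks = list(1:2, 3:4), within = 0.6, between = 0.1),
    list(blocks = list(1:2, 3:4), within = -0.3, between = 0)
  )
  sc <- make_state_covariances(4, 2, block_spec = spec, seed = 2)
  for (m in sc$covariances) {
    expect_gt(min(eigen(m, symmetric = TRUE)$values), 0)
  }
})

test_that("impossible correlation strengths fail naming the state", {
  spec <- list(
    list(blocks = list(1:2, 3:4), within = 0.5, between = 0),
    list(blocks = list(1:2, 3:4), within = 1.2, between = 0)
  )
  expect_error(make_state_covariances(4, 2, block_spec = spec), "state 2")
})

test_that("an identity transition chain never leaves its initial state", {
  covs <- make_state_covariances(4, 2, seed = 3)
  design <- group_design(tibble::tibble(group = "G", n = 1), covs,
                         list(G = diag(2)), T = 100, TR = 2,
                         noise_sd = 0, seed = 4)
  sim <- simulate_subject(design, "G", subject_seed = 9)
  expect_length(unique(sim$states), 1)
  expect_equal(dim(sim$tc), c(100, 4))
})

test_that("symmetric half-half chain hits its stationary occupancy", {
  covs <- make_state_covariances(3, 2, seed = 5)
  design <- group_design(tibble::tibble(group = "G", n = 1), covs,
                         list(G = markov_transition(2, 0.5)),
                         T = 10000, TR = 2, noise_sd = 0, seed = 6)
  sim <- simulate_subject(design, "G", subject_seed = 21)
  ft <- mean(sim$states == 1)
  expect_lt(abs(ft - 0.5), 0.02)
})

test_that("long noiseless single-state run recovers the planted covariance", {
  covs <- make_state_covariances(5, 1, seed = 7)
  design <- group_design(tibble::tibble(group = "G", n = 1), covs,
                         list(G = matrix(1, 1, 1)), T = 5000, TR = 2,
                         noise_sd = 0, seed = 8)
  sim <- simulate_subject(design, "G", subject_seed = 3)
  # time courses are standardized, so compare correlation structures
  expect_lt(norm(cor(sim$tc) - cov2cor(covs$covariances[[1]]), "F"), 0.1)
})

test_that("cohorts are reproducible and perturbation effects reach the FNC", {
  sc <- small_cohort()
  coh1 <- simulate_cohort(sc$design)
  coh2 <- simulate_cohort(sc$design)
  expect_identical(coh1$time_courses, coh2$time_courses)
  expect_identical(coh1$ground_truth$states, coh2$ground_truth$states)
  expect_equal(nrow(coh1$manifest), 10)
  expect_length(coh1$time_courses, 10)

  # planted -0.3 covariance delta on edge (1,2) of state 3 for group B.
  # Oracle: emissions are iid given the state, so pooling all time points
  # whose true state is 3 estimates that state's correlation; isotropic
  # noise of variance s^2 attenuates a unit-diagonal covariance entry to
  # cov / (1 + s^2) exactly.
  coh <- sc$cohort
  att <- 1 + sc$design$noise_sd^2
  covB3 <- sc$covs$covariances[[3]]
  covB3[1, 2] <- covB3[1, 2] - 0.3
  expected <- atanh(sc$covs$covariances[[3]][1, 2] / att) -
    atanh(covB3[1, 2] / att)
  edge_z <- function(grp) {
    ids <- coh$manifest$subject_id[coh$manifest$group == grp]
    pooled <- do.call(rbind, lapply(ids, function(id) {
      coh$time_courses[[id]][coh$ground_truth$states[[id]] == 3, 1:2]
    }))
    atanh(cor(pooled[, 1], pooled[, 2]))
  }
  observed <- edge_z("A") - edge_z("B")
  expect_equal(observed, expected, tolerance = 0.5) # relative: +-50%
  expect_gt(observed, 0)
})

test_that("duplicate group labels are rejected", {
  covs <- make_state_covariances(3, 2, seed = 1)
  expect_error(
    group_design(tibble::tibble(group = c("A", "A"), n = c(2, 2)), covs,
                 markov_transition(2, 0.9)),
    "duplicate"
  )
})

test_that("perturbations that break positive definiteness are rejected", {
  covs <- make_state_covariances(4, 1, seed = 1)
  pert <- tibble::tibble(group = "A", state = 1L, i = 1L, j = 2L, delta = -5)
  expect_error(
    group_design(tibble::tibble(group = "A", n = 2), covs,
                 markov_transition(1, 1), perturbations = pert),
    "positive definiteness"
  )
})

test_that("voxel simulation is the outer product plus noise", {
  out <- simulate_voxel_data(matrix(c(1, 2), 2, 1), matrix(c(3, 4), 2, 1),
                             noise_sd = 0)
  expect_equal(out, matrix(c(3, 6, 4, 8), 2, 2))
  maps <- matrix(rnorm(40 * 3), 40, 3)
  tcs <- matrix(rnorm(30 * 3), 30, 3)
  noiseless <- simulate_voxel_data(maps, tcs, noise_sd = 0)
  expect_equal(sum(svd(noiseless)$d > 1e-8), 3)
  expect_error(simulate_voxel_data(maps, tcs[, 1:2], 0), "component count")
})

test_that("generated time courses are standardized per component", {
  coh <- small_cohort()$cohort
  tc <- coh$time_courses[[1]]
  expect_equal(unname(colMeans(tc)), rep(0, ncol(tc)), tolerance = 1e-12)
  expect_equal(unname(apply(tc, 2, sd)), rep(1, ncol(tc)), tolerance = 1e-12)
})

test_that("cohort round-trips through the delimited text format", {
  dir <- withr::local_tempdir()
  coh <- write_cohort(small_cohort()$cohort, dir)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man$subject_id, coh$manifest$subject_id)
  tcs <- read_time_courses(man)
  expect_equal(tcs[[3]], coh$time_courses[[3]], tolerance = 1e-12,
               ignore_attr = TRUE)
})
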