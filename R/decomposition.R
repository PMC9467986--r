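#' Two-stage PCA reduction of a multi-subject voxel dataset
#'
#' Stage one reduces each subject's temporal dimension to `n_subject_pcs`
#' principal components; the reduced data are concatenated along the
#' temporal dimension and reduced again to `n_group_pcs`. The per-subject
#' and group projection bases are stored for back-reconstruction, and the
#' retained-variance fraction of each stage is reported.
#'
#' @param subject_mats Named list of voxels x T matrices (equal voxel
#'   counts; T may vary).
#' @param n_subject_pcs Temporal components kept per subject.
#' @param n_group_pcs Components kept at the group stage
#'   (<= subjects * n_subject_pcs).
#' @return List of class `two_stage_pca`: `reduced` (n_group_pcs x voxels
#'   matrix, the ICA input), `subject_basis` (list of T_i x n_subject_pcs),
#'   `group_basis` (list of n_subject_pcs x n_group_pcs blocks, one per
#'   subject), `variance_stage1` (per subject), `variance_stage2`,
#'   `variance_retained` (product of stage fractions), ids.
#' @export
two_stage_pca <- function(subject_mats, n_subject_pcs, n_group_pcs) {
  M <- length(subject_mats)
  stopifnot(M >= 1, n_group_pcs <= M * n_subject_pcs)
  ids <- names(subject_mats) %||% sprintf("sub-%03d", seq_len(M))
  reduced <- vector("list", M)
  basis <- vector("list", M)
  v1 <- numeric(M)
  for (i in seq_len(M)) {
    X <- as.matrix(subject_mats[[i]]) # voxels x T
    X <- sweep(X, 1, rowMeans(X))
    sv <- svd(X, nu = 0, nv = min(dim(X)))
    rank_i <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
    if (rank_i < n_subject_pcs) {
      abort(sprintf(
        "subject %s: rank %d below the requested %d subject PCs",
        ids[i], rank_i, n_subject_pcs))
    }
    basis[[i]] <- sv$v[, seq_len(n_subject_pcs), drop = FALSE] # T x n1
    reduced[[i]] <- X %*% basis[[i]]                           # voxels x n1
    v1[i] <- sum(sv$d[seq_len(n_subject_pcs)]^2) / sum(sv$d^2)
  }
  cat_red <- do.call(cbind, reduced) # voxels x (M * n1)
  sv2 <- svd(cat_red, nu = 0, nv = min(dim(cat_red)))
  rank2 <- sum(sv2$d > max(dim(cat_red)) * .Machine$double.eps * sv2$d[1])
  if (rank2 < n_group_pcs) {
    abort(sprintf("group stage: rank %d below the requested %d group PCs",
                  rank2, n_group_pcs))
  }
  Vg <- sv2$v[, seq_len(n_group_pcs), drop = FALSE] # (M*n1) x n2
  G <- cat_red %*% Vg                               # voxels x n2
  v2 <- sum(sv2$d[seq_len(n_group_pcs)]^2) / sum(sv2$d^2)
  group_blocks <- lapply(seq_len(M), function(i) {
    Vg[((i - 1) * n_subject_pcs + 1):(i * n_subject_pcs), , drop = FALSE]
  })
  structure(list(reduced = t(G), subject_basis = setNames(basis, ids),
                 group_basis = setNames(group_blocks, ids),
                 variance_stage1 = setNames(v1, ids), variance_stage2 = v2,
                 variance_retained = mean(v1) * v2,
                 n_subject_pcs = n_subject_pcs, n_group_pcs = n_group_pcs,
                 ids = ids),
            class = "two_stage_pca")
}

#' Infomax independent component analysis
#'
#' Natural-gradient Infomax with the logistic nonlinearity (the
#' Bell-Sejnowski formulation) on whitened data, suited to super-Gaussian
#' sources. Iterates until the relative weight-update norm drops below
#' `tol` (`converged = TRUE`) or `max_iter` is reached (the current solution
#' is returned with `converged = FALSE`); on numerical divergence the
#' learning rate is annealed (halved and restarted) a few times before
#' failing.
#'
#' @param X Mixtures x samples matrix (rows are mixed signals).
#' @param n_components Number of components (<= rows of X).
#' @param learning_rate Initial natural-gradient step size.
#' @param max_iter Iteration cap.
#' @param tol Relative convergence tolerance on the weight update.
#' @param seed Seed for the random orthogonal initial weights.
#' @return List of class `infomax_ica`: `sources` (n_components x samples,
#'   unit variance), `mixing` (rows-of-X x n_components), `unmixing`,
#'   `iterations`, `converged`, `seed`.
#' @export
infomax_ica <- function(X, n_components, learning_rate = 0.1,
                        max_iter = 500L, tol = 1e-4, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(n_components <= nrow(X))
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  # whiten to n_components dimensions
  e <- eigen(tcrossprod(Xc) / n, symmetric = TRUE)
  keep <- seq_len(n_components)
  if (any(e$values[keep] <= 0)) abort("data rank below n_components")
  K <- diag(1 / sqrt(e$values[keep]), n_components) %*% t(e$vectors[, keep])
  Z <- K %*% Xc
  p <- n_components
  for (anneal in 0:7) {
    lr <- learning_rate / 2^anneal
    set.seed(seed)
    W0 <- matrix(rnorm(p * p), p, p)
    W <- qr.Q(qr(W0))
    converged <- FALSE
    iters <- 0L
    diverged <- FALSE
    G_prev <- NULL
    step <- lr
    for (it in seq_len(max_iter)) {
      U <- W %*% Z
      Y <- 1 / (1 + exp(-U))
      G <- (diag(p) + ((1 - 2 * Y) %*% t(U)) / n) %*% W
      if (!all(is.finite(G))) {
        diverged <- TRUE
        break
      }
      # anneal the step when the natural-gradient direction turns by > 60
      # degrees (the classic Infomax annealing rule)
      if (!is.null(G_prev)) {
        cosang <- sum(G * G_prev) / (norm(G, "F") * norm(G_prev, "F"))
        if (is.finite(cosang) && cosang < 0.5) step <- step * 0.9
      }
      G_prev <- G
      dW <- step * G
      W <- W + dW
      iters <- it
      if (norm(dW, "F") / norm(W, "F") < tol) {
        converged <- TRUE
        break
      }
    }
    if (!diverged) {
      S <- W %*% Z
      sc <- sqrt(rowMeans(S^2))
      S <- S / sc
      unmix <- (W / sc) %*% K
      mixing <- pinv_svd(unmix)
      return(structure(list(sources = S, mixing = mixing, unmixing = unmix,
                            whitening = K, iterations = iters,
                            converged = converged, seed = seed,
                            learning_rate = lr),
                       class = "infomax_ica"))
    }
  }
  abort(paste("Infomax diverged even after annealing the learning rate;",
              "reduce learning_rate or pre-reduce the data"))
}

# Moore-Penrose pseudoinverse via SVD (small matrices only).
pinv_svd <- function(A, tol = sqrt(.Machine$double.eps)) {
  sv <- svd(A)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Stability resampling of the Infomax decomposition
#'
#' Repeats the ICA `n_runs` times with different random initializations,
#' clusters the pooled components by absolute correlation (average-linkage
#' agglomeration), and returns one centrotype per cluster with a stability
#' index: mean within-cluster similarity minus mean similarity to components
#' outside the cluster, clamped to the unit interval. Reproducible
#' decompositions give indices near 1.
#'
#' @inheritParams infomax_ica
#' @param n_runs Number of ICA repetitions (>= 2).
#' @param same_seed Use one seed for every run (degenerate check; default
#'   FALSE).
#' @return List of class `ica_stability`: `sources` (centrotypes,
#'   n_components x samples), `stability` (per component, between 0 and 1),
#'   `cluster` (membership of every run component), `runs`.
#' @export
stability_resample <- function(X, n_components, n_runs = 10L, seed = 1L,
                               learning_rate = 0.1, max_iter = 500L,
                               tol = 1e-4, same_seed = FALSE) {
  stopifnot(n_runs >= 2)
  runs <- lapply(seq_len(n_runs), function(r) {
    infomax_ica(X, n_components, learning_rate, max_iter, tol,
                seed = if (same_seed) seed else derive_seed(seed, r, 41L))
  })
  comps <- do.call(rbind, lapply(runs, `[[`, "sources"))
  if (nrow(comps) < n_components) {
    abort("fewer run components than n_components; increase n_runs")
  }
  sim <- abs(cor(t(comps)))
  sim[!is.finite(sim)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = n_components)
  stability <- numeric(n_components)
  centro <- matrix(NA_real_, n_components, ncol(comps))
  for (k in seq_len(n_components)) {
    inside <- which(cl == k)
    outside <- which(cl != k)
    intra <- if (length(inside) > 1) {
      mean(sim[inside, inside][upper.tri(matrix(0, length(inside),
                                                length(inside)))])
    } else 1
    extra <- if (length(outside) > 0) mean(sim[inside, outside]) else 0
    stability[k] <- min(max(intra - extra, 0), 1)
    score <- rowSums(sim[inside, inside, drop = FALSE])
    centro[k, ] <- comps[inside[which.max(score)], ]
  }
  ord <- order(stability, decreasing = TRUE)
  structure(list(sources = centro[ord, , drop = FALSE],
                 stability = stability[ord],
                 cluster = cl, runs = runs, n_runs = n_runs, seed = seed),
            class = "ica_stability")
}

#' Back-reconstruct subject time courses and maps
#'
#' Projects the group unmixing through the stored two-stage PCA reductions
#' to recover each subject's component time courses (z-scored per component)
#' and subject-specific spatial maps (least-squares fit of the time courses
#' to the subject's data).
#'
#' @param sources n_components x voxels group spatial sources (from
#'   [infomax_ica()] or [stability_resample()] run on `pca$reduced`).
#' @param mixing n_group_pcs x n_components mixing matrix for those sources.
#' @param pca The [two_stage_pca()] object the sources were computed from.
#' @param subject_mats The original voxels x T matrices (for subject maps).
#' @return List of class `group_decomposition`: `time_courses` (named list
#'   of T x n_components z-scored matrices), `subject_maps` (named list of
#'   n_components x voxels), `group_maps` (= `sources`).
#' @export
back_reconstruct <- function(sources, mixing, pca, subject_mats) {
  stopifnot(inherits(pca, "two_stage_pca"))
  if (nrow(mixing) != pca$n_group_pcs) {
    abort("mixing matrix does not match this two_stage_pca reduction")
  }
  ids <- pca$ids
  tcs <- list()
  maps <- list()
  for (i in seq_along(ids)) {
    TC <- pca$subject_basis[[i]] %*% pca$group_basis[[i]] %*% mixing
    TC <- scale(TC)
    attr(TC, "scaled:center") <- NULL
    attr(TC, "scaled:scale") <- NULL
    colnames(TC) <- sprintf("IC%02d", seq_len(ncol(TC)))
    tcs[[ids[i]]] <- TC
    X <- as.matrix(subject_mats[[i]])
    X <- sweep(X, 1, rowMeans(X))
    maps[[ids[i]]] <- t(qr.solve(TC, t(X)))
  }
  structure(list(time_courses = tcs, subject_maps = maps,
                 group_maps = sources),
            class = "group_decomposition")
}

#' Screen components by their low/high frequency power ratio
#'
#' Noise components carry relatively more high-frequency power. For each
#' component the periodogram power below `band_split_hz` is divided by the
#' power at or above it; components with a ratio below `ratio_threshold` are
#' rejected. Constant time courses have an undefined ratio and are rejected
#' as degenerate.
#'
#' @param tc T x C component time-course matrix.
#' @param TR Sampling interval in seconds (> 0).
#' @param band_split_hz Split frequency in Hz (0 < split < Nyquist).
#' @param ratio_threshold Minimum low/high ratio to retain.
#' @return Tibble: component, ratio, retained, reason.
#' @export
screen_components <- function(tc, TR, band_split_hz = 0.1,
                              ratio_threshold = 1) {
  stopifnot(TR > 0)
  nyquist <- 1 / (2 * TR)
  if (band_split_hz <= 0 || band_split_hz >= nyquist) {
    abort(sprintf("band_split_hz must lie in (0, %.3f)", nyquist))
  }
  tc <- as.matrix(tc)
  Tn <- nrow(tc)
  freqs <- seq_len(floor(Tn / 2)) / (Tn * TR)
  out <- purrr::map_dfr(seq_len(ncol(tc)), function(j) {
    x <- tc[, j]
    if (sd(x) < 1e-12) {
      return(tibble::tibble(component = j, ratio = NA_real_,
                            retained = FALSE, reason = "degenerate"))
    }
    pw <- Mod(stats::fft(x - mean(x)))[2:(floor(Tn / 2) + 1)]^2
    low <- sum(pw[freqs < band_split_hz])
    high <- sum(pw[freqs >= band_split_hz])
    ratio <- low / max(high, .Machine$double.eps)
    tibble::tibble(component = j, ratio = ratio,
                   retained = ratio >= ratio_threshold,
                   reason = ifelse(ratio >= ratio_threshold, NA_character_,
                                   "low/high power ratio below threshold"))
  })
  out
}
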