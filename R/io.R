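#' Write a cohort to delimited text files
#'
#' Writes one tab-separated time-course file per subject (T rows x C columns,
#' header = component IDs), a `manifest.tsv` (subject_id, group, TR, path),
#' and the ground truth (`ground_truth_states.tsv`, one row per subject, and
#' `ground_truth_transitions.yaml`).
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return The cohort, invisibly, with `manifest$path` filled in.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(cohort$manifest$subject_id, ".tsv"))
  for (i in seq_along(paths)) {
    write.table(cohort$time_courses[[i]], paths[i], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  cohort$manifest$path <- paths
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- cohort$ground_truth
  states <- do.call(rbind, gt$states)
  states <- cbind(subject_id = names(gt$states), as.data.frame(states))
  write.table(states, file.path(dir, "ground_truth_states.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(
    list(transition = lapply(gt$transition, function(m) apply(m, 1, c,
                                                              simplify = FALSE)),
         perturbations = if (is.null(gt$perturbations)) list() else
           as.list(gt$perturbations)),
    file.path(dir, "ground_truth_transitions.yaml")
  )
  invisible(cohort)
}

#' Read a cohort manifest
#'
#' @param path Path to a tab-separated manifest with columns subject_id,
#'   group, TR, path (time-course file paths resolved relative to the
#'   manifest's directory when not absolute).
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  m <- tibble::as_tibble(read.delim(path, sep = "\t",
                                    stringsAsFactors = FALSE))
  need <- c("subject_id", "group", "TR", "path")
  if (!all(need %in% names(m))) {
    abort(paste("manifest must have columns:", paste(need, collapse = ", ")))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Read per-subject time-course matrices listed in a manifest
#'
#' @param manifest A tibble from [read_manifest()].
#' @return A named list of T x C numeric matrices keyed by subject_id.
#' @export
read_time_courses <- function(manifest) {
  tcs <- lapply(manifest$path, function(p) {
    as.matrix(read.delim(p, sep = "\t", check.names = FALSE))
  })
  setNames(tcs, manifest$subject_id)
}
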