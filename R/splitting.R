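# Sequence-group-aware partitioning. All records sharing a peptide sequence
# travel together, so identical sequences can never appear on both sides of a
# split or fold boundary.

.group_keys <- function(task) {
  if (inherits(task, "acp_ovr_task")) task$records$sequence
  else if (is.character(task)) task
  else stop("task must be an acp_ovr_task or a character vector of sequences")
}

#' Group-aware train/test split
#'
#' Shuffles the unique sequences (groups) of a task with the given seed and
#' assigns whole groups to the test side until it holds the group count
#' closest to \code{test_fraction} of all groups. Because assignment is keyed
#' by sequence, permuting the record order does not change the partition.
#' When a draw leaves one side without both classes, the draw is repeated (up
#' to \code{max_attempts} permutations from the same seeded stream) and a
#' warning is emitted if coverage is still not achieved.
#'
#' @param task An \code{acp_ovr_task} (or character vector of sequences, in
#'   which case class coverage is not checked).
#' @param test_fraction Fraction of groups to hold out, in (0, 1); default 0.2.
#' @param seed Integer seed; default 42.
#' @param max_attempts Redraw budget for class coverage (default 25).
#' @return An object of class \code{acp_split}: list with integer
#'   \code{train_idx}, \code{test_idx}, \code{test_groups} (sequences),
#'   \code{seed}, \code{test_fraction}.
#' @export
group_train_test_split <- function(task, test_fraction = 0.2, seed = 42L,
                                   max_attempts = 25L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  keys <- .group_keys(task)
  groups <- sort(unique(keys))
  if (length(groups) < 5L) stop("need at least 5 distinct sequence groups")
  n_test <- max(1L, min(length(groups) - 1L, round(test_fraction * length(groups))))
  labels <- if (inherits(task, "acp_ovr_task")) task$labels else NULL

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chosen <- NULL
  for (attempt in seq_len(max_attempts)) {
    perm <- sample(groups)
    test_groups <- perm[seq_len(n_test)]
    test_idx <- which(keys %in% test_groups)
    train_idx <- setdiff(seq_along(keys), test_idx)
    if (is.null(labels) ||
        (length(unique(labels[test_idx])) == 2L &&
         length(unique(labels[train_idx])) == 2L)) {
      chosen <- list(train_idx, test_idx, test_groups)
      break
    }
  }
  if (is.null(chosen)) {
    warning("could not achieve class coverage in both partitions after ",
            max_attempts, " attempts; using the last draw")
    chosen <- list(train_idx, test_idx, test_groups)
  }
  structure(
    list(train_idx = chosen[[1L]], test_idx = chosen[[2L]],
         test_groups = chosen[[3L]], seed = seed,
         test_fraction = test_fraction),
    class = "acp_split"
  )
}

#' @export
print.acp_split <- function(x, ...) {
  cat(sprintf("Group-aware split (seed %d): %d train / %d test records, %d test groups\n",
              x$seed, length(x$train_idx), length(x$test_idx),
              length(x$test_groups)))
  invisible(x)
}

#' Group-aware k-fold plan
#'
#' Distributes unique sequences across k folds as evenly as possible
#' (shuffled with the seed, then dealt round-robin). Every group lands in
#' exactly one fold.
#'
#' @param task An \code{acp_ovr_task} or character vector of sequences.
#' @param k Number of folds.
#' @param seed Integer seed; default 42.
#' @return An object of class \code{acp_fold_plan}: list with \code{k},
#'   \code{fold_assignment} (named integer vector, one entry per group) and
#'   \code{fold_idx} (list of k integer vectors of record indices).
#' @export
group_kfold <- function(task, k = 5L, seed = 42L) {
  keys <- .group_keys(task)
  groups <- sort(unique(keys))
  if (length(groups) < k) stop("fewer groups (", length(groups), ") than folds (", k, ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(groups)
  assignment <- stats::setNames(rep_len(seq_len(k), length(groups)), perm)
  assignment <- assignment[groups]  # key by sorted group name
  fold_idx <- lapply(seq_len(k), function(f) {
    which(keys %in% names(assignment)[assignment == f])
  })
  structure(list(k = k, fold_assignment = assignment, fold_idx = fold_idx,
                 seed = seed),
            class = "acp_fold_plan")
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
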