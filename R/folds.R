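#' Build class-balanced, leakage-free evaluation folds
#'
#' Subjects are permuted with the given seed, then each test fold receives
#' `round(count_c / n_folds)` subjects of class `c` (nearest integer, halves
#' away from zero), drawn without replacement so test sets are pairwise
#' disjoint across folds.  If a class is exhausted before the last fold, the
#' last fold takes whatever remains of that class.  The validation set of each
#' fold is drawn (seeded per fold) from the non-test remainder with the same
#' per-class sizes as that fold's test set; everything else is training.
#'
#' With `exhaust_last_fold = TRUE`, subjects left over after integer rounding
#' are appended to the final fold's test set so every subject is tested
#' exactly once; by default they are simply never tested.
#'
#' @param labels binary (0/1) vector over subjects.
#' @param n_folds number of test folds.
#' @param seed integer seed controlling the permutation and validation draws.
#' @param exhaust_last_fold append leftover subjects to the last test fold.
#' @return A `fold_plan`: list with `folds` (each `list(train, val, test)` of
#'   integer subject indices) and `n_folds`.
#' @export
make_balanced_folds <- function(labels, n_folds, seed = 0L,
                                exhaust_last_fold = FALSE) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_dircon("labels must be binary 0/1")
  n_folds <- as.integer(n_folds)
  S <- length(labels)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < n_folds))
    stop_dircon("each class must have at least n_folds subjects")
  perm <- with_seed(seed, sample.int(S))
  by_class <- lapply(c(0L, 1L), function(cl) perm[labels[perm] == cl])
  sizes <- vapply(by_class, function(v)
    as.integer(round_half_up(length(v) / n_folds)), 1L)

  folds <- vector("list", n_folds)
  used <- lapply(by_class, function(v) 0L)  # consumed count per class
  for (f in seq_len(n_folds)) {
    test <- integer(0)
    tsize <- integer(2)
    for (cl in 1:2) {
      avail <- length(by_class[[cl]]) - used[[cl]]
      take <- min(sizes[cl], avail)
      if (f == n_folds && exhaust_last_fold) take <- avail
      if (take > 0L)
        test <- c(test, by_class[[cl]][used[[cl]] + seq_len(take)])
      used[[cl]] <- used[[cl]] + take
      tsize[cl] <- take
    }
    rest <- setdiff(perm, test)
    # remove other folds' test subjects from nothing: folds are built on the
    # full remainder; validation mirrors the fold's per-class test sizes
    val <- integer(0)
    for (cl in 1:2) {
      pool <- rest[labels[rest] == (cl - 1L)]
      nv <- min(tsize[cl], length(pool))
      if (nv > 0L)
        val <- c(val, with_seed(seed + 7919L * f + cl,
                                sample(pool, nv)))
    }
    train <- setdiff(rest, val)
    folds[[f]] <- list(train = sort(train), val = sort(val), test = sort(test))
  }
  structure(list(folds = folds, n_folds = n_folds, seed = seed,
                 exhaust_last_fold = exhaust_last_fold),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds\n", x$n_folds))
  for (f in seq_len(min(x$n_folds, 5L))) {
    fd <- x$folds[[f]]
    cat(sprintf("  fold %d: train %d / val %d / test %d\n",
                f, length(fd$train), length(fd$val), length(fd$test)))
  }
  if (x$n_folds > 5L) cat("  ...\n")
  invisible(x)
}
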