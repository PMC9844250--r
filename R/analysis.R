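# Downstream analyses on estimated connectivity: correlation baseline,
# logistic comparisons, group block statistics, edge extraction, dynamic
# states, temporal-attention experiments.

#' Pearson functional connectivity per subject
#'
#' Classic undirected baseline: the `N x N` Pearson correlation matrix of
#' each subject's node series.  With `normalize01` the affine map
#' `r -> (r + 1) / 2` puts values on the `[0, 1]` scale of the attention
#' matrices.  Zero-variance nodes yield undefined correlations; those entries
#' are set to 0 (0.5 after mapping) with a warning.
#'
#' @param ds a [timecourse_dataset()] (`T >= 3`).
#' @param normalize01 map correlations from `[-1, 1]` to `[0, 1]`.
#' @return List of `N x N` matrices, one per subject (diagonal 1).
#' @export
pearson_fnc <- function(ds, normalize01 = FALSE) {
  S <- dim(ds$data)[1L]; N <- dim(ds$data)[2L]; TT <- dim(ds$data)[3L]
  if (TT < 3L) stop_dircon("need at least 3 timepoints for correlations")
  out <- vector("list", S)
  names(out) <- ds$subject_ids
  warned <- FALSE
  for (s in seq_len(S)) {
    x <- matrix(ds$data[s, , ], N)
    sdv <- apply(x, 1L, stats::sd)
    r <- suppressWarnings(stats::cor(t(x)))
    if (any(sdv == 0)) {
      warned <- TRUE
      r[is.na(r)] <- 0
    }
    diag(r) <- 1
    if (normalize01) r <- (r + 1) / 2
    out[[s]] <- r
  }
  if (warned)
    warning("zero-variance node(s): undefined correlations set to 0")
  out
}

# Fit a ridge logistic model on train, choose lambda on validation AUC,
# return test scores.  Features: matrix subjects x p.
ridge_logistic_fold <- function(feat, labels, fd) {
  xtr <- feat[fd$train, , drop = FALSE]; ytr <- labels[fd$train]
  if (length(unique(ytr)) < 2L) return(NULL)
  fit <- glmnet::glmnet(xtr, factor(ytr, levels = c(0L, 1L)),
                        family = "binomial", alpha = 0, nlambda = 30L)
  pv <- stats::predict(fit, feat[fd$val, , drop = FALSE], type = "link")
  yval <- labels[fd$val]
  val_auc <- apply(pv, 2L, function(sc)
    if (length(unique(yval)) < 2L) 0.5 else evaluate_auc(sc, yval))
  best <- which.max(val_auc)
  pt <- stats::predict(fit, feat[fd$test, , drop = FALSE], type = "link")
  pt[, best]
}

#' Fold-wise regularized logistic baseline
#'
#' Trains a ridge-penalized logistic model per fold on flattened per-subject
#' connectivity features (correlation matrices or aggregated attention
#' matrices), choosing the penalty on the fold's validation set, and reports
#' the test AUCs aggregated as mean / max / min / sd.
#'
#' @param features numeric matrix `subjects x p` (or a list of per-subject
#'   matrices, flattened internally).
#' @param labels binary labels.
#' @param plan a `fold_plan`.
#' @param folds which folds to use.
#' @return List with `aucs` (one per usable fold) and `summary`
#'   (mean/max/min/sd).
#' @export
linear_baseline <- function(features, labels, plan,
                            folds = seq_len(plan$n_folds)) {
  if (is.list(features))
    features <- t(vapply(features, as.numeric,
                         numeric(length(as.numeric(features[[1L]])))))
  assert_finite(features, "features")
  labels <- as.integer(labels)
  aucs <- numeric(0)
  for (f in folds) {
    fd <- plan$folds[[f]]
    ytest <- labels[fd$test]
    if (length(unique(ytest)) < 2L) {
      warning(sprintf("fold %d skipped: single-class test set", f))
      next
    }
    sc <- ridge_logistic_fold(features, labels, fd)
    if (is.null(sc)) {
      warning(sprintf("fold %d skipped: single-class training set", f))
      next
    }
    aucs <- c(aucs, evaluate_auc(sc, ytest))
  }
  list(aucs = aucs,
       summary = list(mean = mean(aucs), max = max(aucs), min = min(aucs),
                      sd = stats::sd(aucs)))
}

block_mean <- function(mat, nodes_a, nodes_b = nodes_a) {
  sub <- mat[nodes_a, nodes_b, drop = FALSE]
  if (identical(nodes_a, nodes_b)) {
    off <- row(sub) != col(sub)
    if (!any(off)) stop_dircon("block has no off-diagonal entries")
    mean(sub[off])
  } else mean(sub)
}

#' Group statistics over network blocks of connectivity matrices
#'
#' For each comparison, the per-subject mean over the requested block is
#' computed on each side (a within-network block is all ordered node pairs
#' inside the network, diagonal excluded; `network = NULL` means all
#' off-diagonal entries), then the two sides are compared with both a Welch
#' two-sample t-test and a Mann-Whitney U test.  Each comparison yields two
#' rows (one per test), mirroring the usual two-row table layout.
#'
#' @param matrices list of per-subject `N x N` matrices.
#' @param groups vector assigning each subject to a group (any labels).
#' @param partition a [network_partition()] covering all nodes.
#' @param comparisons list of lists with elements `group1`, `network1`,
#'   `group2`, `network2` (`networkX = NULL` for the whole matrix) and an
#'   optional `label`.
#' @param paired use paired tests (both sides must then be the same
#'   subjects in the same order).
#' @return data.frame with columns comparison, test, p_value, mean1, mean2.
#' @export
network_block_stats <- function(matrices, groups, partition, comparisons,
                                paired = FALSE) {
  N <- nrow(matrices[[1L]])
  if (length(partition$assignment) != N)
    stop_dircon("partition does not cover all nodes")
  side_values <- function(group, network) {
    subj <- which(groups == group)
    if (!is.null(network)) {
      nodes <- which(partition$assignment == network)
      if (length(nodes) == 0L)
        stop_dircon(sprintf("network '%s' has no nodes", network))
      if (length(nodes) < 2L)
        stop_dircon(sprintf("network '%s' block is empty (one node)", network))
      vapply(matrices[subj], block_mean, 0, nodes_a = nodes)
    } else {
      vapply(matrices[subj], function(m) mean(m[row(m) != col(m)]), 0)
    }
  }
  rows <- NULL
  for (cmp in comparisons) {
    v1 <- side_values(cmp$group1, cmp$network1)
    v2 <- side_values(cmp$group2, cmp$network2)
    lab <- cmp$label %||% sprintf("%s_%s vs %s_%s",
                                  cmp$group1, cmp$network1 %||% "All",
                                  cmp$group2, cmp$network2 %||% "All")
    if (isTRUE(all.equal(v1, v2))) {
      pt <- 1; pu <- 1          # identical samples: no difference
    } else {
      pt <- stats::t.test(v1, v2, paired = paired)$p.value
      pu <- suppressWarnings(
        stats::wilcox.test(v1, v2, paired = paired)$p.value)
    }
    rows <- rbind(rows,
                  data.frame(comparison = lab, test = "t-test", p_value = pt,
                             mean1 = mean(v1), mean2 = mean(v2)),
                  data.frame(comparison = lab, test = "mannwhitneyu",
                             p_value = pu, mean1 = mean(v1), mean2 = mean(v2)))
  }
  rows
}

#' Significance stars for p-value bands
#'
#' @param p numeric p-values.
#' @return Character vector: `ns` for p > 0.10 up to `*****` for p < 0.0001.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 0.005, 0.01, 0.05, 0.10, Inf),
      labels = c("*****", "****", "***", "**", "*", "ns"),
      right = FALSE) |> as.character()
}

#' Extract the strongest directed edges of a connectivity matrix
#'
#' Off-diagonal entries at or above the `1 - quantile` quantile of all
#' off-diagonal entries, as a directed edge list under the convention that
#' `W[i, j]` is the influence of node `j` on node `i` (edge `j -> i`).
#'
#' @param matrix `N x N` connectivity matrix.
#' @param quantile fraction of off-diagonal edges to keep (e.g. 0.1 for the
#'   top 10%); 1 returns all off-diagonal edges.
#' @param partition optional [network_partition()]; adds source/target
#'   network columns.
#' @return data.frame with `source`, `target`, `weight`, `direction`
#'   (`"upper"` if source < target, `"lower"` otherwise), sorted by
#'   decreasing weight.
#' @export
top_edges <- function(matrix, quantile = 0.1, partition = NULL) {
  if (quantile <= 0 || quantile > 1) stop_dircon("quantile must be in (0, 1]")
  N <- nrow(matrix)
  off <- which(row(matrix) != col(matrix))
  w <- matrix[off]
  thr <- if (quantile == 1) -Inf else
    stats::quantile(w, 1 - quantile, names = FALSE, type = 7)
  keep <- off[w >= thr]
  tgt <- row(matrix)[keep]; src <- col(matrix)[keep]
  out <- data.frame(source = src, target = tgt, weight = matrix[keep],
                    direction = ifelse(src < tgt, "upper", "lower"))
  if (!is.null(partition)) {
    out$source_network <- partition$assignment[out$source]
    out$target_network <- partition$assignment[out$target]
  }
  out[order(-out$weight), , drop = FALSE]
}

#' Asymmetry of a connectivity matrix
#'
#' Mean absolute difference between a matrix and its transpose over the
#' off-diagonal entries.  Correlation matrices give exactly 0; attention
#' matrices are generally asymmetric, and this diagnostic quantifies how
#' much directional information they carry.
#'
#' @param mat `N x N` connectivity matrix.
#' @return Non-negative scalar.
#' @export
dc_asymmetry <- function(mat) {
  off <- row(mat) != col(mat)
  mean(abs(mat - t(mat))[off])
}

flatten_dcs <- function(dcs) {
  # list of [N, N, T] arrays -> (sum T) x N^2 matrix + subject/timepoint ids
  mats <- lapply(dcs, function(a) {
    TT <- dim(a)[3L]
    t(vapply(seq_len(TT), function(t) as.numeric(a[, , t]),
             numeric(dim(a)[1L] * dim(a)[2L])))
  })
  X <- do.call(rbind, mats)
  subj <- rep(seq_along(dcs), vapply(mats, nrow, 1L))
  list(X = X, subject = subj)
}

#' Cluster per-timepoint connectivity matrices into dynamic states
#'
#' k-means over all subjects' flattened `W_t`; each timepoint is assigned to
#' one of `k` recurring connectivity states.  Per-group occupancy is the
#' fraction of that group's timepoints spent in each state; the per-state
#' group difference is assessed by a two-sample test over per-subject
#' time-in-state fractions.
#'
#' @param dcs list of per-subject connectivity series `[N, N, T]`.
#' @param k number of states.
#' @param seed RNG seed for the k-means starts.
#' @param groups optional per-subject group labels for occupancy.
#' @param test `"wilcox"` or `"t"` for the per-state group comparison.
#' @param max_retry re-seeding attempts if a cluster comes back empty.
#' @return A `state_model`: `centroids` (`[N, N, k]`), `assignments` (list
#'   per subject), `occupancy` (group x state), `state_tests` (p-values),
#'   `sizes`, `k`.
#' @export
kmeans_states <- function(dcs, k, seed = 0L, groups = NULL,
                          test = c("wilcox", "t"), max_retry = 5L) {
  test <- match.arg(test)
  fl <- flatten_dcs(dcs)
  if (nrow(fl$X) < k) stop_dircon("fewer timepoints than states requested")
  km <- NULL
  for (r in seq_len(max_retry)) {
    km <- with_seed(seed + r - 1L,
                    suppressWarnings(stats::kmeans(fl$X, centers = k,
                                                   nstart = 5L,
                                                   iter.max = 50L)))
    if (all(km$size > 0L)) break
    km <- NULL
  }
  if (is.null(km)) stop_dircon("k-means produced an empty cluster repeatedly")
  N <- dim(dcs[[1L]])[1L]
  centroids <- array(t(km$centers), c(N, N, k))
  assignments <- split(km$cluster, fl$subject)
  res <- list(centroids = centroids, assignments = assignments, k = k,
              sizes = km$size, withinss = km$tot.withinss)
  if (!is.null(groups)) {
    glev <- unique(groups)
    occ <- t(vapply(glev, function(g) {
      cl <- unlist(assignments[which(groups == g)])
      tabulate(cl, k) / length(cl)
    }, numeric(k)))
    rownames(occ) <- as.character(glev)
    res$occupancy <- occ
    if (length(glev) == 2L) {
      frac <- t(vapply(assignments, function(a) tabulate(a, k) / length(a),
                       numeric(k)))
      res$state_tests <- vapply(seq_len(k), function(j) {
        a <- frac[groups == glev[1L], j]; b <- frac[groups == glev[2L], j]
        if (isTRUE(all.equal(a, b))) return(1)
        if (test == "wilcox")
          suppressWarnings(stats::wilcox.test(a, b)$p.value)
        else stats::t.test(a, b)$p.value
      }, 0)
    }
  }
  structure(res, class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d, state sizes: %s\n", x$k,
              paste(x$sizes, collapse = ", ")))
  if (!is.null(x$occupancy)) {
    cat("occupancy:\n"); print(round(x$occupancy, 3))
  }
  invisible(x)
}

#' Choose the number of dynamic states by the elbow method
#'
#' Computes the within-cluster sum of squares over `k_range` and returns the
#' knee: the `k` maximizing the discrete second difference of the curve.  If
#' the curve is flat (no curvature), the smallest `k` is returned with a
#' warning.
#'
#' @param dcs list of per-subject connectivity series `[N, N, T]`.
#' @param k_range integer vector of candidate `k` (>= 3 values).
#' @param seed RNG seed.
#' @return The chosen `k`; the curve is attached as attribute `"wss"`.
#' @export
elbow_k <- function(dcs, k_range = 2:8, seed = 0L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) stop_dircon("k_range needs at least 3 values")
  fl <- flatten_dcs(dcs)
  wss <- vapply(k_range, function(k)
    with_seed(seed + k,
              suppressWarnings(stats::kmeans(fl$X, k, nstart = 5L,
                                             iter.max = 50L))$tot.withinss),
    0)
  d2 <- diff(wss, differences = 2L)    # indexed by k_range[2..(m-1)]
  if (max(abs(d2)) < .Machine$double.eps^0.5 * max(abs(wss), 1)) {
    warning("flat within-cluster curve; returning smallest k")
    k <- k_range[1L]
  } else {
    k <- k_range[which.max(d2) + 1L]
  }
  attr(k, "wss") <- stats::setNames(wss, k_range)
  k
}

#' Stability of temporal attention across randomly-seeded trials
#'
#' For each subject, the mean pairwise Pearson correlation between the
#' attention vectors obtained under different training seeds.  Constant
#' vectors (undefined correlation) are excluded pairwise with a warning.
#'
#' @param alphas list per subject of `n_seeds x T` matrices (or a list of
#'   per-seed vectors).
#' @return Numeric vector of per-subject stability scores; plot-ready
#'   per-subject mean/min/max bands are attached as attribute `"bands"`.
#' @export
attention_stability <- function(alphas) {
  score_one <- function(a) {
    if (is.list(a)) a <- do.call(rbind, a)
    ns <- nrow(a)
    if (ns < 2L) stop_dircon("need at least 2 seeds per subject")
    keep <- apply(a, 1L, stats::sd) > 0
    if (!all(keep)) warning("constant attention vector(s) excluded")
    a <- a[keep, , drop = FALSE]
    if (nrow(a) < 2L) return(NA_real_)
    cm <- stats::cor(t(a))
    mean(cm[upper.tri(cm)])
  }
  scores <- vapply(alphas, score_one, 0)
  bands <- lapply(alphas, function(a) {
    if (is.list(a)) a <- do.call(rbind, a)
    data.frame(t = seq_len(ncol(a)), mean = colMeans(a),
               lo = apply(a, 2L, min), hi = apply(a, 2L, max))
  })
  attr(scores, "bands") <- bands
  scores
}

#' Classification value of high- vs low-attention timepoints
#'
#' For each subject the `fraction` of timepoints with the highest (and,
#' separately, the lowest) attention weights are selected; the selected
#' `W_t` are averaged into one matrix per subject, flattened, and a
#' ridge-penalized logistic model is trained and tested fold-wise on each
#' selection.  If the selected timepoints carry the discriminative signal,
#' the top selection should retain most of the full-data AUC while the
#' bottom selection should not.
#'
#' @param dcs list of per-subject connectivity series `[N, N, T]`.
#' @param alphas list (or matrix `S x T`) of per-subject attention vectors.
#' @param labels binary labels.
#' @param plan a `fold_plan`.
#' @param fraction fraction of timepoints selected (in `(0, 0.5]`).
#' @param folds which folds to use.
#' @return List with `top` and `bottom` [linear_baseline()] results.
#' @export
topk_timepoint_experiment <- function(dcs, alphas, labels, plan,
                                      fraction = 0.05,
                                      folds = seq_len(plan$n_folds)) {
  if (fraction <= 0 || fraction > 0.5)
    stop_dircon("fraction must be in (0, 0.5]")
  if (is.matrix(alphas)) alphas <- asplit(alphas, 1L)
  TT <- dim(dcs[[1L]])[3L]
  nsel <- max(1L, floor(fraction * TT))
  if (fraction * TT < 1)
    warning("fraction selects < 1 timepoint; using 1")
  sel_feats <- function(top) {
    t(mapply(function(a, al) {
      ord <- order(al, decreasing = top)
      idx <- ord[seq_len(nsel)]
      as.numeric(apply(a[, , idx, drop = FALSE], c(1L, 2L), mean))
    }, dcs, alphas))
  }
  list(top = linear_baseline(sel_feats(TRUE), labels, plan, folds),
       bottom = linear_baseline(sel_feats(FALSE), labels, plan, folds))
}

#' Adjusted Rand index between two labelings
#'
#' Standard chance-corrected agreement between two partitions of the same
#' items; used to score recovered dynamic states against planted regimes.
#'
#' @param a,b integer label vectors of equal length.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
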