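# Downstream analysis operations.

test_that("correlation baseline matches the covariance formula", {
  set.seed(41)
  ds <- random_dataset(S = 1L, N = 3L, TT = 5L)
  fnc <- pearson_fnc(ds)[[1]]
  x <- matrix(ds$data[1, , ], 3)
  for (i in 1:3) for (j in 1:3) {
    r <- sum((x[i, ] - mean(x[i, ])) * (x[j, ] - mean(x[j, ]))) /
      sqrt(sum((x[i, ] - mean(x[i, ]))^2) * sum((x[j, ] - mean(x[j, ]))^2))
    expect_equal(fnc[i, j], r, tolerance = 1e-9)
  }
  expect_equal(diag(fnc), rep(1, 3))
})

test_that("0-1 normalization maps the correlation endpoints correctly", {
  ds <- random_dataset(S = 1L, N = 3L, TT = 8L)
  ds$data[1, 2, ] <- -ds$data[1, 1, ]          # exact anti-correlation
  fnc <- pearson_fnc(ds, normalize01 = TRUE)[[1]]
  expect_equal(fnc[1, 2], 0, tolerance = 1e-12)
  expect_equal(diag(fnc), rep(1, 3))
  expect_true(all(fnc >= 0 & fnc <= 1))
})

test_that("zero-variance nodes yield neutral correlations with a warning", {
  ds <- random_dataset(S = 1L, N = 3L, TT = 8L)
  ds$data[1, 3, ] <- 2
  expect_warning(fnc <- pearson_fnc(ds, normalize01 = TRUE), "zero-variance")
  expect_equal(fnc[[1]][1, 3], 0.5)
})

test_that("logistic baseline separates separable features and not noise", {
  set.seed(42)
  n <- 120L
  labels <- rep(c(0L, 1L), each = n / 2)
  plan <- make_balanced_folds(labels, 4L, seed = 2L)
  sep <- cbind(labels + rnorm(n, sd = 0.05), matrix(rnorm(n * 5), n))
  r1 <- linear_baseline(sep, labels, plan)
  expect_equal(r1$summary$mean, 1.0)
  noise <- matrix(rnorm(n * 6), n)
  r0 <- linear_baseline(noise, labels, plan)
  expect_lt(abs(r0$summary$mean - 0.5), 0.2)
})

test_that("block statistics match the textbook test statistics", {
  pb <- planted_block_matrices()
  part <- network_partition(rep(c("DM", "SM"), c(3, 5)))
  out <- network_block_stats(pb$matrices, pb$groups, part,
                             list(list(group1 = "A", network1 = "DM",
                                       group2 = "B", network2 = "DM")))
  # recompute the per-subject block means and reference tests directly
  nodes <- 1:3
  v <- vapply(pb$matrices, function(m) {
    sub <- m[nodes, nodes]; mean(sub[row(sub) != col(sub)])
  }, 0)
  a <- v[pb$groups == "A"]; b <- v[pb$groups == "B"]
  expect_equal(out$p_value[out$test == "t-test"],
               stats::t.test(a, b)$p.value, tolerance = 1e-9)
  expect_equal(out$p_value[out$test == "mannwhitneyu"],
               stats::wilcox.test(a, b)$p.value, tolerance = 1e-9)
  expect_equal(out$mean1[1], mean(a)); expect_equal(out$mean2[1], mean(b))
})

test_that("identical sides give p = 1", {
  pb <- planted_block_matrices()
  part <- network_partition(rep(c("DM", "SM"), c(3, 5)))
  out <- network_block_stats(pb$matrices, pb$groups, part,
                             list(list(group1 = "A", network1 = NULL,
                                       group2 = "A", network2 = NULL)))
  expect_equal(out$p_value, c(1, 1))
})

test_that("significance stars follow the printed p-value bands", {
  expect_equal(significance_stars(c(0.2, 0.07, 0.03, 0.007, 0.001, 1e-5)),
               c("ns", "*", "**", "***", "****", "*****"))
})

test_that("top edge extraction is an exact sort of off-diagonal entries", {
  set.seed(43)
  m <- matrix(stats::runif(16), 4, 4)
  ed <- top_edges(m, quantile = 0.25)
  off <- m[row(m) != col(m)]
  expect_equal(nrow(ed), 3L)
  expect_setequal(ed$weight, sort(off, decreasing = TRUE)[1:3])
  # the direction convention: W[i, j] is the edge j -> i
  expect_equal(m[cbind(ed$target, ed$source)], ed$weight)
  # degenerate quantile returns all off-diagonal edges
  expect_equal(nrow(top_edges(m, quantile = 1)), 12L)
})

test_that("a symmetric matrix yields a direction-symmetric edge list", {
  set.seed(44)
  m <- matrix(stats::runif(25), 5, 5); m <- (m + t(m)) / 2
  ed <- top_edges(m, quantile = 0.5)
  key <- paste(pmin(ed$source, ed$target), pmax(ed$source, ed$target))
  expect_true(all(table(key) == 2L))
})

test_that("k-means recovers exactly repeated matrices with zero scatter", {
  set.seed(45)
  protos <- lapply(1:3, function(k) matrix(stats::runif(9), 3, 3))
  dcs <- lapply(1:4, function(s) {
    pick <- sample(1:3, 10, replace = TRUE)
    array(unlist(protos[pick]), c(3, 3, 10))
  })
  sm <- kmeans_states(dcs, k = 3L, seed = 1L,
                      groups = rep(c("a", "b"), each = 2L))
  expect_equal(sm$withinss, 0, tolerance = 1e-12)
  expect_equal(rowSums(sm$occupancy), c(a = 1, b = 1), tolerance = 1e-9)
  expect_true(all(vapply(sm$assignments, length, 1L) == 10L))
})

test_that("the elbow finds a planted number of regimes", {
  set.seed(46)
  protos <- lapply(1:3, function(k) matrix(stats::runif(16, 0, 1), 4, 4))
  dcs <- lapply(1:6, function(s) {
    pick <- sample(1:3, 30, replace = TRUE)
    arr <- array(unlist(protos[pick]), c(4, 4, 30))
    arr + array(rnorm(length(arr), sd = 0.03), dim(arr))
  })
  k <- elbow_k(dcs, k_range = 2:6, seed = 2L)
  expect_equal(as.integer(k), 3L)
  wss <- attr(k, "wss")
  # the knee is the arg-max of the discrete second difference
  expect_equal(as.integer(k), as.integer(names(wss))[
    which.max(diff(wss, differences = 2L)) + 1L])
})

test_that("attention stability scores match mean pairwise correlation", {
  a1 <- c(0.1, 0.5, 0.9, 0.2); a2 <- c(0.2, 0.4, 0.8, 0.3)
  a3 <- c(0.9, 0.1, 0.3, 0.7)
  A <- rbind(a1, a2, a3)
  s <- attention_stability(list(subj = A))
  ref <- mean(c(cor(a1, a2), cor(a1, a3), cor(a2, a3)))
  expect_equal(as.numeric(s), ref, tolerance = 1e-12)
  # identical vectors: perfect stability
  expect_equal(as.numeric(attention_stability(list(s = rbind(a1, a1)))), 1)
  # independent long vectors: near zero
  set.seed(47)
  B <- matrix(stats::runif(5 * 400), 5)
  expect_lt(abs(as.numeric(attention_stability(list(s = B)))), 0.1)
})

test_that("correlation matrices are symmetric; attention matrices need not be", {
  set.seed(51)
  ds <- random_dataset(S = 1L, N = 4L, TT = 12L)
  expect_equal(dc_asymmetry(pearson_fnc(ds)[[1]]), 0, tolerance = 1e-12)
  m <- tiny_model(4L)
  emb <- encode_nodes(matrix(ds$data[1, , ], 4), m)
  W <- estimate_instantaneous_dc(emb, m)
  expect_gt(dc_asymmetry(W[, , 1]), 0)
  # hand check: 2x2 with off-diagonal gap d has asymmetry d
  expect_equal(dc_asymmetry(matrix(c(1, 0.2, 0.7, 1), 2, 2)), 0.5)
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(48)
  a <- sample(1:3, 3000, replace = TRUE)
  b <- sample(1:3, 3000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)
})

test_that("uniform attention makes top and bottom selections equivalent", {
  set.seed(49)
  S <- 24L; N <- 3L; TT <- 10L
  labels <- rep(c(0L, 1L), each = S / 2)
  dcs <- lapply(seq_len(S), function(s)
    array(stats::runif(N * N * TT) + 0.3 * labels[s], c(N, N, TT)))
  alphas <- matrix(0.5, S, TT)
  plan <- make_balanced_folds(labels, 3L, seed = 3L)
  r <- topk_timepoint_experiment(dcs, alphas, labels, plan, fraction = 0.2)
  # ties in alpha: both selections see the same group signal
  expect_equal(r$top$summary$mean, r$bottom$summary$mean, tolerance = 0.15)
  expect_error(
    topk_timepoint_experiment(dcs, alphas, labels, plan, fraction = 0.9),
    "fraction")
})
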