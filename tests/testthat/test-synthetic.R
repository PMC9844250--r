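test_that("identical seeds give bitwise-identical datasets", {
  spec <- benchmark_spec(seed = 5L, n_nodes = 6L, n_time = 30L,
                         n_per_group = 4L, n_delta_edges = 3L, delta = 0.2)
  a <- simulate_var_groups(spec)
  b <- simulate_var_groups(spec)
  expect_identical(a$dataset$data, b$dataset$data)
  c <- simulate_var_groups(benchmark_spec(seed = 6L, n_nodes = 6L,
                                          n_time = 30L, n_per_group = 4L,
                                          n_delta_edges = 3L, delta = 0.2))
  expect_false(identical(a$dataset$data, c$dataset$data))
})

test_that("an empty delta leaves the two groups exchangeable", {
  A <- diag(0.3, 4)
  spec <- synthetic_spec(4L, 20L, 3L, base_adjacency = A, noise_sd = 0.5,
                         seed = 2L)
  sim <- simulate_var_groups(spec)
  expect_identical(sim$ground_truth$A0, sim$ground_truth$A1)
  expect_null(sim$ground_truth$delta_edges)
})

test_that("zero adjacency with unit noise yields near-white series", {
  spec <- synthetic_spec(4L, 500L, 100L, base_adjacency = matrix(0, 4, 4),
                         noise_sd = 1, seed = 7L)
  sim <- simulate_var_groups(spec)
  x <- sim$dataset$data
  ac1 <- mean(apply(x, c(1L, 2L), function(v)
    stats::cor(v[-1L], v[-length(v)])))
  expect_lt(abs(ac1), 0.02)   # Monte-Carlo error at 400 series x T=500
  # generated data satisfies the standardization invariants
  expect_lt(max(abs(apply(x, c(1L, 2L), mean))), 1e-6)
  expect_lt(max(abs(apply(x, c(1L, 2L), stats::var) - 1)), 1e-6)
})

test_that("non-stationary transition matrices are rejected", {
  A <- diag(1.1, 3)
  expect_error(synthetic_spec(3L, 10L, 2L, base_adjacency = A),
               "spectral radius")
  # a delta pushing past the bound is also caught
  B <- diag(0.9, 3)
  expect_error(
    synthetic_spec(3L, 10L, 2L, base_adjacency = B,
                   group_delta_edges = data.frame(source = 1L, target = 1L,
                                                  delta = 0.1)),
    "spectral radius")
})

test_that("dwell probability one freezes each subject in one regime", {
  spec <- regime_benchmark_spec(seed = 1L, n_nodes = 5L, n_time = 40L,
                                n_per_group = 3L, dwell = 1)
  sim <- simulate_regime_switching(spec)
  expect_true(all(apply(sim$regime_labels, 1L,
                        function(z) length(unique(z)) == 1L)))
})

test_that("mean dwell length matches the geometric-distribution value", {
  p <- 0.9
  spec <- regime_benchmark_spec(seed = 3L, n_nodes = 5L, n_time = 500L,
                                n_per_group = 30L, dwell = p)
  sim <- simulate_regime_switching(spec)
  g0 <- sim$regime_labels[sim$dataset$labels == 0L, , drop = FALSE]
  runs <- unlist(apply(g0, 1L, function(z) rle(z)$lengths))
  # censored runs at the scan edges bias the mean down slightly
  expect_equal(mean(runs), 1 / (1 - p), tolerance = 0.15)
})

test_that("planted group occupancies are recovered empirically", {
  spec <- regime_benchmark_spec(seed = 4L, n_nodes = 5L, n_time = 500L,
                                n_per_group = 20L, dwell = 0.9,
                                occupancy1 = 0.8)
  sim <- simulate_regime_switching(spec)
  lab <- sim$dataset$labels
  occ0 <- mean(sim$regime_labels[lab == 0L, ] == 1L)
  occ1 <- mean(sim$regime_labels[lab == 1L, ] == 1L)
  expect_lt(abs(occ0 - 0.5), 0.05)
  expect_lt(abs(occ1 - 0.8), 0.05)
})
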