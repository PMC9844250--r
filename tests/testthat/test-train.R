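# Training-loop behaviour on small problems.

small_training_setup <- function(seed = 31L) {
  spec <- benchmark_spec(seed = seed, n_nodes = 5L, n_time = 20L,
                         n_per_group = 10L, n_delta_edges = 3L)
  sim <- simulate_var_groups(spec)
  plan <- make_balanced_folds(sim$dataset$labels, n_folds = 3L, seed = 1L)
  cfg <- dc_model_config(lstm_hidden = 4L, attn_dim = 3L, n_heads = 1L,
                         max_epochs = 4L, patience = 10L, batch_size = 8L,
                         seed = 7L)
  list(ds = sim$dataset, plan = plan, cfg = cfg)
}

test_that("identical config and seed reproduce identical trials", {
  st <- small_training_setup()
  r1 <- train_dc_model(st$ds, st$plan, st$cfg, folds = 1L)
  r2 <- train_dc_model(st$ds, st$plan, st$cfg, folds = 1L)
  k <- names(r1$models)[1]
  expect_identical(r1$models[[k]]$train_hist, r2$models[[k]]$train_hist)
  expect_identical(r1$models[[k]]$val_hist, r2$models[[k]]$val_hist)
  expect_identical(r1$records$test_auc, r2$records$test_auc)
  e1 <- estimate_connectivity(r1$models[[k]]$model, st$ds, idx = 1:2)
  e2 <- estimate_connectivity(r2$models[[k]]$model, st$ds, idx = 1:2)
  expect_identical(e1[[1]]$W_f, e2[[1]]$W_f)
})

test_that("one record per (fold, seed) pair with AUC in range", {
  st <- small_training_setup()
  rr <- train_dc_model(st$ds, st$plan, st$cfg, n_seeds = 2L, folds = 1:2,
                       keep_models = FALSE)
  expect_equal(nrow(rr$records), 4L)
  expect_equal(rr$records$fold, rep(1:2, each = 2L))
  expect_equal(rr$records$seed, rep(st$cfg$seed + 0:1, 2L))
  expect_true(all(rr$records$test_auc >= 0 & rr$records$test_auc <= 1))
})

test_that("chunked prediction averages per-chunk logits", {
  st <- small_training_setup()
  m <- init_dc_model(5L, st$cfg)
  chunks <- chunk_long_scans(st$ds, 2L)
  manual <- (predict_logits(m, chunks[[1]], idx = 1:4) +
             predict_logits(m, chunks[[2]], idx = 1:4)) / 2
  expect_equal(predict_logits(m, st$ds, idx = 1:4, n_chunks = 2L), manual,
               tolerance = 1e-12)
})

test_that("connectivity estimates are row-stochastic with matching W_f", {
  st <- small_training_setup()
  m <- init_dc_model(5L, st$cfg)
  est <- estimate_connectivity(m, st$ds, idx = 1:3, batch_size = 2L)
  for (e in est) {
    expect_lt(max(abs(apply(e$W, 3L, rowSums) - 1)), 1e-5)
    expect_true(all(e$W >= 0 & e$W <= 1))
    expect_true(all(e$alpha >= 0 & e$alpha <= 1))
    ref <- matrix(0, 5, 5)
    for (t in seq_along(e$alpha)) ref <- ref + e$alpha[t] * e$W[, , t]
    expect_equal(e$W_f, ref, tolerance = 1e-9)
  }
})

test_that("a tampered fold plan with train/test overlap is refused", {
  st <- small_training_setup()
  bad <- st$plan
  bad$folds[[1]]$train <- c(bad$folds[[1]]$train, bad$folds[[1]]$test[1])
  expect_error(train_dc_model(st$ds, bad, st$cfg, folds = 1L))
})

test_that("checkpoints round-trip through disk", {
  m <- tiny_model(4L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m$params, m2$params)
  X <- array(rnorm(2 * 4 * 6), c(2, 4, 6))
  expect_identical(dircon:::dc_forward_batch(m, X)$logits,
                   dircon:::dc_forward_batch(m2, X)$logits)
})
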