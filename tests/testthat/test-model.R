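# Equation-level oracles for every stage of the network, against independent
# brute-force evaluations on hand-set micro-instances.

test_that("zero encoder weights give exactly zero embeddings", {
  m <- zero_params(tiny_model())
  x <- matrix(rnorm(5 * 6), 5, 6)
  emb <- encode_nodes(x, m)
  expect_equal(max(abs(emb)), 0)
})

test_that("one LSTM step matches direct evaluation of the gate equations", {
  # 1 hidden unit, hand-set constants, single step: i, f, g, o, c, h by hand
  wi <- c(0.3, -0.2, 0.5, 0.1)        # input weights per gate (i, f, g, o)
  wh <- matrix(c(0.2, -0.4, 0.3, -0.1), 1, 4)
  b <- c(0.05, -0.02, 0.1, 0.2)
  x <- 0.7
  r <- dircon:::lstm_forward(matrix(x, 1, 1), wi, wh, b, numeric(4),
                             reverse = FALSE)
  sig <- function(z) 1 / (1 + exp(-z))
  i_ <- sig(wi[1] * x + b[1]); f_ <- sig(wi[2] * x + b[2])
  g_ <- tanh(wi[3] * x + b[3]); o_ <- sig(wi[4] * x + b[4])
  c_ <- i_ * g_; h_ <- o_ * tanh(c_)
  expect_equal(as.numeric(r$H[1, 1, 1]), h_, tolerance = 1e-10)
  expect_equal(as.numeric(r$cache$C[1, 1, 1]), c_, tolerance = 1e-10)
})

test_that("two LSTM steps propagate the cell state correctly", {
  set.seed(8)
  wi <- rnorm(4); wh <- matrix(rnorm(4), 1, 4); b <- rnorm(4)
  x <- c(0.4, -0.9)
  r <- dircon:::lstm_forward(matrix(x, 1, 2), wi, wh, b, numeric(4),
                             reverse = FALSE)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- 0; cc <- 0
  for (t in 1:2) {
    pre <- wi * x[t] + as.numeric(wh) * h + b
    cc <- sig(pre[2]) * cc + sig(pre[1]) * tanh(pre[3])
    h <- sig(pre[4]) * tanh(cc)
  }
  expect_equal(as.numeric(r$H[1, 1, 2]), h, tolerance = 1e-10)
})

test_that("embedding width is twice the hidden dimension", {
  m <- tiny_model(4L, tiny_config(lstm_hidden = 7L))
  emb <- encode_nodes(matrix(rnorm(12), 4, 3), m)
  expect_equal(dim(emb), c(3L, 4L, 14L))
})

test_that("identical node embeddings give a uniform connectivity matrix", {
  m <- tiny_model(4L)
  emb <- array(0, c(2, 4, 8))
  v <- rnorm(8)
  for (t in 1:2) for (i in 1:4) emb[t, i, ] <- v
  W <- estimate_instantaneous_dc(emb, m)
  expect_equal(W, array(0.25, c(4, 4, 2)), tolerance = 1e-12)
})

test_that("attention matches a brute-force dot-product/softmax evaluation", {
  cfg <- tiny_config(n_heads = 1L, attn_dim = 2L)
  m <- tiny_model(3L, cfg)
  set.seed(2)
  emb <- array(rnorm(1 * 3 * 8), c(1, 3, 8))
  W <- estimate_instantaneous_dc(emb, m)[, , 1]
  E <- matrix(emb[1, , ], 3)
  Q <- E %*% m$params$attn_Wq_1
  K <- E %*% m$params$attn_Wk_1
  for (i in 1:3) {
    sc <- sapply(1:3, function(j) sum(Q[i, ] * K[j, ]))
    expect_equal(W[i, ], exp(sc) / sum(exp(sc)), tolerance = 1e-6)
  }
})

test_that("rows are stochastic for 1, 2 and 4 heads", {
  for (nh in c(1L, 2L, 4L)) {
    m <- tiny_model(5L, tiny_config(n_heads = nh))
    emb <- encode_nodes(matrix(rnorm(5 * 4), 5, 4), m)
    W <- estimate_instantaneous_dc(emb, m)
    expect_true(all(W >= 0 & W <= 1))
    expect_lt(max(abs(apply(W, 3L, rowSums) - 1)), 1e-5)
  }
})

test_that("single-timepoint temporal attention uses W itself as global view", {
  m <- tiny_model(3L)
  W <- array(stats::runif(9), c(3, 3, 1))
  # independent re-computation of the T = 1 path: W_global = W_1
  a <- compute_gta(W, m)
  expect_length(a, 1L)
  expect_true(a >= 0 && a <= 1)
})

test_that("identical matrices over time get equal attention weights", {
  m <- tiny_model(4L)
  w1 <- matrix(stats::runif(16), 4, 4)
  W <- array(rep(w1, 5), c(4, 4, 5))
  a <- compute_gta(W, m)   # evaluation mode
  expect_equal(max(a) - min(a), 0, tolerance = 1e-12)
})

test_that("temporal attention matches a hand-rolled MLP forward pass", {
  cfg <- tiny_config(gta_eta1 = 0.5, gta_eta2 = 0.5)   # widths 2, 2 at N = 2
  m <- tiny_model(2L, cfg)
  set.seed(3)
  W <- array(stats::runif(2 * 2 * 2), c(2, 2, 2))
  a <- compute_gta(W, m)
  p <- m$params; bn <- m$bn
  Wg <- (W[, , 1] + W[, , 2]) / 2
  manual <- numeric(2)
  for (t in 1:2) {
    v <- as.numeric(W[, , t] * Wg)
    z1 <- as.numeric(v %*% p$gta_W1) + p$gta_b1
    xh <- (z1 - bn$mean) / sqrt(bn$var + bn$eps)
    r1 <- pmax(xh * p$gta_gamma + p$gta_beta, 0)
    r2 <- pmax(as.numeric(r1 %*% p$gta_W2) + p$gta_b2, 0)
    manual[t] <- 1 / (1 + exp(-(sum(r2 * p$gta_W3) + p$gta_b3)))
  }
  expect_equal(a, manual, tolerance = 1e-6)
})

test_that("aggregation is the alpha-weighted sum of the series", {
  m <- tiny_model(4L)
  set.seed(4)
  W <- array(stats::runif(4 * 4 * 6), c(4, 4, 6))
  # one-hot selection
  a1 <- rep(0, 6); a1[3] <- 1
  expect_equal(aggregate_dc(W, a1)$W_f, W[, , 3])
  # uniform weights = time mean
  expect_equal(aggregate_dc(W, rep(1 / 6, 6))$W_f,
               apply(W, c(1, 2), mean), tolerance = 1e-12)
  # random alpha vs naive loop
  a <- stats::runif(6)
  ref <- matrix(0, 4, 4)
  for (t in 1:6) ref <- ref + a[t] * W[, , t]
  expect_equal(aggregate_dc(W, a)$W_f, ref, tolerance = 1e-9)
  expect_error(aggregate_dc(W, a[-1]), "length")
})

test_that("zero classifier head maps everything to even logits", {
  m <- zero_params(tiny_model(4L))
  lg <- classify_from_dc(matrix(stats::runif(16), 4, 4), m)
  expect_equal(lg, c(0, 0))
  pr <- exp(lg) / sum(exp(lg))
  expect_equal(pr[2], 0.5)
})

test_that("classifier head has the documented parameter count", {
  N <- 6L
  m <- tiny_model(N, tiny_config(head_hidden = 64L))
  expect_equal(length(m$params$head_W1), N^2 * 64)
  expect_equal(length(m$params$head_b1), 64L)
  expect_equal(length(m$params$head_W2), 64L * 2L)
  expect_equal(length(m$params$head_b2), 2L)
})

test_that("classifier matches manual affine-relu-affine evaluation", {
  m <- tiny_model(2L, tiny_config(head_hidden = 2L))
  set.seed(5)
  Wf <- matrix(stats::runif(4), 2, 2)
  lg <- classify_from_dc(Wf, m)
  p <- m$params
  hid <- pmax(as.numeric(as.numeric(Wf) %*% p$head_W1) + p$head_b1, 0)
  ref <- as.numeric(hid %*% p$head_W2) + p$head_b2
  expect_equal(lg, ref, tolerance = 1e-12)
})

test_that("loss equals ln 2 at even logits and vanishes when confident", {
  m <- zero_params(tiny_model())      # all parameters zero: no L1 term
  expect_equal(compute_loss(c(0, 0), 1L, m), log(2), tolerance = 1e-9)
  expect_lt(compute_loss(c(-20, 20), 1L, m), 1e-8)
  # the L1 term adds lambda * sum |theta|
  m2 <- tiny_model()
  m2$cfg$lambda_l1 <- 1e-3
  expect_equal(compute_loss(c(0, 0), 0L, m2),
               log(2) + 1e-3 * sum(vapply(m2$params,
                                          function(w) sum(abs(w)), 0)),
               tolerance = 1e-9)
})

test_that("AUC equals brute-force concordant-pair counting", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.2)
  labels <- c(0L, 0L, 1L, 1L, 0L, 1L)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  conc <- 0
  for (p_ in pos) for (n_ in neg)
    conc <- conc + (p_ > n_) + 0.5 * (p_ == n_)
  expect_equal(evaluate_auc(scores, labels), conc / (length(pos) * length(neg)))
  expect_equal(evaluate_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_error(evaluate_auc(1:4, rep(1L, 4)), "both classes")
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(evaluate_auc(sc, lb), ref, tolerance = 1e-12)
})
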