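# User-facing single-subject operations.  These spell out each stage of the
# architecture on one subject; the batched trainer in nn-core.R computes the
# identical function (asserted in the test suite).

#' Encode node time series with the shared bidirectional LSTM
#'
#' Each node's series is fed as a length-`T` sequence of scalars through one
#' LSTM weight set shared across all nodes (so the encoder learns temporal
#' structure, not node identity); forward and backward hidden states are
#' concatenated.
#'
#' @param x numeric `N x T` matrix: one subject's node signals.
#' @param model a `dc_model` from [init_dc_model()].
#' @return Array `[T, N, 2 * lstm_hidden]` of node embeddings.
#' @export
encode_nodes <- function(x, model) {
  x <- as.matrix(x)
  assert_finite(x, "node signals")
  N <- nrow(x); TT <- ncol(x); H <- model$cfg$lstm_hidden
  p <- model$params
  lf <- lstm_forward(x, p$lstm_f_Wi, p$lstm_f_Wh, p$lstm_f_bih, p$lstm_f_bhh,
                     reverse = FALSE)
  lb <- lstm_forward(x, p$lstm_b_Wi, p$lstm_b_Wh, p$lstm_b_bih, p$lstm_b_bhh,
                     reverse = TRUE)
  emb <- array(0, c(TT, N, 2L * H))
  for (t in seq_len(TT)) {
    emb[t, , seq_len(H)] <- lf$H[, , t]
    emb[t, , H + seq_len(H)] <- lb$H[, , t]
  }
  emb
}

#' Estimate instantaneous directed connectivity
#'
#' At every timepoint the `N` node embeddings form one attention sequence:
#' key and query projections are taken, row `i` of `W_t` is the softmax over
#' `j` of `q_i . k_j`, giving a row-stochastic directed connectivity matrix
#' per timepoint (window size 1).  With several heads, the per-head
#' row-stochastic matrices are averaged, which keeps rows summing to one.
#' `W_t[i, j]` is query node `i` attending to key node `j`, read as the
#' influence of node `j` on node `i` (directed edge `j -> i`).
#'
#' @param emb embeddings from [encode_nodes()], `[T, N, 2H]`.
#' @param model a `dc_model`.
#' @return Array `[N, N, T]`; each slice `[, , t]` is `W_t`.
#' @export
estimate_instantaneous_dc <- function(emb, model) {
  TT <- dim(emb)[1L]; N <- dim(emb)[2L]
  if (N < 2L) stop_dircon("need at least 2 nodes")
  cfg <- model$cfg; p <- model$params
  scale <- if (cfg$attn_scale) 1 / sqrt(cfg$attn_dim) else 1
  W <- array(0, c(N, N, TT))
  for (t in seq_len(TT)) {
    E <- matrix(emb[t, , ], N)
    acc <- matrix(0, N, N)
    for (h in seq_len(cfg$n_heads)) {
      Q <- E %*% p[[paste0("attn_Wq_", h)]]
      K <- E %*% p[[paste0("attn_Wk_", h)]]
      acc <- acc + row_softmax(tcrossprod(Q, K) * scale)
    }
    W[, , t] <- acc / cfg$n_heads
  }
  W
}

#' Global temporal attention over a connectivity series
#'
#' The time-mean matrix `W_global` is the model's global view; each `W_t` is
#' compared to it by the Hadamard product `W_t * W_global`, whose flattened
#' form passes through a three-layer MLP (widths `round(eta1 N^2)`,
#' `round(eta2 N^2)`, 1; batch normalization after the first layer, ReLU
#' between layers) producing one attention score per timepoint, squashed to
#' `[0, 1]`.
#'
#' @param dc connectivity series `[N, N, T]` (from
#'   [estimate_instantaneous_dc()]).
#' @param model a `dc_model`.
#' @param training if `TRUE` batch statistics over the `T` rows are used for
#'   normalization; by default the stored running statistics are used
#'   (evaluation mode).
#' @return Numeric vector `alpha` of length `T` with entries in `[0, 1]`.
#' @export
compute_gta <- function(dc, model, training = FALSE) {
  N <- dim(dc)[1L]; TT <- dim(dc)[3L]
  p <- model$params; bn <- model$bn
  Wg <- apply(dc, c(1L, 2L), mean)
  Wflat <- t(vapply(seq_len(TT),
                    function(t) as.numeric(dc[, , t] * Wg),
                    numeric(N * N)))
  Z1 <- add_bias(Wflat %*% p$gta_W1, p$gta_b1)
  if (training) {
    mu <- colMeans(Z1); v <- colMeans(Z1^2) - mu^2
  } else {
    mu <- bn$mean; v <- bn$var
  }
  xhat <- sweep(sweep(Z1, 2L, mu), 2L, 1 / sqrt(v + bn$eps), `*`)
  R1 <- relu(add_bias(sweep(xhat, 2L, p$gta_gamma, `*`), p$gta_beta))
  R2 <- relu(add_bias(R1 %*% p$gta_W2, p$gta_b2))
  z3 <- as.numeric(add_bias(R2 %*% p$gta_W3, p$gta_b3))
  if (model$cfg$alpha_activation == "sigmoid") sigmoid(z3)
  else as.numeric(row_softmax(matrix(z3, 1L)))
}

#' Aggregate a connectivity series with temporal attention weights
#'
#' `W_f = sum_t alpha_t W_t`: the single matrix handed to the classifier.
#'
#' @param dc connectivity series `[N, N, T]`.
#' @param alpha attention weights of length `T`.
#' @return List with `W_f` (`N x N`) and `alpha`, class `aggregated_dc`.
#' @export
aggregate_dc <- function(dc, alpha) {
  TT <- dim(dc)[3L]
  if (length(alpha) != TT)
    stop_dircon("length(alpha) must equal the number of timepoints")
  N <- dim(dc)[1L]
  Wf <- matrix(0, N, N)
  for (t in seq_len(TT)) Wf <- Wf + alpha[t] * dc[, , t]
  structure(list(W_f = Wf, alpha = as.numeric(alpha)),
            class = "aggregated_dc")
}

#' Classify a subject from the aggregated connectivity matrix alone
#'
#' The classifier sees only the flattened `W_f` — never the embeddings — so
#' every bit of discriminative signal must pass through the interpretable
#' connectivity layer.
#'
#' @param agg an `aggregated_dc` (or a bare `N x N` matrix).
#' @param model a `dc_model`.
#' @return Numeric vector of 2 logits.
#' @export
classify_from_dc <- function(agg, model) {
  Wf <- if (inherits(agg, "aggregated_dc")) agg$W_f else agg
  p <- model$params
  hidden <- relu(as.numeric(crossprod(p$head_W1, as.numeric(Wf))) + p$head_b1)
  as.numeric(crossprod(p$head_W2, hidden)) + p$head_b2
}

#' Training loss
#'
#' Mean cross-entropy over the batch plus `lambda * ||theta||_1` over all
#' parameters; optionally plus a penalty pulling connectivity diagonals
#' toward 1 when `diag_loss_weight > 0`.
#'
#' @param logits numeric matrix `S x 2` (or length-2 vector for one subject).
#' @param labels binary labels of length `S`.
#' @param model a `dc_model` (supplies `lambda_l1` and the parameters).
#' @param dc optional connectivity series `[N, N, T]` (one subject) or list
#'   thereof, needed only for the diagonal term.
#' @return Scalar loss.
#' @export
compute_loss <- function(logits, labels, model, dc = NULL) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_dircon("labels must be binary")
  loss <- ce_loss_grad(logits, labels)$loss +
    model$cfg$lambda_l1 * l1_penalty(model$params)
  if (model$cfg$diag_loss_weight > 0 && !is.null(dc)) {
    if (!is.list(dc)) dc <- list(dc)
    dvals <- unlist(lapply(dc, function(w)
      apply(w, 3L, function(m) diag(m))))
    loss <- loss + model$cfg$diag_loss_weight * mean((1 - dvals)^2)
  }
  loss
}

#' Area under the ROC curve
#'
#' Rank-based computation equal to the normalized Mann-Whitney U statistic
#' with ties counted half: the probability that a random positive scores
#' above a random negative.
#'
#' @param scores numeric scores (higher = more class-1).
#' @param labels binary labels.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_dircon("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}
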