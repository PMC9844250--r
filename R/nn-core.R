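# Batched forward / backward passes.
#
# The encoder (shared biLSTM) and the per-timepoint self-attention run in
# compiled code (src/core.cpp); the temporal-attention MLP, classifier head
# and loss are assembled here.  Layout conventions (S subjects, N nodes, T
# timepoints, M = S*N):
#   - sequences are indexed m = (s-1)*N + i;
#   - one (subject, timepoint) pair has group index g = (t-1)*S + s, with
#     s_of_g = rep(1:S, T);
#   - Wflat (ST x N^2) holds each W_t flattened column-major: column
#     (j-1)*N + i is W_t[i, j], query node i attending to key node j
#     (influence j -> i).

add_bias <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

# X2: M x T matrix of scalar inputs.  Thin wrappers over the compiled
# kernels, used by the per-subject operations.
lstm_forward <- function(X2, Wi, Wh, bih, bhh, reverse = FALSE) {
  r <- lstm_forward_cpp(X2, as.numeric(Wi), Wh, as.numeric(bih + bhh),
                        reverse)
  list(H = r$H, cache = list(X2 = X2, C = r$C, Gates = r$Gates,
                             Hout = r$H, reverse = reverse))
}

lstm_backward <- function(dH, cache, Wh) {
  r <- lstm_backward_cpp(dH, cache$X2, cache$C, cache$Gates, cache$Hout,
                         Wh, cache$reverse)
  list(dWi = as.numeric(r$dWi), dWh = r$dWh, db = as.numeric(r$db))
}

attn_param_lists <- function(p, nh) {
  list(Wq = lapply(seq_len(nh), function(h) p[[paste0("attn_Wq_", h)]]),
       Wk = lapply(seq_len(nh), function(h) p[[paste0("attn_Wk_", h)]]))
}

# --- full forward -----------------------------------------------------------

# X: array [S, N, T].  Returns logits, alpha [S, T], Wf (S x N^2), Wflat,
# and (optionally) the cache for the backward pass.  `training` selects
# batch-norm semantics; running statistics update only when training.
dc_forward_batch <- function(model, X, training = FALSE, want_cache = FALSE,
                             update_bn = training) {
  cfg <- model$cfg; p <- model$params
  S <- dim(X)[1L]; N <- dim(X)[2L]; TT <- dim(X)[3L]
  if (N != model$n_nodes) stop_dircon("node count does not match model")
  assert_finite(X, "model input")
  scale <- if (cfg$attn_scale) 1 / sqrt(cfg$attn_dim) else 1
  X2 <- matrix(aperm(X, c(2L, 1L, 3L)), S * N, TT)
  ap <- attn_param_lists(p, cfg$n_heads)
  co <- core_forward_cpp(X2,
                         as.numeric(p$lstm_f_Wi), p$lstm_f_Wh,
                         as.numeric(p$lstm_f_bih + p$lstm_f_bhh),
                         as.numeric(p$lstm_b_Wi), p$lstm_b_Wh,
                         as.numeric(p$lstm_b_bih + p$lstm_b_bhh),
                         ap$Wq, ap$Wk, S, N, scale, want_cache)
  Wflat <- co$Wflat
  sg <- rep(seq_len(S), TT)
  Wg <- rowsum(Wflat, sg) / TT                       # S x N^2 global views
  Wtil <- Wflat * Wg[sg, , drop = FALSE]
  # temporal attention MLP
  Z1 <- add_bias(Wtil %*% p$gta_W1, p$gta_b1)
  if (training) {
    mu <- colMeans(Z1)
    v <- colMeans(Z1^2) - mu^2
    if (update_bn) {
      mom <- model$bn$momentum
      model$bn$mean <- (1 - mom) * model$bn$mean + mom * mu
      model$bn$var <- (1 - mom) * model$bn$var + mom * v
    }
  } else {
    mu <- model$bn$mean; v <- model$bn$var
  }
  inv_sd <- 1 / sqrt(v + model$bn$eps)
  xhat <- sweep(sweep(Z1, 2L, mu), 2L, inv_sd, `*`)
  Y1 <- add_bias(sweep(xhat, 2L, p$gta_gamma, `*`), p$gta_beta)
  R1 <- relu(Y1)
  Z2 <- add_bias(R1 %*% p$gta_W2, p$gta_b2)
  R2 <- relu(Z2)
  z3 <- as.numeric(add_bias(R2 %*% p$gta_W3, p$gta_b3))
  if (cfg$alpha_activation == "sigmoid") {
    alpha <- sigmoid(z3)
  } else {
    alpha <- as.numeric(row_softmax(matrix(z3, S, TT)))
  }
  Wf <- rowsum(Wflat * alpha, sg)                    # S x N^2
  Zh <- add_bias(Wf %*% p$head_W1, p$head_b1)
  Rh <- relu(Zh)
  logits <- add_bias(Rh %*% p$head_W2, p$head_b2)
  out <- list(logits = logits, alpha = matrix(alpha, S, TT), Wf = Wf,
              Wflat = Wflat, model = model)
  if (want_cache)
    out$cache <- list(S = S, N = N, TT = TT, attn = co$cache, Wflat = Wflat,
                      Wg = Wg, Wtil = Wtil, xhat = xhat, inv_sd = inv_sd,
                      Y1 = Y1, R1 = R1, Z2 = Z2, R2 = R2, alpha = alpha,
                      Wf = Wf, Zh = Zh, Rh = Rh, sg = sg,
                      training = training)
  out
}

# Reassemble one subject's connectivity series [N, N, T] from Wflat.
wflat_subject <- function(Wflat, s, S, N, TT) {
  rows <- s + S * (seq_len(TT) - 1L)
  array(t(Wflat[rows, , drop = FALSE]), c(N, N, TT))
}

# Cross-entropy (mean over batch) from logits, plus gradient.
ce_loss_grad <- function(logits, labels) {
  S <- nrow(logits)
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  idx <- cbind(seq_len(S), labels + 1L)
  ce <- mean(lse - logits[idx])
  pr <- exp(logits - lse)
  dlogits <- pr
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = ce, grad = dlogits / S)
}

l1_penalty <- function(params) sum(vapply(params, function(w) sum(abs(w)), 0))

# Full loss + parameter gradients on one batch.  Returns
# list(loss, ce, grads, model, logits); grads has an entry per parameter.
dc_loss_and_grad <- function(model, X, labels, training = TRUE) {
  cfg <- model$cfg; p <- model$params
  fwd <- dc_forward_batch(model, X, training = training, want_cache = TRUE)
  model <- fwd$model                     # bn running stats possibly updated
  ca <- fwd$cache
  S <- ca$S; N <- ca$N; TT <- ca$TT
  nh <- cfg$n_heads
  cg <- ce_loss_grad(fwd$logits, labels)
  loss <- cg$loss + cfg$lambda_l1 * l1_penalty(p)
  grads <- lapply(p, function(w) w * 0)

  # classifier head
  dlogits <- cg$grad
  grads$head_b2 <- colSums(dlogits)
  grads$head_W2 <- crossprod(ca$Rh, dlogits)
  dRh <- dlogits %*% t(p$head_W2)
  dZh <- dRh * (ca$Zh > 0)
  grads$head_b1 <- colSums(dZh)
  grads$head_W1 <- crossprod(fwd$Wf, dZh)
  dWf <- dZh %*% t(p$head_W1)            # S x N^2

  # aggregation: Wf = sum_t alpha * Wflat
  alpha <- ca$alpha; Wflat <- ca$Wflat; sg <- ca$sg
  dalpha <- rowSums(dWf[sg, , drop = FALSE] * Wflat)
  dWflat <- alpha * dWf[sg, , drop = FALSE]

  # alpha activation
  if (cfg$alpha_activation == "sigmoid") {
    dz3 <- dalpha * alpha * (1 - alpha)
  } else {
    am <- matrix(alpha, S, TT); dm <- matrix(dalpha, S, TT)
    dz3 <- as.numeric(am * (dm - rowSums(dm * am)))
  }
  # temporal attention MLP
  dz3m <- matrix(dz3, ncol = 1L)
  grads$gta_b3 <- sum(dz3)
  grads$gta_W3 <- crossprod(ca$R2, dz3m)
  dR2 <- dz3m %*% t(p$gta_W3)
  dZ2 <- dR2 * (ca$Z2 > 0)
  grads$gta_b2 <- colSums(dZ2)
  grads$gta_W2 <- crossprod(ca$R1, dZ2)
  dR1 <- dZ2 %*% t(p$gta_W2)
  dY1 <- dR1 * (ca$Y1 > 0)
  grads$gta_gamma <- colSums(dY1 * ca$xhat)
  grads$gta_beta <- colSums(dY1)
  dxhat <- sweep(dY1, 2L, p$gta_gamma, `*`)
  if (ca$training) {
    mean_dx <- colMeans(dxhat)
    mean_dxx <- colMeans(dxhat * ca$xhat)
    dZ1 <- sweep(dxhat, 2L, mean_dx) - sweep(ca$xhat, 2L, mean_dxx, `*`)
    dZ1 <- sweep(dZ1, 2L, ca$inv_sd, `*`)
  } else {
    dZ1 <- sweep(dxhat, 2L, ca$inv_sd, `*`)
  }
  grads$gta_b1 <- colSums(dZ1)
  grads$gta_W1 <- crossprod(ca$Wtil, dZ1)
  dWtil <- dZ1 %*% t(p$gta_W1)

  # Wtil = Wflat * Wg[sg];  Wg = rowsum(Wflat, sg) / T
  Wg <- ca$Wg
  dWflat <- dWflat + dWtil * Wg[sg, , drop = FALSE]
  dWg <- rowsum(dWtil * Wflat, sg)
  dWflat <- dWflat + dWg[sg, , drop = FALSE] / TT

  # optional diagonal penalty: diagonal entries sit in columns (i-1)*N + i
  if (cfg$diag_loss_weight > 0) {
    dcols <- seq(1L, N * N, by = N + 1L)
    dv <- Wflat[, dcols, drop = FALSE]
    loss <- loss + cfg$diag_loss_weight * mean((1 - dv)^2)
    dWflat[, dcols] <- dWflat[, dcols] +
      cfg$diag_loss_weight * 2 * (dv - 1) / length(dv)
  }

  # attention + encoder backward (compiled; consumes the cache)
  ap <- attn_param_lists(p, nh)
  bk <- core_backward_cpp(ca$attn, dWflat, ap$Wq, ap$Wk,
                          p$lstm_f_Wh, p$lstm_b_Wh)
  grads$lstm_f_Wi <- as.numeric(bk$f_dWi)
  grads$lstm_f_Wh <- bk$f_dWh
  grads$lstm_f_bih <- as.numeric(bk$f_db)
  grads$lstm_f_bhh <- as.numeric(bk$f_db)
  grads$lstm_b_Wi <- as.numeric(bk$b_dWi)
  grads$lstm_b_Wh <- bk$b_dWh
  grads$lstm_b_bih <- as.numeric(bk$b_db)
  grads$lstm_b_bhh <- as.numeric(bk$b_db)
  for (h in seq_len(nh)) {
    grads[[paste0("attn_Wq_", h)]] <- bk$dWq[[h]]
    grads[[paste0("attn_Wk_", h)]] <- bk$dWk[[h]]
  }

  # L1 subgradient on every parameter (the penalty covers all of theta)
  if (cfg$lambda_l1 > 0)
    for (nm in names(grads))
      grads[[nm]] <- grads[[nm]] + cfg$lambda_l1 * sign(p[[nm]])

  list(loss = loss, ce = cg$loss, grads = grads, model = model,
       logits = fwd$logits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
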