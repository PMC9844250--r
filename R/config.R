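#' Model configuration
#'
#' Hyper-parameters of the directed-connectivity network.  Defaults follow the
#' reference configuration used for ICA-component cohorts: biLSTM hidden width
#' 100, attention projections of width 48, temporal-attention MLP widths
#' `round(eta * N^2)` with `eta1 = eta2 = 0.05`, classifier widths 64 and 2,
#' L1 weight `1e-6`, Adam at learning rate `2e-4`, early-stopping patience 25.
#'
#' @param lstm_hidden hidden units per LSTM direction.
#' @param attn_dim width of the key/query/value projections.
#' @param n_heads number of self-attention heads; per-head row-stochastic
#'   matrices are averaged (which preserves row-stochasticity).
#' @param gta_eta1,gta_eta2 fractions of `N^2` giving the first two temporal
#'   attention MLP widths (each at least 1).
#' @param head_hidden hidden width of the classifier MLP (output is 2 logits).
#' @param lambda_l1 L1 regularization weight on all parameters.
#' @param lr Adam learning rate.
#' @param scheduler `"plateau"` (halve on validation-loss plateau) or
#'   `"exponential"` (multiply by `gamma` per epoch).
#' @param scheduler_patience epochs without improvement before a plateau cut.
#' @param gamma exponential decay factor.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement of at least `min_delta`).
#' @param min_delta minimum decrease counting as improvement.
#' @param max_epochs safety cap on epochs.
#' @param batch_size minibatch size.
#' @param seed base seed; trial `k` uses `seed + k`.
#' @param diag_loss_weight optional weight of a penalty pulling the diagonal
#'   of each connectivity matrix toward 1 (off by default).
#' @param attn_scale divide attention scores by `sqrt(attn_dim)`; off by
#'   default (the connectivity equations use unscaled scores).
#' @param alpha_activation `"sigmoid"` (each timepoint weighted in `[0, 1]`
#'   independently) or `"softmax"` (weights normalized over time).
#' @return A `dc_config` list.
#' @export
dc_model_config <- function(lstm_hidden = 100L, attn_dim = 48L, n_heads = 2L,
                            gta_eta1 = 0.05, gta_eta2 = 0.05,
                            head_hidden = 64L, lambda_l1 = 1e-6, lr = 2e-4,
                            scheduler = c("plateau", "exponential"),
                            scheduler_patience = 10L, gamma = 0.99,
                            patience = 25L, min_delta = 1e-6,
                            max_epochs = 300L, batch_size = 32L, seed = 0L,
                            diag_loss_weight = 0,
                            attn_scale = FALSE,
                            alpha_activation = c("sigmoid", "softmax")) {
  cfg <- list(
    lstm_hidden = as.integer(lstm_hidden), attn_dim = as.integer(attn_dim),
    n_heads = as.integer(n_heads), gta_eta1 = gta_eta1, gta_eta2 = gta_eta2,
    head_hidden = as.integer(head_hidden), lambda_l1 = lambda_l1, lr = lr,
    scheduler = match.arg(scheduler),
    scheduler_patience = as.integer(scheduler_patience), gamma = gamma,
    patience = as.integer(patience), min_delta = min_delta,
    max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed), diag_loss_weight = diag_loss_weight,
    attn_scale = isTRUE(attn_scale),
    alpha_activation = match.arg(alpha_activation))
  stopifnot(cfg$lstm_hidden > 0L, cfg$attn_dim > 0L, cfg$n_heads > 0L,
            cfg$gta_eta1 > 0, cfg$gta_eta2 > 0, cfg$head_hidden > 0L,
            cfg$lambda_l1 >= 0, cfg$lr > 0, cfg$diag_loss_weight >= 0)
  class(cfg) <- "dc_config"
  cfg
}

gta_widths <- function(N, cfg) {
  c(max(1L, as.integer(round(cfg$gta_eta1 * N^2))),
    max(1L, as.integer(round(cfg$gta_eta2 * N^2))))
}

unif_init <- function(nr, nc, k) {
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

#' Initialize a directed-connectivity model
#'
#' Parameters are drawn from the standard uniform fan-in initializers
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`; for LSTM weights the fan-in is the
#' hidden width), seeded by `cfg$seed`.
#'
#' @param n_nodes number of nodes the model operates on.
#' @param cfg a [dc_model_config()].
#' @return A `dc_model` object holding parameters and batch-norm state.
#' @export
init_dc_model <- function(n_nodes, cfg = dc_model_config()) {
  N <- as.integer(n_nodes)
  if (N < 2L) stop_dircon("need at least 2 nodes")
  H <- cfg$lstm_hidden; d <- cfg$attn_dim
  wd <- gta_widths(N, cfg)
  p <- with_seed(cfg$seed, {
    kl <- 1 / sqrt(H)
    p <- list()
    for (dir in c("f", "b")) {
      p[[paste0("lstm_", dir, "_Wi")]] <- as.numeric(unif_init(1L, 4L * H, kl))
      p[[paste0("lstm_", dir, "_Wh")]] <- unif_init(H, 4L * H, kl)
      p[[paste0("lstm_", dir, "_bih")]] <- stats::runif(4L * H, -kl, kl)
      p[[paste0("lstm_", dir, "_bhh")]] <- stats::runif(4L * H, -kl, kl)
    }
    ka <- 1 / sqrt(2 * H)
    for (h in seq_len(cfg$n_heads)) {
      p[[paste0("attn_Wq_", h)]] <- unif_init(2L * H, d, ka)
      p[[paste0("attn_Wk_", h)]] <- unif_init(2L * H, d, ka)
      p[[paste0("attn_Wv_", h)]] <- unif_init(2L * H, d, ka)
    }
    k1 <- 1 / sqrt(N^2); k2 <- 1 / sqrt(wd[1]); k3 <- 1 / sqrt(wd[2])
    p$gta_W1 <- unif_init(N^2, wd[1], k1)
    p$gta_b1 <- stats::runif(wd[1], -k1, k1)
    p$gta_gamma <- rep(1, wd[1]); p$gta_beta <- rep(0, wd[1])
    p$gta_W2 <- unif_init(wd[1], wd[2], k2)
    p$gta_b2 <- stats::runif(wd[2], -k2, k2)
    p$gta_W3 <- unif_init(wd[2], 1L, k3)
    p$gta_b3 <- stats::runif(1L, -k3, k3)
    kh <- 1 / sqrt(N^2); kh2 <- 1 / sqrt(cfg$head_hidden)
    p$head_W1 <- unif_init(N^2, cfg$head_hidden, kh)
    p$head_b1 <- stats::runif(cfg$head_hidden, -kh, kh)
    p$head_W2 <- unif_init(cfg$head_hidden, 2L, kh2)
    p$head_b2 <- stats::runif(2L, -kh2, kh2)
    p
  })
  structure(list(
    n_nodes = N, cfg = cfg, params = p,
    bn = list(mean = rep(0, wd[1]), var = rep(1, wd[1]), momentum = 0.1,
              eps = 1e-5)),
    class = "dc_model")
}

#' @export
print.dc_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<dc_model> %d nodes, biLSTM hidden %d, attn dim %d x %d heads, %d parameters\n",
    x$n_nodes, x$cfg$lstm_hidden, x$cfg$attn_dim, x$cfg$n_heads, np))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the configuration, all
#' parameters and the batch-norm running statistics.
#'
#' @param model a `dc_model`.
#' @param path file path.
#' @return `path` (save) or the restored `dc_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "dc_model")
}
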