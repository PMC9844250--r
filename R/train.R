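# Fold-wise training with early stopping and AUC reporting.

# Fit one trial (one fold x one seed).  All randomness (init, shuffles) comes
# from trial_seed, so identical calls reproduce identical epoch losses.
fit_one_trial <- function(ds, train_idx, val_idx, cfg, trial_seed,
                          verbose = FALSE) {
  N <- dim(ds$data)[2L]
  cfg$seed <- trial_seed
  model <- init_dc_model(N, cfg)
  opt <- adam_init(model$params)
  lr <- cfg$lr
  best_val <- Inf; best_model <- model
  no_improve <- 0L; sched_no_improve <- 0L
  train_hist <- numeric(0); val_hist <- numeric(0); val_auc_hist <- numeric(0)
  ytr <- ds$labels[train_idx]
  if (length(unique(ytr)) < 2L)
    stop_dircon("training set must contain both classes")
  set.seed(trial_seed + 1L)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / cfg$batch_size)
    ep_loss <- 0; ep_n <- 0L
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):
                   min(b * cfg$batch_size, length(ord))]
      res <- dc_loss_and_grad(model, ds$data[idx, , , drop = FALSE],
                              ds$labels[idx], training = TRUE)
      model <- res$model
      if (!is.finite(res$loss)) {
        return(list(ok = FALSE, reason = "non-finite training loss",
                    epochs = epoch, train_hist = train_hist,
                    val_hist = val_hist))
      }
      st <- adam_step(model$params, res$grads, opt, lr)
      model$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + res$loss * length(idx); ep_n <- ep_n + length(idx)
    }
    train_hist <- c(train_hist, ep_loss / ep_n)
    vf <- dc_forward_batch(model, ds$data[val_idx, , , drop = FALSE],
                           training = FALSE)
    val_loss <- ce_loss_grad(vf$logits, ds$labels[val_idx])$loss
    val_hist <- c(val_hist, val_loss)
    val_auc_hist <- c(val_auc_hist,
                      evaluate_auc(vf$logits[, 2L] - vf$logits[, 1L],
                                   ds$labels[val_idx]))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  val_auc %.3f  lr %.2e",
                      epoch, train_hist[epoch], val_loss,
                      val_auc_hist[epoch], lr))
    if (val_loss < best_val - cfg$min_delta) {
      best_val <- val_loss
      best_model <- model
      no_improve <- 0L; sched_no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
      sched_no_improve <- sched_no_improve + 1L
    }
    if (cfg$scheduler == "exponential") {
      lr <- lr * cfg$gamma
    } else if (sched_no_improve >= cfg$scheduler_patience) {
      lr <- lr * 0.5
      sched_no_improve <- 0L
    }
    if (no_improve >= cfg$patience) break
  }
  list(ok = TRUE, model = best_model, best_val = best_val, epochs = epoch,
       train_hist = train_hist, val_hist = val_hist,
       val_auc_hist = val_auc_hist)
}

#' Predict class logits
#'
#' Runs the model in evaluation mode.  With `n_chunks > 1` the scan is split
#' into contiguous segments and the per-chunk logits are averaged into the
#' final logits (the protocol for long recordings).
#'
#' @param model a trained `dc_model`.
#' @param ds a [timecourse_dataset()].
#' @param idx subject indices (default all).
#' @param n_chunks number of temporal chunks.
#' @return Numeric matrix `length(idx) x 2` of logits.
#' @export
predict_logits <- function(model, ds, idx = seq_len(dim(ds$data)[1L]),
                           n_chunks = 1L) {
  if (n_chunks > 1L) {
    chunks <- chunk_long_scans(ds, n_chunks)
    lg <- lapply(chunks, function(ch)
      dc_forward_batch(model, ch$data[idx, , , drop = FALSE],
                       training = FALSE)$logits)
    return(Reduce(`+`, lg) / length(lg))
  }
  dc_forward_batch(model, ds$data[idx, , , drop = FALSE],
                   training = FALSE)$logits
}

#' Train across folds and seeds
#'
#' For every requested fold and random trial the model is trained with Adam
#' on the training set, the learning rate is scheduled, training stops when
#' the validation loss fails to improve for `cfg$patience` epochs, and the
#' checkpoint with the best validation loss is evaluated once on the fold's
#' test set (test subjects are touched at no other point).
#'
#' @param ds a [timecourse_dataset()] (standardize first).
#' @param plan a `fold_plan` from [make_balanced_folds()].
#' @param cfg a [dc_model_config()].
#' @param n_seeds randomly-seeded trials per fold (trial `k` uses
#'   `cfg$seed + k - 1`).
#' @param folds which folds to run (default all).
#' @param n_chunks temporal chunks for long scans (per-chunk logits are
#'   averaged).
#' @param keep_models keep each trial's best model in the result.
#' @param verbose print per-epoch progress.
#' @return A `dc_run_result`: `records` data.frame (fold, seed,
#'   best_val_loss, test_auc, test_acc, epochs), `summary` of the AUCs
#'   (mean/max/min/sd), and optionally `models`.
#' @export
train_dc_model <- function(ds, plan, cfg = dc_model_config(), n_seeds = 1L,
                           folds = seq_len(plan$n_folds), n_chunks = 1L,
                           keep_models = TRUE, verbose = FALSE) {
  records <- NULL
  models <- list()
  for (f in folds) {
    fd <- plan$folds[[f]]
    stopifnot(length(intersect(fd$train, fd$test)) == 0L,
              length(intersect(fd$val, fd$test)) == 0L)
    for (k in seq_len(n_seeds)) {
      trial_seed <- cfg$seed + (k - 1L)
      fit <- fit_one_trial(ds, fd$train, fd$val, cfg, trial_seed,
                           verbose = verbose)
      if (!fit$ok) {
        warning(sprintf("fold %d seed %d aborted: %s", f, trial_seed,
                        fit$reason))
        rec <- data.frame(fold = f, seed = trial_seed, best_val_loss = NA,
                          test_auc = NA, test_acc = NA, epochs = fit$epochs)
      } else {
        lg <- predict_logits(fit$model, ds, fd$test, n_chunks = n_chunks)
        scores <- lg[, 2L] - lg[, 1L]
        ytest <- ds$labels[fd$test]
        auc <- evaluate_auc(scores, ytest)
        acc <- mean((lg[, 2L] > lg[, 1L]) == (ytest == 1L))
        rec <- data.frame(fold = f, seed = trial_seed,
                          best_val_loss = fit$best_val, test_auc = auc,
                          test_acc = acc, epochs = fit$epochs)
        if (keep_models)
          models[[sprintf("fold%d_seed%d", f, trial_seed)]] <-
            list(model = fit$model, train_hist = fit$train_hist,
                 val_hist = fit$val_hist)
      }
      records <- rbind(records, rec)
    }
  }
  aucs <- records$test_auc[!is.na(records$test_auc)]
  structure(list(
    records = records,
    summary = list(mean = mean(aucs), max = max(aucs), min = min(aucs),
                   sd = stats::sd(aucs)),
    models = if (keep_models) models else NULL),
    class = "dc_run_result")
}

#' @export
print.dc_run_result <- function(x, ...) {
  cat(sprintf("<dc_run_result> %d trials, mean AUC %.3f (min %.3f, max %.3f)\n",
              nrow(x$records), x$summary$mean, x$summary$min, x$summary$max))
  invisible(x)
}

#' Extract connectivity series, temporal attention and aggregated matrices
#'
#' Runs the trained model in evaluation mode over the requested subjects and
#' returns, per subject, the full directed connectivity series `W_t`
#' (`[N, N, T]`, each slice row-stochastic), the temporal attention vector
#' `alpha`, and the aggregated `W_f = sum_t alpha_t W_t`.
#'
#' @param model a trained `dc_model`.
#' @param ds a [timecourse_dataset()].
#' @param idx subject indices (default all).
#' @param batch_size subjects per forward pass.
#' @return Named list (by subject id) of lists with `W`, `alpha`, `W_f`.
#' @export
estimate_connectivity <- function(model, ds, idx = seq_len(dim(ds$data)[1L]),
                                  batch_size = 32L) {
  out <- vector("list", length(idx))
  names(out) <- ds$subject_ids[idx]
  N <- dim(ds$data)[2L]; TT <- dim(ds$data)[3L]
  pos <- 1L
  while (pos <= length(idx)) {
    take <- idx[pos:min(pos + batch_size - 1L, length(idx))]
    fw <- dc_forward_batch(model, ds$data[take, , , drop = FALSE],
                           training = FALSE, want_cache = FALSE)
    S <- length(take)
    for (si in seq_len(S)) {
      out[[pos + si - 1L]] <- list(
        W = wflat_subject(fw$Wflat, si, S, N, TT),
        alpha = fw$alpha[si, ],
        W_f = matrix(fw$Wf[si, ], N, N))
    }
    pos <- pos + S
  }
  out
}
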