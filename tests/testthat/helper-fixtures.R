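# Shared fixture builders.  Everything is generated in code; sizes are kept
# tiny so each unit test runs in well under a second.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(lstm_hidden = 4L, attn_dim = 3L, n_heads = 2L,
         gta_eta1 = 0.2, gta_eta2 = 0.2,   # widths >= 2 even at tiny N
         batch_size = 8L, seed = 11L),
    list(...))
  do.call(dc_model_config, args)
}

tiny_model <- function(n_nodes = 5L, cfg = tiny_config()) {
  init_dc_model(n_nodes, cfg)
}

random_dataset <- function(S = 6L, N = 5L, TT = 8L, seed = 42L) {
  set.seed(seed)
  timecourse_dataset(array(rnorm(S * N * TT), c(S, N, TT)),
                     labels = rep_len(c(0L, 1L), S))
}

# Zero out every parameter of a model (the fixed point of the encoder and a
# zero map for the classifier head).
zero_params <- function(model) {
  model$params <- lapply(model$params, function(w) w * 0)
  model
}

# A small two-group matrix sample with a planted block effect: groups differ
# only inside the nodes of `hot_nodes`.
planted_block_matrices <- function(n_per_group = 15L, N = 8L, hot_nodes = 1:3,
                                   effect = 0.3, seed = 1L) {
  set.seed(seed)
  mats <- list(); groups <- character(0)
  for (g in 0:1) for (k in seq_len(n_per_group)) {
    m <- matrix(stats::runif(N * N, 0.2, 0.6), N, N)
    if (g == 1L)
      m[hot_nodes, hot_nodes] <- m[hot_nodes, hot_nodes] + effect
    diag(m) <- 1
    mats[[length(mats) + 1L]] <- m
    groups <- c(groups, ifelse(g == 0L, "A", "B"))
  }
  list(matrices = mats, groups = groups)
}
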