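#' Specification for a two-group VAR(1) synthetic benchmark
#'
#' Each subject's signal follows a first-order vector autoregression
#' `x_t = A_g x_{t-1} + eps_t`, `eps_t ~ N(0, noise_sd^2 I)`.  Group 0 uses
#' `base_adjacency`; group 1 uses the base plus the planted
#' `group_delta_edges`, optionally only inside `active_window`.  The directed
#' ground-truth graph is therefore known exactly, which is what every
#' downstream recovery check needs (the estimator itself assumes no generative
#' model).
#'
#' @param n_nodes number of nodes `N`.
#' @param n_time timepoints `T` per subject.
#' @param n_per_group subjects per group.
#' @param base_adjacency `N x N` transition matrix (directed; diagonal allowed).
#' @param group_delta_edges data.frame with columns `source`, `target`,
#'   `delta`: group 1 has `A[target, source]` changed by `delta` (edge
#'   source -> target).
#' @param active_window optional integer pair `c(t0, t1)`, 1-based half-open
#'   `[t0, t1)`: the delta applies only at those timepoints.
#' @param regime_centroids optional list of `N x N` transition matrices for
#'   regime switching (see [simulate_regime_switching()]).
#' @param dwell stay-probability of the group-0 regime chain.
#' @param occupancy1 stationary occupancy of regime 1 for group 1.
#' @param noise_sd innovation standard deviation.
#' @param seed integer seed.
#' @return A validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_nodes, n_time, n_per_group,
                           base_adjacency,
                           group_delta_edges = NULL,
                           active_window = NULL,
                           regime_centroids = NULL,
                           dwell = 0.9, occupancy1 = 0.8,
                           noise_sd = 0.5, seed = 0L) {
  N <- as.integer(n_nodes)
  if (!is.matrix(base_adjacency) || !all(dim(base_adjacency) == N))
    stop_dircon("base_adjacency must be N x N")
  if (!is.null(group_delta_edges)) {
    gd <- group_delta_edges
    if (!all(c("source", "target", "delta") %in% names(gd)))
      stop_dircon("group_delta_edges needs columns source, target, delta")
    if (any(gd$source < 1 | gd$source > N | gd$target < 1 | gd$target > N))
      stop_dircon("group_delta_edges reference invalid node indices")
  }
  if (!is.null(active_window)) {
    if (length(active_window) != 2L || active_window[1] < 1 ||
        active_window[2] > n_time + 1 || active_window[1] >= active_window[2])
      stop_dircon("active_window must be a valid half-open interval [t0, t1)")
  }
  spec <- structure(
    list(n_nodes = N, n_time = as.integer(n_time),
         n_per_group = as.integer(n_per_group),
         base_adjacency = base_adjacency,
         group_delta_edges = group_delta_edges,
         active_window = active_window,
         regime_centroids = regime_centroids,
         dwell = dwell, occupancy1 = occupancy1,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_spec")
  for (A in effective_matrices(spec)) {
    r <- spectral_radius(A)
    if (r >= 0.95)
      stop_dircon(sprintf(
        "transition matrix has spectral radius %.3f >= 0.95 (non-stationary)", r))
  }
  spec
}

# All transition matrices a spec can put into play (stationarity guard).
effective_matrices <- function(spec) {
  mats <- list(spec$base_adjacency)
  if (!is.null(spec$group_delta_edges))
    mats <- c(mats, list(apply_delta(spec$base_adjacency,
                                     spec$group_delta_edges)))
  if (!is.null(spec$regime_centroids)) mats <- c(mats, spec$regime_centroids)
  mats
}

apply_delta <- function(A, gd) {
  for (k in seq_len(nrow(gd)))
    A[gd$target[k], gd$source[k]] <- A[gd$target[k], gd$source[k]] + gd$delta[k]
  A
}

# One VAR(1) trajectory: N x T, with a possibly time-varying transition
# matrix given by mats[[which_mat[t]]].
var_trajectory <- function(mats, which_mat, N, TT, noise_sd, burn_in = 50L) {
  x <- matrix(0, N, TT + burn_in)
  x[, 1L] <- stats::rnorm(N, sd = noise_sd)
  A_burn <- mats[[which_mat[1L]]]
  for (t in 2:(burn_in)) x[, t] <- A_burn %*% x[, t - 1L] +
      stats::rnorm(N, sd = noise_sd)
  for (t in seq_len(TT)) {
    tc <- burn_in + t
    x[, tc] <- mats[[which_mat[t]]] %*% x[, tc - 1L] +
      stats::rnorm(N, sd = noise_sd)
  }
  x[, burn_in + seq_len(TT), drop = FALSE]
}

#' Simulate two groups differing in known directed edges
#'
#' Generates `2 * n_per_group` subjects (group 0 then group 1) from the
#' group-specific VAR(1) processes of the spec and z-scores each series.  The
#' returned ground truth carries both transition matrices and the planted
#' edge set, so directed-edge recovery can be scored exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a [timecourse_dataset()]) and `ground_truth`
#'   (`A0`, `A1`, `delta_edges`, `active_window`).
#' @export
simulate_var_groups <- function(spec) {
  N <- spec$n_nodes; TT <- spec$n_time; P <- spec$n_per_group
  A0 <- spec$base_adjacency
  A1 <- if (is.null(spec$group_delta_edges)) A0 else
    apply_delta(A0, spec$group_delta_edges)
  win <- spec$active_window
  data <- array(0, c(2L * P, N, TT))
  labels <- rep(c(0L, 1L), each = P)
  with_seed(spec$seed, {
    for (s in seq_len(2L * P)) {
      g <- labels[s]
      if (g == 0L || is.null(win)) {
        mats <- list(if (g == 0L) A0 else A1)
        wm <- rep(1L, TT)
      } else {
        mats <- list(A0, A1)
        wm <- rep(1L, TT)
        wm[win[1]:(win[2] - 1L)] <- 2L
      }
      data[s, , ] <- var_trajectory(mats, wm, N, TT, spec$noise_sd)
    }
  })
  ds <- zscore_timecourses(
    timecourse_dataset(data, labels,
                       sprintf("sim%03d", seq_len(2L * P))))
  list(dataset = ds,
       ground_truth = list(A0 = A0, A1 = A1,
                           delta_edges = spec$group_delta_edges,
                           active_window = win))
}

#' Simulate regime-switching connectivity with group-dependent occupancy
#'
#' Each subject follows a two-state Markov chain over the spec's
#' `regime_centroids`; at each timepoint the current regime's transition
#' matrix generates the next observation.  Group 0 uses a symmetric chain
#' (stay probability `dwell`, stationary occupancy 1/2 each); group 1's chain
#' is tilted so regime 1 has stationary occupancy `occupancy1`.  The regime
#' labels are returned as ground truth for state-recovery checks.
#'
#' @param spec a [synthetic_spec()] with non-null `regime_centroids`.
#' @return list with `dataset`, `regime_labels` (`S x T` integer matrix) and
#'   `ground_truth` (`centroids`, per-group stationary occupancies).
#' @export
simulate_regime_switching <- function(spec) {
  cents <- spec$regime_centroids
  if (is.null(cents) || length(cents) < 1L)
    stop_dircon("spec$regime_centroids must be non-empty")
  K <- length(cents)
  p <- spec$dwell
  if (p <= 0 || p > 1) stop_dircon("dwell probability must be in (0, 1]")
  N <- spec$n_nodes; TT <- spec$n_time; P <- spec$n_per_group
  # group-0 chain: symmetric stay probability p over K states
  P0 <- matrix((1 - p) / max(K - 1L, 1L), K, K); diag(P0) <- p
  if (K == 1L) P0 <- matrix(1, 1, 1)
  # group-1 chain (K = 2): tilt so that state 1 has stationary mass occupancy1
  if (K == 2L) {
    pi1 <- spec$occupancy1
    leave1 <- 1 - p
    leave2 <- leave1 * pi1 / (1 - pi1)
    if (leave2 >= 1) { leave2 <- 0.95; leave1 <- leave2 * (1 - pi1) / pi1 }
    P1 <- matrix(c(1 - leave1, leave1, leave2, 1 - leave2), 2, 2, byrow = TRUE)
  } else P1 <- P0
  data <- array(0, c(2L * P, N, TT))
  labels <- rep(c(0L, 1L), each = P)
  regimes <- matrix(0L, 2L * P, TT)
  with_seed(spec$seed + 1L, {
    for (s in seq_len(2L * P)) {
      Pm <- if (labels[s] == 0L) P0 else P1
      z <- integer(TT)
      statio <- if (labels[s] == 0L || K != 2L) rep(1 / K, K)
                else c(spec$occupancy1, 1 - spec$occupancy1)
      z[1L] <- sample.int(K, 1L, prob = statio)
      if (TT > 1L) for (t in 2:TT)
        z[t] <- sample.int(K, 1L, prob = Pm[z[t - 1L], ])
      regimes[s, ] <- z
      data[s, , ] <- var_trajectory(cents, z, N, TT, spec$noise_sd)
    }
  })
  ds <- zscore_timecourses(
    timecourse_dataset(data, labels, sprintf("sim%03d", seq_len(2L * P))))
  list(dataset = ds, regime_labels = regimes,
       ground_truth = list(
         centroids = cents,
         occupancy = rbind(group0 = rep(1 / K, K),
                           group1 = if (K == 2L)
                             c(spec$occupancy1, 1 - spec$occupancy1)
                           else rep(1 / K, K))))
}

#' Canonical directed-recovery benchmark specification
#'
#' The study conditions used throughout the package's validation: `N` nodes,
#' `T` timepoints, `n_per_group` subjects per group, a sparse random base
#' adjacency rescaled to spectral radius 0.5 with a 0.2 self-decay diagonal,
#' five planted group-difference directed edges of weight +0.35, and
#' innovation noise sd 0.5.  The base graph and planted edges are drawn from
#' a fixed internal seed so the ground truth does not change across runs; the
#' `seed` argument only controls the sampled trajectories.
#'
#' @param seed trajectory seed.
#' @param n_nodes,n_time,n_per_group problem size (defaults 10 / 100 / 100).
#' @param n_delta_edges number of planted directed group-difference edges.
#' @param delta edge-weight change planted in group 1.
#' @param noise_sd innovation sd.
#' @param active_window optional `[t0, t1)` restriction of the group effect.
#' @return A [synthetic_spec()].
#' @export
benchmark_spec <- function(seed = 0L, n_nodes = 10L, n_time = 100L,
                           n_per_group = 100L, n_delta_edges = 5L,
                           delta = 0.35, noise_sd = 0.5,
                           active_window = NULL) {
  N <- as.integer(n_nodes)
  gt <- with_seed(20260901L + N, {
    A <- matrix(0, N, N)
    off <- which(row(A) != col(A))
    picked <- sample(off, max(1L, round(0.15 * length(off))))
    A[picked] <- stats::runif(length(picked), 0.15, 0.35) *
      sample(c(-1, 1), length(picked), replace = TRUE)
    diag(A) <- 0.2
    A <- A * (0.5 / spectral_radius(A))
    free <- setdiff(which(row(A) != col(A)), which(A != 0))
    ek <- sample(free, n_delta_edges)
    list(A = A,
         edges = data.frame(source = col(matrix(0, N, N))[ek],
                            target = row(matrix(0, N, N))[ek],
                            delta = delta))
  })
  synthetic_spec(N, n_time, n_per_group,
                 base_adjacency = gt$A,
                 group_delta_edges = gt$edges,
                 active_window = active_window,
                 noise_sd = noise_sd, seed = seed)
}

#' Canonical regime-switching benchmark specification
#'
#' Two (or `k`) shared connectivity regimes with clearly distinct directed
#' support; group 0 occupies them evenly while group 1 spends `occupancy1` of
#' its time in regime 1.  Used to validate the dynamic-state machinery.
#'
#' @param seed trajectory seed.
#' @param k number of regimes.
#' @param n_nodes,n_time,n_per_group problem size.
#' @param dwell group-0 stay probability.
#' @param occupancy1 group-1 stationary occupancy of regime 1 (k = 2 only).
#' @param noise_sd innovation sd.
#' @return A [synthetic_spec()].
#' @export
regime_benchmark_spec <- function(seed = 0L, k = 2L, n_nodes = 8L,
                                  n_time = 500L, n_per_group = 20L,
                                  dwell = 0.9, occupancy1 = 0.8,
                                  noise_sd = 0.5) {
  N <- as.integer(n_nodes)
  cents <- with_seed(20260902L + N + k, {
    lapply(seq_len(k), function(j) {
      A <- matrix(0, N, N)
      off <- which(row(A) != col(A))
      picked <- sample(off, max(1L, round(0.2 * length(off))))
      A[picked] <- stats::runif(length(picked), 0.2, 0.4)
      diag(A) <- 0.2
      A * (0.6 / spectral_radius(A))
    })
  })
  synthetic_spec(N, n_time, n_per_group,
                 base_adjacency = cents[[1L]],
                 regime_centroids = cents,
                 dwell = dwell, occupancy1 = occupancy1,
                 noise_sd = noise_sd, seed = seed)
}
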