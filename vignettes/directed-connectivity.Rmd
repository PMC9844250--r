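---
title: "Estimating instantaneous directed connectivity with dircon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating instantaneous directed connectivity with dircon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`dircon` estimates, for each subject, a sequence of *directed* connectivity
matrices between the nodes of a multivariate time series — in the motivating
application, ICA-component or ROI time-courses from resting-state fMRI —
together with a temporal attention profile saying which timepoints mattered
for a downstream binary classification. The estimator is a neural network
whose middle layer *is* the quantity of interest: classification operates on
the connectivity matrices alone, so the discriminative signal is forced
through an interpretable bottleneck ("glass-box" layer).

The pipeline per subject, with $N$ nodes and $T$ timepoints:

1. **Node encoder.** Each node's series is fed as a length-$T$ sequence of
   scalars through one bidirectional LSTM whose weights are shared across
   nodes. The standard six gate equations apply (input/forget/output gates
   with logistic activations, a tanh candidate, the cell update, and a tanh
   squashing of the output); forward and backward states are concatenated
   into $h_t^i \in \mathbb{R}^{2H}$. Sharing weights means the encoder learns
   temporal structure, not node identity; spatial relations are left to the
   attention stage.
2. **Instantaneous self-attention.** At each timepoint, the $N$ embeddings
   form one attention sequence. With key/query projections $k_i = h_i^\top
   W^{(k)}$, $q_i = h_i^\top W^{(q)}$, row $i$ of $W_t$ is
   $\mathrm{softmax}_j(q_i \cdot k_j)$. Each $W_t$ is therefore
   row-stochastic and generally asymmetric — a directed graph at a single
   timepoint (window size 1, so no sliding-window parameter exists). With
   several heads, the per-head row-stochastic matrices are averaged, which
   preserves row sums. We read $W_t[i, j]$ as the influence of node $j$ on
   node $i$ (edge $j \to i$); the convention is applied consistently in
   `top_edges()` and all reporting.
3. **Global temporal attention.** The time-mean $W^{\mathrm{global}}$ serves
   as a global view; each $\tilde W_t = W_t \odot W^{\mathrm{global}}$ is
   flattened and passed through a three-layer MLP (widths
   $\lceil \eta_1 N^2 \rfloor$, $\lceil \eta_2 N^2 \rfloor$, 1, batch
   normalization after the first layer, ReLU between layers), yielding a
   scalar score per timepoint squashed to $[0,1]$ — the attention vector
   $\alpha$.
4. **Aggregation and classification.** $W^f = \sum_t \alpha_t W_t$ is the
   only input to a two-layer classifier (widths 64 and 2). The loss is mean
   cross-entropy plus $\lambda \lVert \theta \rVert_1$ over all parameters.

## Design choices where the architecture was open

* **Attention scaling.** The connectivity softmax uses *unscaled* dot
  products by default (`attn_scale = FALSE`); the usual $1/\sqrt{d}$ factor
  is available as a switch but is not part of the reference equations.
* **$\alpha$ activation.** The per-timepoint scores pass through an
  elementwise logistic by default, so each subject's weights span $[0,1]$
  independently of $T$. A softmax-over-time variant
  (`alpha_activation = "softmax"`) is provided; with $T$ in the hundreds it
  forces individually tiny weights, which is why it is not the default.
* **Multi-head combination.** Averaging the per-head matrices is the only
  combination that keeps the glass-box layer row-stochastic, so that is what
  we do.
* **Batch normalization semantics.** During training the first GTA layer is
  normalized with statistics over all (subject, timepoint) rows in the
  minibatch; running means/variances (momentum 0.1) are used in evaluation
  mode. All reported estimates (`estimate_connectivity()`) are produced in
  evaluation mode, so they are deterministic given a trained model.
* **Value projections.** A value projection per head is initialized for
  completeness but nothing downstream consumes its output — only the
  attention weights propagate — so it receives no task gradient (asserted in
  the tests).
* **ReLU placement in the GTA MLP.** Nonlinearities sit between layers 1–2
  and 2–3; the final scalar goes straight into the $[0,1]$ squashing.
* **Diagonal penalty.** An optional term pulling $\mathrm{diag}(W_t)$ toward
  1 exists behind `diag_loss_weight` (default 0, i.e. off).

## Training protocol

Optimization is Adam at learning rate $2 \times 10^{-4}$ (default), with
either plateau halving (factor 0.5 after 10 stale epochs) or exponential
decay ($\gamma = 0.99$); early stopping monitors validation cross-entropy
with patience 25 and a strict improvement threshold of $10^{-6}$; the
checkpoint with the best validation loss is the one evaluated on the test
fold. Validation loss is cross-entropy only (the L1 term is a function of
the parameters alone, so adding it would shift every epoch equally). An
epoch cap of 300 bounds runaway trials. Divergent trials (non-finite loss)
are recorded as failures and do not abort the remaining trials.

Fold construction permutes subjects with a seed, gives every test fold
`round(count_c / n_folds)` subjects of class `c` (halves away from zero),
and draws a validation set of the same per-class size from the non-test
remainder (seeded per fold; validation subjects are fixed per fold, not
re-drawn per trial seed). Test sets are kept disjoint across folds: when
integer rounding over-allocates a class, the last fold takes whatever
remains of it rather than reusing tested subjects, and
`exhaust_last_fold = TRUE` additionally appends never-tested leftovers to
the final fold. For long recordings, `chunk_long_scans()` splits the scan
into equal segments and `predict_logits(..., n_chunks = k)` averages the
per-chunk logits.

The trainer runs the encoder and self-attention in compiled code
(RcppArmadillo); the analytic backpropagation is verified against central
finite differences in the test suite on every parameter group.

## What the synthetic generator emulates — and what it does not

There is no ground-truth connectivity for real resting-state data, so all
quantitative validation runs on simulated cohorts with *known* directed
structure. The generator is a first-order vector autoregression,
$x_t = A_g x_{t-1} + \varepsilon_t$: the simplest process with an
unambiguous directed graph (the support of $A$). Group 1 differs from group
0 in a small set of planted directed edges, optionally only inside a known
time window; a regime-switching variant draws the transition matrix at each
timepoint from a small set of "states" via a Markov chain with
group-dependent occupancy. Series are z-scored exactly as real time-courses
would be.

The canonical study conditions (`benchmark_spec()`): $N = 10$ nodes,
$T = 100$ timepoints, 100 subjects per group, a sparse random base adjacency
(15% density, mixed signs, self-decay 0.2, rescaled to spectral radius 0.5),
five planted group-difference edges of weight $+0.35$ placed on empty
off-diagonal cells, innovation noise $\sigma = 0.5$. A stationarity guard
rejects any transition matrix with spectral radius $\ge 0.95$. The base
graph and planted edges come from a fixed internal seed, so the ground
truth is identical across runs; the user seed moves only the sampled
trajectories. The regime benchmark uses two shared regimes with dwell
probability 0.9 for group 0 (stationary occupancy 1/2 each) and a tilted
chain giving group 1 occupancy 0.8/0.2.

What this does **not** emulate: hemodynamic response convolution, scanner
noise spectra, inter-subject variability in the base graph, non-stationary
artifacts. Passing the benchmarks therefore shows the estimator recovers
planted linear directed structure under realistic sample sizes — not that
it resolves the neural substrate of BOLD dynamics.

For the simulated cohorts we train a reduced architecture
(`benchmark_config()`: hidden width 32, attention width 16, two heads) —
appropriate for 10-node graphs where the full 100/48 architecture would be
heavily over-parameterized — with Adam at $10^{-3}$, exponential decay, an
80-epoch cap and patience 25. Two observations from calibrating this
configuration are worth recording. First, a single head on these small
cohorts frequently spends its first dozens of epochs in a spurious basin
(the validation ranking transiently *inverts*) before converging; averaging
two heads escapes it almost immediately, consistent with multiple heads
stabilizing the estimated connectivity. Second, raising the L1 weight far
above the reference $10^{-6}$ (to $10^{-4}$) can collapse training
entirely on some seeds: the constant L1 subgradient dominates Adam's
normalized updates, shrinking the encoder toward the zero fixed point where
every connectivity matrix is uniform and no task gradient survives — so the
reference $\lambda$ is kept. On these cohorts a typical
trial trains in a few minutes on one CPU core; the validation suite uses
smaller variants of the same conditions (fewer subjects and trial seeds)
so the full suite completes in minutes.

## Downstream analyses

* `pearson_fnc()` computes the classic undirected per-subject correlation
  matrix; `normalize01 = TRUE` applies $(r+1)/2$, the affine map onto the
  $[0,1]$ range of the attention matrices. Correlation matrices are
  symmetric; the estimated directed matrices generally are not, and the mean
  $|W - W^\top|$ asymmetry is a useful diagnostic of how much directional
  information was added.
* `linear_baseline()` trains a ridge-penalized logistic model fold-wise on
  flattened connectivity features (the penalty is chosen on each fold's
  validation set), reporting mean/max/min/sd of the test AUCs — the
  apples-to-apples comparison between correlation features and learned
  directed features.
* `network_block_stats()` compares group means over network blocks with both
  Welch's t and Mann-Whitney U per comparison (two rows per comparison, as
  is conventional); within-network blocks exclude the diagonal. Unpaired
  tests are the default even when the two sides involve the same subjects,
  matching the two-sample table convention; `paired = TRUE` is available.
* `kmeans_states()` clusters all subjects' per-timepoint matrices into `k`
  recurring states, reports per-group occupancy, and tests per-state group
  differences over per-subject time-in-state fractions (not pooled
  timepoints, which would ignore within-subject dependence);
  `elbow_k()` picks `k` as the knee (arg-max discrete second difference) of
  the within-cluster sum-of-squares curve.
* `attention_stability()` scores per-subject mean pairwise correlation of
  attention vectors across independently seeded trainings.
* `topk_timepoint_experiment()` selects each subject's highest- (and
  lowest-) attention timepoints, averages the selected $W_t$, and runs the
  logistic baseline on each selection: if attention finds the informative
  interval, the top fraction retains most of the AUC and the bottom fraction
  does not. Aggregating the selected matrices by their mean (rather than
  treating them as separate samples) keeps one feature vector per subject
  and is the choice we document here.

## Numerical notes and degenerate inputs

* Constant series z-score to all zeros with a warning (flat artifact
  channels should not abort a run); zero-variance nodes give correlation 0
  (0.5 after mapping) with a warning.
* Row sums of every $W_t$ are within $10^{-5}$ of 1 by construction and are
  asserted across head counts in the tests; $W^f = \sum_t \alpha_t W_t$
  holds to $10^{-9}$.
* Cross-entropy is computed through a log-sum-exp; AUC is the rank statistic
  with ties counted half.
* k-means re-seeds up to 5 times on an empty cluster; a flat elbow curve
  returns the smallest candidate `k` with a warning.
* Every user-facing source of randomness takes a seed; two runs with the
  same configuration and seeds produce identical losses, estimates and fold
  plans (asserted in the tests).

## Known limitations

* **Edge-level attribution degrades with training.** On the VAR benchmark,
  the difference of group-mean aggregated matrices ranks the planted edges
  almost perfectly for a *barely trained* model (whose attention geometry
  mirrors lag-1 cross-correlation), but after the classifier converges the
  same ranking typically scores ~0.7 AUROC even while held-out
  classification exceeds 0.9: optimization re-encodes the discriminative
  structure in ways that spread attribution over correlated entries. A
  lag-1 cross-correlation oracle on the same data ranks the edges
  perfectly, so this is a property of the trained representation, not of
  the data. Group-difference matrices should therefore be read as showing
  *where* discriminative connectivity concentrates, not as an exact edge
  detector.
* **Temporal-attention polarity is not identified.** The attention score is
  a learned function of each timepoint's connectivity; a subject-dependent
  *dip* at informative timepoints separates the groups exactly as well as a
  peak, so the sign of the within-window attention contrast can flip
  between randomly-seeded trainings on the windowed benchmark (and the
  across-seed stability of the profile suffers accordingly). On real
  cohorts with many more subjects and longer training this symmetry may
  break in practice, but nothing in the objective enforces the
  peak-polarity reading.
* Attention weights are non-negative, so negative coupling appears only as
  low weight, not as sign — unlike correlation matrices.
* The VAR benchmarks validate linear dynamics only; attention can, in
  principle, exploit nonlinear structure the benchmark never exercises.
* Binary classification is the only training signal implemented; regression
  heads are out of scope.
* With very small validation sets, early stopping on validation
  cross-entropy is noisy; transient epochs where the validation ranking
  inverts before converging are visible on small simulated cohorts.
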