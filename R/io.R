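#' Construct a time-course dataset
#'
#' Container for a cohort of multivariate time series: `S` subjects, each a
#' `N x T` matrix of node signals (e.g. ICA component or ROI time-courses),
#' with a binary label per subject.
#'
#' @param data numeric array `[S, N, T]` (subjects x nodes x timepoints).
#' @param labels integer vector of length `S` with values in `{0, 1}`.
#' @param subject_ids character vector of unique subject identifiers.
#' @param node_names character vector of node names (length `N`).
#' @return An object of class `timecourse_dataset`.
#' @export
timecourse_dataset <- function(data, labels,
                               subject_ids = NULL, node_names = NULL) {
  if (length(dim(data)) != 3L)
    stop_dircon("data must be a 3-d array [subjects, nodes, timepoints]")
  S <- dim(data)[1L]; N <- dim(data)[2L]; TT <- dim(data)[3L]
  if (S < 1L || N < 2L || TT < 2L)
    stop_dircon("need at least 2 nodes and 2 timepoints")
  assert_finite(data, "time-course data")
  labels <- as.integer(labels)
  if (length(labels) != S || !all(labels %in% c(0L, 1L)))
    stop_dircon("labels must be a length-S vector with values in {0, 1}")
  if (is.null(subject_ids)) subject_ids <- sprintf("subj%03d", seq_len(S))
  if (anyDuplicated(subject_ids)) stop_dircon("subject_ids must be unique")
  if (is.null(node_names)) node_names <- sprintf("node%02d", seq_len(N))
  structure(
    list(data = data, labels = labels,
         subject_ids = as.character(subject_ids),
         node_names = as.character(node_names)),
    class = "timecourse_dataset")
}

#' @export
print.timecourse_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<timecourse_dataset> %d subjects x %d nodes x %d timepoints\n",
              d[1], d[2], d[3]))
  cat(sprintf("  labels: %d zeros, %d ones\n",
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' @export
dim.timecourse_dataset <- function(x) dim(x$data)

# Subset a dataset by subject indices.
subset_subjects <- function(ds, idx) {
  timecourse_dataset(ds$data[idx, , , drop = FALSE], ds$labels[idx],
                     ds$subject_ids[idx], ds$node_names)
}

#' Load a time-course dataset from disk
#'
#' Two on-disk layouts are supported.  `csv_manifest`: a TSV with columns
#' `subject_id`, `label`, `path`; each `path` points to a per-subject CSV with
#' nodes as rows and timepoints as columns (no header).  `rds_stack`: a single
#' RDS file holding a list with keys `data`, `labels`, `subject_ids`,
#' `node_names` as written by [save_timecourses()].
#'
#' @param manifest_path path to the manifest TSV or stack RDS.
#' @param format `"csv_manifest"` or `"rds_stack"`.
#' @param truncate_t if `TRUE`, subjects with differing series lengths are
#'   truncated to the shortest common length; otherwise ragged lengths are an
#'   error.
#' @return A [timecourse_dataset()].  No normalization is applied.
#' @export
load_timecourses <- function(manifest_path,
                             format = c("csv_manifest", "rds_stack"),
                             truncate_t = FALSE) {
  format <- match.arg(format)
  if (!file.exists(manifest_path))
    stop_dircon(sprintf("manifest not found: %s", manifest_path))
  if (format == "rds_stack") {
    obj <- readRDS(manifest_path)
    return(timecourse_dataset(obj$data, obj$labels, obj$subject_ids,
                              obj$node_names))
  }
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(man)))
    stop_dircon("manifest must have columns subject_id, label, path")
  base <- dirname(manifest_path)
  mats <- vector("list", nrow(man))
  for (k in seq_len(nrow(man))) {
    p <- man$path[k]
    if (!file.exists(p)) p2 <- file.path(base, p) else p2 <- p
    if (!file.exists(p2))
      stop_dircon(sprintf("missing time-course file for subject '%s': %s",
                          man$subject_id[k], man$path[k]))
    mats[[k]] <- as.matrix(utils::read.csv(p2, header = FALSE))
  }
  Ns <- vapply(mats, nrow, 1L)
  if (length(unique(Ns)) > 1L) {
    bad <- which(Ns != Ns[1L])[1L]
    stop_dircon(sprintf(
      "subject '%s' has %d nodes; expected %d (ragged node dimension)",
      man$subject_id[bad], Ns[bad], Ns[1L]))
  }
  Ts <- vapply(mats, ncol, 1L)
  if (length(unique(Ts)) > 1L) {
    if (!truncate_t) {
      bad <- which(Ts != Ts[1L])[1L]
      stop_dircon(sprintf(
        "subject '%s' has %d timepoints; expected %d (set truncate_t = TRUE to truncate)",
        man$subject_id[bad], Ts[bad], Ts[1L]))
    }
    Tmin <- min(Ts)
    warning(sprintf("truncating all subjects to T = %d", Tmin))
    mats <- lapply(mats, function(m) m[, seq_len(Tmin), drop = FALSE])
  }
  S <- length(mats); N <- Ns[1L]; TT <- ncol(mats[[1L]])
  data <- array(0, c(S, N, TT))
  for (k in seq_len(S)) data[k, , ] <- mats[[k]]
  timecourse_dataset(data, man$label, man$subject_id)
}

#' Save a time-course dataset
#'
#' Writes either a manifest TSV plus one CSV per subject (nodes as rows), or a
#' single RDS stack.  Inverse of [load_timecourses()].
#'
#' @param ds a [timecourse_dataset()].
#' @param path for `csv_manifest`, the manifest TSV path (per-subject CSVs are
#'   written next to it); for `rds_stack`, the RDS path.
#' @param format `"csv_manifest"` or `"rds_stack"`.
#' @return `path`, invisibly.
#' @export
save_timecourses <- function(ds, path,
                             format = c("csv_manifest", "rds_stack")) {
  format <- match.arg(format)
  if (format == "rds_stack") {
    saveRDS(list(data = ds$data, labels = ds$labels,
                 subject_ids = ds$subject_ids, node_names = ds$node_names),
            path)
    return(invisible(path))
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  rel <- sprintf("%s.csv", ds$subject_ids)
  for (k in seq_along(ds$subject_ids)) {
    utils::write.table(ds$data[k, , ], file.path(dirname(path), rel[k]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  man <- data.frame(subject_id = ds$subject_ids, label = ds$labels,
                    path = rel, stringsAsFactors = FALSE)
  utils::write.table(man, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a node-to-network partition
#'
#' TSV with columns `node_index` (1-based), `node_name`, `network`.
#'
#' @param path TSV path.
#' @param n_nodes expected number of nodes; every index `1..n_nodes` must be
#'   assigned exactly once.
#' @return A list with `assignment` (character vector of length `n_nodes`) and
#'   `networks` (ordered unique labels), class `network_partition`.
#' @export
load_partition <- function(path, n_nodes) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  network_partition(tab$network[order(tab$node_index)], n_nodes = n_nodes)
}

#' Construct a node-to-network partition
#'
#' @param assignment character vector: network label per node (in node order).
#' @param n_nodes optional expected node count.
#' @return A `network_partition` object.
#' @export
network_partition <- function(assignment, n_nodes = length(assignment)) {
  assignment <- as.character(assignment)
  if (length(assignment) != n_nodes || anyNA(assignment))
    stop_dircon("every node must have exactly one network label")
  structure(list(assignment = assignment, networks = unique(assignment)),
            class = "network_partition")
}

#' Standardize each node series to zero mean and unit variance
#'
#' z-scores every (subject, node) series independently.  Constant series are
#' mapped to all zeros with a warning (flat artifact components occur in
#' practice and should not abort a run).
#'
#' @param ds a [timecourse_dataset()].
#' @return The dataset with standardized series; idempotent to numerical
#'   tolerance.
#' @export
zscore_timecourses <- function(ds) {
  d <- ds$data
  S <- dim(d)[1L]; N <- dim(d)[2L]
  n_const <- 0L
  for (s in seq_len(S)) {
    x <- d[s, , , drop = TRUE]            # N x T
    if (is.null(dim(x))) x <- matrix(x, nrow = N)
    mu <- rowMeans(x)
    sdv <- apply(x, 1L, stats::sd)
    flat <- sdv < .Machine$double.eps^0.5
    n_const <- n_const + sum(flat)
    sdv[flat] <- 1
    z <- (x - mu) / sdv
    z[flat, ] <- 0
    d[s, , ] <- z
  }
  if (n_const > 0L)
    warning(sprintf("%d constant series mapped to zeros", n_const))
  ds$data <- d
  ds
}

#' Split long scans into equal-length chunks
#'
#' For long recordings the model is trained and evaluated on `n_chunks`
#' contiguous segments; downstream, per-chunk logits are averaged into the
#' final prediction.  If `T` is not divisible by `n_chunks`, trailing
#' timepoints are dropped with a warning.
#'
#' @param ds a [timecourse_dataset()].
#' @param n_chunks number of segments.
#' @return A list of `n_chunks` datasets, each with `T / n_chunks` timepoints.
#' @export
chunk_long_scans <- function(ds, n_chunks) {
  TT <- dim(ds$data)[3L]
  n_chunks <- as.integer(n_chunks)
  if (n_chunks < 1L || n_chunks > TT)
    stop_dircon("n_chunks must be between 1 and T")
  if (n_chunks == 1L) return(list(ds))
  len <- TT %/% n_chunks
  if (len * n_chunks != TT)
    warning(sprintf("T = %d not divisible by %d; dropping %d trailing timepoints",
                    TT, n_chunks, TT - len * n_chunks))
  lapply(seq_len(n_chunks), function(k) {
    idx <- ((k - 1L) * len + 1L):(k * len)
    timecourse_dataset(ds$data[, , idx, drop = FALSE], ds$labels,
                       ds$subject_ids, ds$node_names)
  })
}
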