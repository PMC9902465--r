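#' ROI time-series container
#'
#' A subject's T x N matrix of regional mean signals (timepoints in rows,
#' ROIs in columns) plus acquisition metadata. All connectivity estimators
#' in the package consume this container.
#'
#' @param data Numeric T x N matrix.
#' @param roi_labels Character vector of N ROI names; defaults to
#'   `ROI1..ROIN`.
#' @param tr_seconds Sampling interval in seconds.
#' @param subject_id Subject identifier.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, roi_labels = NULL, tr_seconds = 0.8,
                           subject_id = "sub") {
  data <- as.matrix(data)
  if (nrow(data) < 3) abort("need at least 3 timepoints")
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(ncol(data)))
  if (length(roi_labels) != ncol(data)) {
    abort("`roi_labels` length must match the number of ROI columns")
  }
  colnames(data) <- roi_labels
  structure(
    list(data = data, roi_labels = roi_labels, tr_seconds = tr_seconds,
         subject_id = subject_id),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s: T = %d, N = %d, TR = %gs\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

as_ts_matrix <- function(series) {
  if (inherits(series, "roi_timeseries")) series$data else as.matrix(series)
}

new_fc_matrix <- function(values, method, roi_labels = NULL) {
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(ncol(values)))
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(
    list(values = values, method = method, roi_labels = roi_labels),
    class = "fc_matrix"
  )
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %s, %d x %d\n", x$method,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Pearson-correlation functional connectivity
#'
#' The classical low-order FC estimate: the N x N matrix of pairwise
#' Pearson correlations between regional time series.
#'
#' @param series A [roi_timeseries()] or plain T x N matrix.
#' @return An `fc_matrix` with method tag `"PC"`: symmetric, unit
#'   diagonal, entries in `[-1, 1]`.
#' @export
pearson_fc <- function(series) {
  x <- as_ts_matrix(series)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant ROI signal(s): %s",
                  paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  v <- cor(x)
  diag(v) <- 1
  labels <- if (inherits(series, "roi_timeseries")) series$roi_labels else
    colnames(x)
  new_fc_matrix(v, "PC", labels)
}

#' Topographical high-order functional connectivity
#'
#' Correlation of correlation: entry (i, j) is the Pearson correlation
#' between ROI i's and ROI j's whole-brain connectivity profiles, taken
#' over the remaining ROIs k with k != i and k != j. The diagonal is set
#' to 1 by convention. Degenerate profiles (zero variance after the
#' exclusions) give 0 and are flagged in the `degenerate` attribute.
#'
#' @param lofc An `fc_matrix` with method tag `"PC"` (from
#'   [pearson_fc()]).
#' @return An `fc_matrix` with method tag `"tHOFC"`.
#' @export
thofc <- function(lofc) {
  stopifnot(inherits(lofc, "fc_matrix"))
  w <- lofc$values
  n <- nrow(w)
  if (n < 4) abort("tHOFC needs at least 4 ROIs")
  out <- diag(1, n)
  degenerate <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- setdiff(seq_len(n), c(i, j))
      r <- safe_cor(w[i, keep], w[j, keep])
      out[i, j] <- out[j, i] <- as.numeric(r)
      degenerate[i, j] <- degenerate[j, i] <- attr(r, "degenerate")
    }
  }
  res <- new_fc_matrix(out, "tHOFC", lofc$roi_labels)
  res$degenerate <- degenerate
  res
}

#' Sliding-window dynamic functional connectivity
#'
#' Computes the Pearson correlation of every ROI pair inside each
#' rectangular window of length `window_length` advanced by `step`,
#' giving Theta = floor((T - L) / s) + 1 windows. Rows index the
#' row-major upper-triangle pairs (i < j).
#'
#' @param series A [roi_timeseries()] or T x N matrix.
#' @param window_length Window length L in timepoints (3 <= L <= T).
#' @param step Step size s >= 1 in timepoints.
#' @return A `dynamic_fc` object: `window_series` (P x Theta matrix,
#'   P = N(N-1)/2), `pair_index`, `window_length`, `step`, `n_windows`,
#'   plus a logical `degenerate` matrix flagging constant-window entries
#'   (stored as 0).
#' @export
sliding_window_fc <- function(series, window_length, step = 1L) {
  x <- as_ts_matrix(series)
  t_points <- nrow(x)
  n <- ncol(x)
  window_length <- check_count(window_length, "window_length", min = 3L)
  step <- check_count(step, "step", min = 1L)
  if (window_length > t_points) abort("`window_length` exceeds series length")
  n_windows <- (t_points - window_length) %/% step + 1L
  pairs <- pair_index(n)
  p <- nrow(pairs)
  ws <- matrix(NA_real_, p, n_windows)
  degenerate <- matrix(FALSE, p, n_windows)
  for (th in seq_len(n_windows)) {
    t0 <- (th - 1L) * step + 1L
    seg <- x[t0:(t0 + window_length - 1L), , drop = FALSE]
    sds <- apply(seg, 2, sd)
    if (all(sds > 0)) {
      cm <- cor(seg)
      ws[, th] <- cm[pairs]
    } else {
      cs <- seg
      cs[, sds == 0] <- 0
      ok <- sds > 0
      cm <- matrix(0, n, n)
      if (sum(ok) >= 2) cm[ok, ok] <- cor(seg[, ok, drop = FALSE])
      ws[, th] <- cm[pairs]
      bad <- !ok[pairs[, 1]] | !ok[pairs[, 2]]
      degenerate[bad, th] <- TRUE
    }
  }
  labels <- if (inherits(series, "roi_timeseries")) series$roi_labels else
    colnames(x) %||% paste0("ROI", seq_len(n))
  rownames(ws) <- paste0(labels[pairs[, 1]], "-", labels[pairs[, 2]])
  structure(
    list(window_series = ws, pair_index = pairs,
         window_length = window_length, step = step, n_windows = n_windows,
         roi_labels = labels, degenerate = degenerate),
    class = "dynamic_fc"
  )
}

#' @export
print.dynamic_fc <- function(x, ...) {
  cat(sprintf("<dynamic_fc> %d pairs x %d windows (L = %d, s = %d)\n",
              nrow(x$window_series), x$n_windows, x$window_length, x$step))
  invisible(x)
}

#' Ward clustering of dynamic-connectivity pair series
#'
#' Groups the P ROI-pair window series into K clusters with Ward's
#' minimum-variance linkage on Euclidean distances (`hclust` method
#' `ward.D2`), the standard dimension-reduction step before building the
#' K x K dynamics-based high-order network.
#'
#' @param dyn A `dynamic_fc` from [sliding_window_fc()].
#' @param k_clusters Number of clusters K, 2 <= K <= P (K = 1 allowed for
#'   the degenerate single-cluster case).
#' @return Integer vector of cluster ids (1..K), one per ROI pair.
#' @export
ward_cluster_pairs <- function(dyn, k_clusters) {
  stopifnot(inherits(dyn, "dynamic_fc"))
  p <- nrow(dyn$window_series)
  k_clusters <- check_count(k_clusters, "k_clusters", min = 1L)
  if (k_clusters > p) abort("`k_clusters` exceeds the number of ROI pairs")
  if (k_clusters == p) return(seq_len(p))
  hc <- hclust(dist(dyn$window_series), method = "ward.D2")
  cutree(hc, k = k_clusters)
}

#' Dynamics-based high-order functional connectivity network
#'
#' Averages the window series of each cluster's member pairs (unweighted)
#' and correlates the K cluster-mean series, yielding the K x K network
#' that summarizes how the dynamics of one set of connections track the
#' dynamics of another.
#'
#' @param dyn A `dynamic_fc`.
#' @param assignments Integer cluster ids from [ward_cluster_pairs()].
#' @return A `dhofc_result`: `assignments`, `cluster_mean_series`
#'   (K x Theta), `network` (K x K, symmetric, unit diagonal),
#'   `k_clusters`, and a `degenerate` flag matrix.
#' @export
dhofc_network <- function(dyn, assignments) {
  stopifnot(inherits(dyn, "dynamic_fc"))
  if (length(assignments) != nrow(dyn$window_series)) {
    abort("one assignment per ROI pair required")
  }
  k <- max(assignments)
  means <- matrix(0, k, dyn$n_windows)
  for (cl in seq_len(k)) {
    rows <- which(assignments == cl)
    if (length(rows) == 0) abort(sprintf("cluster %d is empty", cl))
    means[cl, ] <- colMeans(dyn$window_series[rows, , drop = FALSE])
  }
  net <- diag(1, k)
  degenerate <- matrix(FALSE, k, k)
  if (k > 1) {
    for (p in seq_len(k - 1)) {
      for (q in (p + 1):k) {
        r <- safe_cor(means[p, ], means[q, ])
        net[p, q] <- net[q, p] <- as.numeric(r)
        degenerate[p, q] <- degenerate[q, p] <- attr(r, "degenerate")
      }
    }
  }
  structure(
    list(assignments = assignments, cluster_mean_series = means,
         network = net, k_clusters = k, degenerate = degenerate,
         pair_index = dyn$pair_index, roi_labels = dyn$roi_labels),
    class = "dhofc_result"
  )
}

#' Full dynamics-based high-order pipeline
#'
#' Convenience wrapper: sliding windows, Ward clustering, K x K network.
#'
#' @inheritParams sliding_window_fc
#' @inheritParams ward_cluster_pairs
#' @return A `dhofc_result`.
#' @export
dhofc <- function(series, window_length, k_clusters, step = 1L) {
  dyn <- sliding_window_fc(series, window_length, step)
  assignments <- ward_cluster_pairs(dyn, k_clusters)
  dhofc_network(dyn, assignments)
}
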