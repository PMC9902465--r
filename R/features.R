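#' Subjects-by-features table
#'
#' The container consumed by the classification stage: a numeric feature
#' matrix with one row per subject, aligned binary labels (levels
#' `control`, `case`) and a covariate tibble.
#'
#' @param features Numeric subjects x features matrix with unique column
#'   names.
#' @param labels Factor (or coercible) with levels control/case.
#' @param covariates Tibble of per-subject covariates (may be empty).
#' @param modality Modality tag recorded on the table.
#' @return A `feature_table`.
#' @export
feature_table <- function(features, labels, covariates = NULL,
                          modality = "features") {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  if (anyDuplicated(colnames(features))) {
    abort("feature names must be unique")
  }
  labels <- factor(labels, levels = c("control", "case"))
  if (length(labels) != nrow(features)) {
    abort("one label per subject row required")
  }
  if (any(!is.finite(features))) abort("feature matrix must be finite")
  covariates <- covariates %||%
    tibble::tibble(.rows = nrow(features))
  if (nrow(covariates) != nrow(features)) {
    abort("one covariate row per subject required")
  }
  structure(
    list(features = features, labels = labels, covariates = covariates,
         modality = modality),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d subjects x %d features (%d case / %d control)\n",
              x$modality, nrow(x$features), ncol(x$features),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' @method as_tibble feature_table
#' @export
as_tibble.feature_table <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(label = x$labels),
    x$covariates,
    tibble::as_tibble(x$features)
  )
}

#' Vectorize a connectivity matrix, high-order network or voxel map
#'
#' FC matrices become their upper triangle (row-major, diagonal excluded,
#' N(N-1)/2 features); dynamics-based high-order results become the upper
#' triangle of the K x K cluster network; voxel maps become the in-mask
#' voxel values. Names carry the modality tag and the ROI-pair,
#' cluster-pair or voxel identity.
#'
#' @param x An `fc_matrix`, `dhofc_result` or `voxel_map`.
#' @param modality_tag Tag prefixed to feature names; defaults to the
#'   object's own method/measure tag.
#' @return Named numeric feature row.
#' @export
vectorize <- function(x, modality_tag = NULL) {
  if (inherits(x, "fc_matrix")) {
    if (max(abs(x$values - t(x$values))) > 1e-8) {
      abort("asymmetric FC matrix: apply symmetrize() first")
    }
    tag <- modality_tag %||% x$method
    idx <- pair_index(nrow(x$values))
    vals <- x$values[idx]
    names(vals) <- paste0(tag, "|", x$roi_labels[idx[, 1]], "-",
                          x$roi_labels[idx[, 2]])
    vals
  } else if (inherits(x, "dhofc_result")) {
    tag <- modality_tag %||% "dHOFC"
    k <- x$k_clusters
    if (k < 2) {
      return(setNames(numeric(0), character(0)))
    }
    idx <- pair_index(k)
    vals <- x$network[idx]
    names(vals) <- paste0(tag, "|C", idx[, 1], "-C", idx[, 2])
    vals
  } else if (inherits(x, "voxel_map")) {
    tag <- modality_tag %||% x$measure
    vals <- x$values[x$mask]
    names(vals) <- paste0(tag, "|v", which(as.vector(x$mask)))
    vals
  } else {
    abort("cannot vectorize this object")
  }
}

#' Rebuild a symmetric matrix from a vectorized feature row
#'
#' Inverse of [vectorize()] for FC-type rows: off-diagonal entries are
#' restored exactly, the diagonal is set to `diag_value`.
#'
#' @param row Numeric vector of length N(N-1)/2.
#' @param n Matrix dimension N.
#' @param diag_value Diagonal fill.
#' @return N x N symmetric matrix.
#' @export
unvectorize <- function(row, n, diag_value = 0) {
  idx <- pair_index(n)
  if (length(row) != nrow(idx)) {
    abort("length of `row` does not match n(n-1)/2")
  }
  m <- diag(diag_value, n)
  m[idx] <- row
  m[idx[, c(2, 1)]] <- row
  m
}

#' Extract a per-measure feature table from a cohort
#'
#' Computes the requested connectivity measure for every subject and
#' stacks the vectorized results. For the dynamics-based high-order
#' measure, pairs are clustered once on the pooled window series of all
#' subjects so cluster identities align across subjects, then each
#' subject's K x K network is built from its own windows with the shared
#' assignment.
#'
#' @param cohort A `cohort`.
#' @param measure One of `"PC"`, `"tHOFC"`, `"dHOFC"`, `"SR"`, `"SLR"`,
#'   `"GSR"`, `"SSGSR"`.
#' @param params An [sr_params()] for the sparse estimators.
#' @param window_length,k_clusters,step Dynamic high-order settings.
#' @return A [feature_table()] with the cohort's labels and covariates.
#' @export
cohort_features <- function(cohort, measure = "PC",
                            params = NULL,
                            window_length = 50L, k_clusters = 10L,
                            step = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  measure <- match.arg(measure,
                       c("PC", "tHOFC", "dHOFC", "SR", "SLR", "GSR", "SSGSR"))
  subjects <- cohort$subjects
  rows <- switch(
    measure,
    PC = lapply(subjects, function(s) vectorize(pearson_fc(s))),
    tHOFC = lapply(subjects, function(s) vectorize(thofc(pearson_fc(s)))),
    dHOFC = {
      dyns <- lapply(subjects, sliding_window_fc,
                     window_length = window_length, step = step)
      pooled <- do.call(cbind, lapply(dyns, `[[`, "window_series"))
      pooled_dyn <- dyns[[1]]
      pooled_dyn$window_series <- pooled
      pooled_dyn$n_windows <- ncol(pooled)
      assignments <- ward_cluster_pairs(pooled_dyn, k_clusters)
      lapply(dyns, function(d) vectorize(dhofc_network(d, assignments)))
    },
    SR = lapply(subjects, function(s) {
      vectorize(symmetrize(solve_sr(s, params %||% sr_params(0.01))))
    }),
    SLR = lapply(subjects, function(s) {
      vectorize(symmetrize(solve_slr(
        s, params %||% sr_params(lambda1 = 0.05, lambda2 = 0.08))))
    }),
    GSR = {
      fcs <- solve_gsr(cohort, params %||% sr_params(0.01))
      lapply(fcs, function(fc) vectorize(symmetrize(fc)))
    },
    SSGSR = {
      fcs <- solve_ssgsr(cohort,
                         params %||% sr_params(lambda1 = 0.06,
                                               lambda2 = 0.01))
      lapply(fcs, function(fc) vectorize(symmetrize(fc)))
    }
  )
  features <- do.call(rbind, rows)
  rownames(features) <- cohort$covariates$subject_id
  feature_table(features, cohort$labels, cohort$covariates,
                modality = measure)
}

#' Residualize features on nuisance covariates
#'
#' Replaces each feature by its least-squares residual on an intercept
#' plus the named covariates (categorical covariates one-hot encoded), so
#' downstream classifiers cannot exploit sex, scanner, site or motion
#' differences. Residuals are exactly orthogonal to the design.
#'
#' @param table A [feature_table()].
#' @param covariate_names Covariate columns to remove; default all except
#'   `subject_id`.
#' @return A residualized [feature_table()].
#' @export
residualize <- function(table, covariate_names = NULL) {
  stopifnot(inherits(table, "feature_table"))
  covs <- table$covariates
  covariate_names <- covariate_names %||%
    setdiff(names(covs), "subject_id")
  if (length(covariate_names) == 0) return(table)
  design_df <- as.data.frame(covs[, covariate_names, drop = FALSE])
  design <- model.matrix(~., data = design_df)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warn(sprintf("dropping %d linearly dependent covariate column(s)",
                 ncol(design) - qrd$rank))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  table$features <- qr.resid(qrd, table$features)
  table$residualized <- covariate_names
  table
}

subset_table <- function(table, rows) {
  table$features <- table$features[rows, , drop = FALSE]
  table$labels <- table$labels[rows]
  table$covariates <- table$covariates[rows, , drop = FALSE]
  table
}

select_features <- function(table, mask) {
  table$features <- table$features[, mask, drop = FALSE]
  table
}
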