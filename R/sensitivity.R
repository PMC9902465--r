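#' Parameter-sensitivity protocol
#'
#' For every point of a parameter grid, recomputes the measure on the
#' cohort, residualizes the features and runs a plain (non-nested)
#' stratified 10-fold cross-validation with an RBF-kernel SVM at fixed
#' `C = 1`, recording the mean AUC. The winning point (ties broken toward
#' the smallest parameter values) is the suggested setting for the
#' subsequent nested evaluation. Grids follow the measure's shape:
#' `list(k_clusters = ..., window_length = ...)` for the dynamic
#' high-order measure, `list(lambda1 = ...)` for SR/GSR,
#' `list(lambda1 = ..., lambda2 = ...)` for SSGSR/SLR.
#'
#' @param cohort A `cohort`.
#' @param measure Measure tag as in [cohort_features()].
#' @param grid Named list of parameter value vectors.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for fold assignment.
#' @param residualize_features Remove covariate structure first.
#' @return A `sensitivity_result`: tibble of grid points with `mean_auc`,
#'   plus the selected `best` row.
#' @export
parameter_sensitivity <- function(cohort, measure, grid, folds = 10L,
                                  seed = 1L, residualize_features = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  # Ascending lexicographic order so argmax ties resolve to the smallest
  # parameter values.
  combos <- combos[do.call(order, as.list(combos)), , drop = FALSE]
  rownames(combos) <- NULL
  mean_auc <- rep(NA_real_, nrow(combos))
  spec <- classifier_spec("svm_rbf", grid = list(cost = 1))
  for (g in seq_len(nrow(combos))) {
    pars <- as.list(combos[g, , drop = FALSE])
    tab <- tryCatch({
      args <- list(cohort = cohort, measure = measure)
      if (measure %in% c("SR", "GSR")) {
        args$params <- sr_params(lambda1 = pars$lambda1)
      } else if (measure %in% c("SLR", "SSGSR")) {
        args$params <- sr_params(lambda1 = pars$lambda1,
                                 lambda2 = pars$lambda2)
      } else if (measure == "dHOFC") {
        args$window_length <- pars$window_length
        args$k_clusters <- pars$k_clusters
      }
      do.call(cohort_features, args)
    }, error = function(e) {
      warn(sprintf("grid point %d failed: %s", g, conditionMessage(e)))
      NULL
    })
    if (is.null(tab)) next
    if (residualize_features) tab <- residualize(tab)
    fold_id <- stratified_folds(tab$labels, folds, seed)
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_classifier(spec, tab$features[tr, , drop = FALSE],
                            tab$labels[tr], list(cost = 1),
                            seed = derive_seed(seed, f))
      auc_score(predict_scores(fit, tab$features[!tr, , drop = FALSE]),
                tab$labels[!tr])
    }, numeric(1))
    mean_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  res <- tibble::as_tibble(combos)
  res$mean_auc <- mean_auc
  if (all(is.na(mean_auc))) {
    abort("every grid point failed")
  }
  best_idx <- which(mean_auc == max(mean_auc, na.rm = TRUE))[1]
  structure(
    list(table = res, best = res[best_idx, , drop = FALSE],
         measure = measure, folds = folds, seed = seed),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %s over %d grid points\n",
              x$measure, nrow(x$table)))
  cat("best: ")
  print(x$best)
  invisible(x)
}

#' @method autoplot sensitivity_result
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  tab <- object$table
  par_cols <- setdiff(names(tab), "mean_auc")
  if (length(par_cols) == 1) {
    ggplot2::ggplot(tab, ggplot2::aes(x = .data[[par_cols[1]]],
                                      y = .data$mean_auc)) +
      ggplot2::geom_col(width = diff(range(tab[[par_cols[1]]])) /
                          (2 * nrow(tab)) + 1e-9) +
      ggplot2::labs(y = "mean 10-fold AUC",
                    title = sprintf("Parameter sensitivity (%s)",
                                    object$measure)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tab, ggplot2::aes(
      x = factor(.data[[par_cols[1]]]), y = factor(.data[[par_cols[2]]]),
      fill = .data$mean_auc)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = par_cols[1], y = par_cols[2], fill = "mean AUC",
                    title = sprintf("Parameter sensitivity (%s)",
                                    object$measure)) +
      ggplot2::theme_minimal()
  }
}
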