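#' Stratified fold assignment
#'
#' Shuffles each class independently and deals subjects round-robin into
#' `k` folds, so per-fold class proportions are within one subject of the
#' global ratio and test indices partition the cohort.
#'
#' @param labels Factor of subject labels.
#' @param k Number of folds.
#' @param seed Seed for the shuffles.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    for (lev in levels(labels)) {
      idx <- which(labels == lev)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midpoint handling of tied scores,
#' equivalent to the trapezoidal rule over all thresholds; all-tied
#' scores give exactly 0.5.
#'
#' @param scores Continuous scores, larger favouring the case class.
#' @param labels Factor control/case.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == "case"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts from hard predictions
#'
#' @param predicted,actual Factors with levels control/case; `case` is
#'   the positive class.
#' @return A list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, actual) {
  list(
    tp = sum(predicted == "case" & actual == "case"),
    tn = sum(predicted == "control" & actual == "control"),
    fp = sum(predicted == "case" & actual == "control"),
    fn = sum(predicted == "control" & actual == "case")
  )
}

#' Classification metrics
#'
#' Accuracy, precision, recall and F1 from confusion counts, plus ROC AUC
#' when continuous scores are supplied. Ratios with zero denominators are
#' reported as 0 and flagged.
#'
#' @param counts Output of [confusion_counts()] (or a list with tp, tn,
#'   fp, fn).
#' @param scores Optional continuous scores for the AUC.
#' @param labels Labels matching `scores`.
#' @return One-row tibble: acc, precision, recall, f1, auc,
#'   degenerate flag.
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else {
      num / den
    }
  }
  acc <- ratio(tp + tn, total)
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (precision + recall == 0) {
    degenerate <- TRUE
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  auc <- if (!is.null(scores)) auc_score(scores, labels) else NA_real_
  tibble::tibble(acc = acc, precision = precision, recall = recall,
                 f1 = f1, auc = auc, degenerate = degenerate)
}

score_threshold <- function(spec_name) {
  # Probability-type learners are cut at 1/2, margin-type at 0.
  if (spec_name %in% c("knn", "gnb", "rf", "gbt")) 0.5 else 0
}

inner_grid_search <- function(spec, x, y, inner_k, seed) {
  configs <- expand_grid_configs(spec$grid)
  if (length(configs) == 1) {
    return(list(config = configs[[1]], inner_auc = NA_real_))
  }
  folds <- stratified_folds(y, inner_k, seed)
  mean_aucs <- vapply(configs, function(cfg) {
    aucs <- vapply(seq_len(inner_k), function(f) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < 2 || sum(!tr) == 0) return(NA_real_)
      fit <- fit_classifier(spec, x[tr, , drop = FALSE], y[tr], cfg,
                            seed = derive_seed(seed, f))
      auc_score(predict_scores(fit, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(mean_aucs)  # ties: first (smallest) configuration
  list(config = configs[[best]], inner_auc = mean_aucs[best])
}

#' Nested cross-validation
#'
#' Outer stratified k-fold estimates generalization; inside each outer
#' training set, shadow-feature selection picks the candidate features
#' and an inner stratified k-fold grid search (by AUC) tunes each
#' classifier. The winning configuration is refit on the full outer
#' training set and evaluated once on the untouched outer test fold.
#' Selection and tuning never see outer-test rows; `audit_poison = TRUE`
#' overwrites the outer-test feature rows with noise immediately after
#' each split, which must leave every selection and tuning decision
#' unchanged (the leakage audit used by the test suite).
#'
#' @param table A [feature_table()] (residualize first if desired).
#' @param classifiers List of [classifier_spec()]s (default: RBF SVM).
#' @param outer_k,inner_k Fold counts (default 10 and 5).
#' @param seed Global seed; fold splits, selection and stochastic
#'   learners all derive from it.
#' @param selector `"boruta"` or `"none"`.
#' @param selector_args Arguments forwarded to [boruta_select()].
#' @param audit_poison Leakage audit switch (see above).
#' @return A `cv_report`: per-fold metrics tibble, selected features per
#'   fold, chosen configurations, seed.
#' @export
nested_cv <- function(table, classifiers = list(classifier_spec("svm_rbf")),
                      outer_k = 10L, inner_k = 5L, seed = 1L,
                      selector = c("boruta", "none"),
                      selector_args = list(), audit_poison = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  selector <- match.arg(selector)
  if (inherits(classifiers, "classifier_spec")) {
    classifiers <- list(classifiers)
  }
  if (is.null(names(classifiers)) || any(names(classifiers) == "")) {
    names(classifiers) <- vapply(classifiers, `[[`, character(1), "name")
  }
  y <- table$labels
  if (min(table(y)) < outer_k) {
    abort("need at least `outer_k` subjects per class for stratification")
  }
  folds <- stratified_folds(y, outer_k, seed)
  metrics <- list()
  selected <- vector("list", outer_k)
  chosen <- vector("list", outer_k)
  for (f in seq_len(outer_k)) {
    test_rows <- folds == f
    work <- table
    if (audit_poison) {
      work$features[test_rows, ] <- with_seed(
        derive_seed(seed, 777000L + f),
        matrix(rnorm(sum(test_rows) * ncol(work$features)),
               nrow = sum(test_rows))
      )
    }
    train_tab <- subset_table(work, which(!test_rows))
    fold_seed <- derive_seed(seed, f)
    mask <- if (selector == "boruta") {
      do.call(boruta_select,
              c(list(train_tab, seed = fold_seed), selector_args))
    } else {
      rep(TRUE, ncol(train_tab$features))
    }
    if (!any(mask)) {
      # No feature cleared the shadow test; keep everything and flag it.
      mask <- rep(TRUE, ncol(train_tab$features))
      attr(mask, "fallback_all") <- TRUE
    }
    selected[[f]] <- colnames(train_tab$features)[mask]
    x_train <- train_tab$features[, mask, drop = FALSE]
    x_test <- work$features[test_rows, mask, drop = FALSE]
    chosen[[f]] <- list()
    for (cl_name in names(classifiers)) {
      spec <- classifiers[[cl_name]]
      tune <- inner_grid_search(spec, x_train, train_tab$labels, inner_k,
                                derive_seed(fold_seed, match(cl_name,
                                                             names(classifiers))))
      fit <- fit_classifier(spec, x_train, train_tab$labels, tune$config,
                            seed = fold_seed)
      scores <- predict_scores(fit, x_test)
      thr <- score_threshold(spec$name)
      pred <- factor(ifelse(scores > thr, "case", "control"),
                     levels = c("control", "case"))
      row <- compute_metrics(confusion_counts(pred, y[test_rows]),
                             scores, y[test_rows])
      row$fold <- f
      row$classifier <- cl_name
      row$n_selected <- sum(mask)
      metrics[[length(metrics) + 1]] <- row
      chosen[[f]][[cl_name]] <- tune$config
    }
  }
  structure(
    list(metrics = dplyr::bind_rows(metrics), selected = selected,
         chosen = chosen, outer_k = outer_k, inner_k = inner_k,
         seed = seed, folds = folds, modality = table$modality),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: %d outer folds\n", x$modality, x$outer_k))
  print(glance(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-fold metrics of a nested-CV run
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with one row per fold and classifier.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  dplyr::select(x$metrics, "fold", "classifier", "auc", "acc",
                "precision", "recall", "f1", "n_selected")
}

#' Fold-averaged summary of a nested-CV run
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with one row per classifier (mean metrics over folds).
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$metrics, .data$classifier),
    dplyr::across(c("auc", "acc", "precision", "recall", "f1"),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
}

#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$classifier, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = NULL, y = "outer-fold AUC",
                  title = sprintf("Nested CV (%s)", object$modality)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
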