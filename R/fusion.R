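#' Early fusion by feature concatenation
#'
#' Column-binds the (typically per-modality, already selected) feature
#' tables of the same subjects; feature names keep their modality tags
#' and are disambiguated if duplicated.
#'
#' @param tables List of [feature_table()]s over identical subjects in
#'   identical order.
#' @return A single [feature_table()] with modality `"fusion"`.
#' @export
early_fuse <- function(tables) {
  if (inherits(tables, "feature_table")) return(tables)
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]
  ids <- ref$covariates$subject_id
  for (tab in tables[-1]) {
    if (nrow(tab$features) != nrow(ref$features) ||
        !identical(tab$covariates$subject_id, ids) ||
        !identical(tab$labels, ref$labels)) {
      bad <- if (!is.null(ids) && !is.null(tab$covariates$subject_id)) {
        paste(setdiff(union(ids, tab$covariates$subject_id),
                      intersect(ids, tab$covariates$subject_id)),
              collapse = ", ")
      } else {
        "row mismatch"
      }
      abort(sprintf("tables cover different subjects: %s", bad))
    }
  }
  features <- do.call(cbind, lapply(tables, `[[`, "features"))
  colnames(features) <- make.unique(colnames(features))
  feature_table(features, ref$labels, ref$covariates, modality = "fusion")
}

#' Per-modality Gram matrices
#'
#' Builds one kernel per modality: RBF with the median-pairwise-distance
#' bandwidth heuristic (or linear), centered in feature space and
#' trace-normalized to the number of subjects. Training parameters
#' (bandwidth, centering statistics, training features) are retained so
#' matching test-vs-train kernels can be formed later.
#'
#' @param tables List of [feature_table()]s (training subjects).
#' @param kernel_kind `"rbf"` or `"linear"`.
#' @param center Center the kernel in feature space (default TRUE).
#' @return A `kernel_set`: `grams` (list of S x S matrices),
#'   `modality_tags`, `params`, `weights` (NULL until fitted).
#' @export
build_kernels <- function(tables, kernel_kind = c("rbf", "linear"),
                          center = TRUE) {
  kernel_kind <- match.arg(kernel_kind)
  if (inherits(tables, "feature_table")) tables <- list(tables)
  grams <- list()
  params <- list()
  tags <- character(0)
  for (tab in tables) {
    x <- tab$features
    if (all(apply(x, 2, sd) == 0)) {
      abort(sprintf("zero-variance modality: %s", tab$modality))
    }
    if (kernel_kind == "rbf") {
      d <- as.matrix(dist(x))
      med <- median(d[upper.tri(d)])
      if (med == 0) med <- 1
      gamma <- 1 / (2 * med^2)
      k <- exp(-gamma * d^2)
    } else {
      gamma <- NA_real_
      k <- tcrossprod(x)
    }
    s <- nrow(x)
    if (center) {
      mu_j <- colMeans(k)
      mu <- mean(k)
      kc <- k - matrix(mu_j, s, s, byrow = TRUE) -
        matrix(mu_j, s, s) + mu
    } else {
      mu_j <- rep(0, s)
      mu <- 0
      kc <- k
    }
    kc <- clip_psd(kc)
    scale <- s / sum(diag(kc))
    grams[[length(grams) + 1]] <- kc * scale
    params[[length(params) + 1]] <- list(
      kind = kernel_kind, gamma = gamma, train_x = x, mu_j = mu_j,
      mu = mu, scale = scale, center = center
    )
    tags <- c(tags, tab$modality)
  }
  names(grams) <- tags
  names(params) <- tags
  structure(list(grams = grams, modality_tags = tags, params = params,
                 weights = NULL),
            class = "kernel_set")
}

clip_psd <- function(k, tol = 1e-8) {
  k <- (k + t(k)) / 2
  e <- eigen(k, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1)) {
    abort("kernel is not positive semi-definite")
  }
  if (min(e$values) < 0) {
    k <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    k <- (k + t(k)) / 2
  }
  k
}

#' Test-vs-train kernels for a fitted kernel set
#'
#' @param kernels A `kernel_set` from [build_kernels()].
#' @param tables Test-subject [feature_table()]s with matching modality
#'   tags.
#' @return List of m x S cross-kernel matrices (centered and scaled with
#'   the training statistics).
#' @export
build_cross_kernels <- function(kernels, tables) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  tags <- vapply(tables, `[[`, character(1), "modality")
  if (!setequal(tags, kernels$modality_tags)) {
    abort("test modalities do not match the fitted kernel set")
  }
  out <- list()
  for (tab in tables) {
    p <- kernels$params[[tab$modality]]
    if (p$kind == "rbf") {
      d2 <- outer(rowSums(tab$features^2), rowSums(p$train_x^2), "+") -
        2 * tab$features %*% t(p$train_x)
      k <- exp(-p$gamma * pmax(d2, 0))
    } else {
      k <- tab$features %*% t(p$train_x)
    }
    kc <- if (isTRUE(p$center)) {
      k - matrix(rowMeans(k), nrow(k), ncol(k)) -
        matrix(p$mu_j, nrow(k), ncol(k), byrow = TRUE) + p$mu
    } else {
      k
    }
    out[[tab$modality]] <- kc * p$scale
  }
  out[kernels$modality_tags]
}

#' Multiple kernel learning by centered-kernel alignment
#'
#' Weights each modality kernel by the positive part of its alignment
#' with the label kernel `y y^T` (centered labels), normalized onto the
#' probability simplex, then trains a least-squares kernel machine
#' (kernel ridge on +/-1 labels) on the convex combination. Deterministic
#' given its inputs.
#'
#' @param kernels A `kernel_set`.
#' @param labels Factor control/case for the training subjects.
#' @param regularization Ridge weight on the combined kernel.
#' @return An `mkl_model`: simplex `weights`, dual coefficients, training
#'   labels, the kernel set.
#' @export
mkl_fit <- function(kernels, labels, regularization = 1) {
  stopifnot(inherits(kernels, "kernel_set"))
  labels <- factor(labels, levels = c("control", "case"))
  if (min(table(labels)) < 2) abort("need at least 2 subjects per class")
  y <- ifelse(labels == "case", 1, -1)
  yc <- y - mean(y)
  yk <- tcrossprod(yc)
  align <- vapply(kernels$grams, function(k) {
    denom <- sqrt(sum(k^2)) * sqrt(sum(yk^2))
    if (denom == 0) 0 else sum(k * yk) / denom
  }, numeric(1))
  w <- pmax(align, 0)
  if (sum(w) == 0) w <- rep(1, length(w))
  w <- w / sum(w)
  combined <- Reduce(`+`, Map(`*`, kernels$grams, w))
  combined <- clip_psd(combined)
  s <- nrow(combined)
  alpha <- solve(combined + regularization * diag(s), y)
  kernels$weights <- w
  structure(
    list(weights = setNames(w, kernels$modality_tags), alpha = alpha,
         labels = labels, kernels = kernels,
         regularization = regularization),
    class = "mkl_model"
  )
}

#' Score new subjects with a fitted MKL model
#'
#' @param model An `mkl_model`.
#' @param tables Test [feature_table()]s (same modalities as training),
#'   or a precomputed list of cross-kernels from [build_cross_kernels()].
#' @return Continuous scores; threshold at 0 for hard labels.
#' @export
mkl_predict <- function(model, tables) {
  cross <- if (is.list(tables) && !inherits(tables[[1]], "feature_table") &&
               is.matrix(tables[[1]])) {
    tables[model$kernels$modality_tags]
  } else {
    build_cross_kernels(model$kernels, tables)
  }
  if (any(vapply(cross, is.null, logical(1)))) {
    abort("cross-kernel modalities do not match the fitted model")
  }
  combined <- Reduce(`+`, Map(`*`, cross, model$weights))
  as.numeric(combined %*% model$alpha)
}

#' @export
print.mkl_model <- function(x, ...) {
  cat("<mkl_model> kernel weights:\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @method tidy mkl_model
#' @export
tidy.mkl_model <- function(x, ...) {
  tibble::tibble(modality = names(x$weights), weight = unname(x$weights))
}

#' Multi-modal nested cross-validation
#'
#' Evaluates early fusion and multiple kernel learning under the same
#' outer-fold protocol as the unimodal [nested_cv()]: inside each outer
#' training fold, shadow-feature selection runs per modality, kernels and
#' alignment weights are fitted on training subjects only, and the outer
#' test fold is touched exactly once.
#'
#' @param tables List of per-modality [feature_table()]s (same subjects).
#' @param methods Subset of `c("early", "mkl")`.
#' @param classifier [classifier_spec()] used for early fusion.
#' @param outer_k,inner_k,seed,selector,selector_args As in
#'   [nested_cv()].
#' @param regularization Ridge weight for the MKL machine.
#' @return A `cv_report` whose `classifier` column distinguishes
#'   `early_<name>` and `mkl`.
#' @export
fusion_cv <- function(tables, methods = c("early", "mkl"),
                      classifier = classifier_spec("svm_rbf"),
                      outer_k = 10L, inner_k = 5L, seed = 1L,
                      selector = c("boruta", "none"),
                      selector_args = list(), regularization = 1) {
  selector <- match.arg(selector)
  methods <- match.arg(methods, several.ok = TRUE)
  ref <- tables[[1]]
  y <- ref$labels
  folds <- stratified_folds(y, outer_k, seed)
  metrics <- list()
  selected <- vector("list", outer_k)
  for (f in seq_len(outer_k)) {
    test_rows <- folds == f
    fold_seed <- derive_seed(seed, f)
    train_tabs <- list()
    test_tabs <- list()
    sel_names <- character(0)
    for (m in seq_along(tables)) {
      tr <- subset_table(tables[[m]], which(!test_rows))
      mask <- if (selector == "boruta") {
        do.call(boruta_select,
                c(list(tr, seed = derive_seed(fold_seed, m)), selector_args))
      } else {
        rep(TRUE, ncol(tr$features))
      }
      if (!any(mask)) mask <- rep(TRUE, ncol(tr$features))
      train_tabs[[m]] <- select_features(tr, mask)
      te <- subset_table(tables[[m]], which(test_rows))
      test_tabs[[m]] <- select_features(te, mask)
      sel_names <- c(sel_names, colnames(tr$features)[mask])
    }
    selected[[f]] <- sel_names
    if ("early" %in% methods) {
      fused_train <- early_fuse(train_tabs)
      fused_test <- early_fuse(test_tabs)
      tune <- inner_grid_search(classifier, fused_train$features,
                                fused_train$labels, inner_k,
                                derive_seed(fold_seed, 51L))
      fit <- fit_classifier(classifier, fused_train$features,
                            fused_train$labels, tune$config,
                            seed = fold_seed)
      scores <- predict_scores(fit, fused_test$features)
      thr <- score_threshold(classifier$name)
      pred <- factor(ifelse(scores > thr, "case", "control"),
                     levels = c("control", "case"))
      row <- compute_metrics(confusion_counts(pred, y[test_rows]),
                             scores, y[test_rows])
      row$fold <- f
      row$classifier <- paste0("early_", classifier$name)
      row$n_selected <- length(sel_names)
      metrics[[length(metrics) + 1]] <- row
    }
    if ("mkl" %in% methods) {
      kern <- build_kernels(train_tabs)
      model <- mkl_fit(kern, y[!test_rows], regularization)
      scores <- mkl_predict(model, test_tabs)
      pred <- factor(ifelse(scores > 0, "case", "control"),
                     levels = c("control", "case"))
      row <- compute_metrics(confusion_counts(pred, y[test_rows]),
                             scores, y[test_rows])
      row$fold <- f
      row$classifier <- "mkl"
      row$n_selected <- length(sel_names)
      metrics[[length(metrics) + 1]] <- row
    }
  }
  structure(
    list(metrics = dplyr::bind_rows(metrics), selected = selected,
         chosen = list(), outer_k = outer_k, inner_k = inner_k,
         seed = seed, folds = folds, modality = "fusion"),
    class = "cv_report"
  )
}
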