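#' Classifier zoo
#'
#' Nine named classifier families behind a uniform fit/score interface:
#' logistic regression, k-nearest neighbors, ridge-penalized linear
#' classifier, Gaussian naive Bayes, linear- and RBF-kernel SVMs, random
#' forest, gradient-boosted trees and adaptive boosting. Each family has
#' a small default hyperparameter grid searched by the inner loop of
#' [nested_cv()].
#'
#' @param name One of `"logistic"`, `"knn"`, `"ridge"`, `"gnb"`,
#'   `"svm_linear"`, `"svm_rbf"`, `"rf"`, `"gbt"`, `"adaboost"`.
#' @param grid Optional named list of hyperparameter vectors overriding
#'   the default grid.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(name, grid = NULL) {
  name <- match.arg(name, c("logistic", "knn", "ridge", "gnb", "svm_linear",
                            "svm_rbf", "rf", "gbt", "adaboost"))
  structure(list(name = name, grid = grid %||% default_grid(name)),
            class = "classifier_spec")
}

#' The full nine-family classifier set
#'
#' @return Named list of [classifier_spec()]s.
#' @export
classifier_zoo <- function() {
  names <- c("logistic", "knn", "ridge", "gnb", "svm_linear", "svm_rbf",
             "rf", "gbt", "adaboost")
  setNames(lapply(names, classifier_spec), names)
}

default_grid <- function(name) {
  switch(name,
    logistic = list(dummy = 0),
    knn = list(k = c(3, 5, 9)),
    ridge = list(lambda = c(0.01, 0.1, 1)),
    gnb = list(dummy = 0),
    svm_linear = list(cost = c(0.1, 1, 10)),
    svm_rbf = list(cost = c(0.1, 1, 10)),
    rf = list(num_trees = 300),
    gbt = list(nrounds = c(50, 100)),
    adaboost = list(n_rounds = 50)
  )
}

# Expand a named list of value vectors into a list of configurations.
expand_grid_configs <- function(grid) {
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Fit one classifier configuration
#'
#' @param spec A [classifier_spec()].
#' @param x Training feature matrix.
#' @param y Training labels (factor control/case).
#' @param config Named list with one value per hyperparameter.
#' @param seed Seed for stochastic learners.
#' @return A `fitted_classifier`; score with [predict_scores()].
#' @export
fit_classifier <- function(spec, x, y, config = NULL, seed = 1L) {
  if (nlevels(droplevels(y)) < 2) abort("training labels are single-class")
  config <- config %||% expand_grid_configs(spec$grid)[[1]]
  x <- as.matrix(x)
  y01 <- as.integer(y == "case")
  model <- switch(
    spec$name,
    logistic = {
      df <- data.frame(y = y01, x)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    knn = list(x = x, y = y, k = config$k),
    ridge = {
      xr <- if (ncol(x) == 1) cbind(x, 0) else x
      glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                     lambda = config$lambda, standardize = TRUE)
    },
    gnb = e1071::naiveBayes(x, y),
    svm_linear = with_seed(seed, e1071::svm(
      x, y, kernel = "linear", cost = config$cost, scale = FALSE)),
    svm_rbf = with_seed(seed, e1071::svm(
      x, y, kernel = "radial", cost = config$cost, scale = FALSE)),
    rf = ranger::ranger(
      x = x, y = y, num.trees = config$num_trees, probability = TRUE,
      seed = seed, num.threads = 1),
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y01, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.1, nthread = 1),
        data = dtrain, nrounds = config$nrounds, verbose = 0)
    },
    adaboost = fit_adaboost(x, y01, config$n_rounds)
  )
  flip <- FALSE
  fitted <- structure(list(spec = spec, model = model, config = config,
                           flip = FALSE, p = ncol(x)),
                      class = "fitted_classifier")
  if (spec$name %in% c("svm_linear", "svm_rbf")) {
    # e1071 decision values are signed relative to an arbitrary class
    # order; orient them so larger means "case" using the training data.
    sc <- predict_scores(fitted, x)
    if (mean(sc[y == "case"]) < mean(sc[y == "control"])) flip <- TRUE
    fitted$flip <- flip
  }
  fitted
}

#' Continuous case-vs-control scores
#'
#' @param fitted A `fitted_classifier`.
#' @param x Feature matrix to score.
#' @return Numeric vector; larger values favour the case class.
#' @export
predict_scores <- function(fitted, x) {
  x <- as.matrix(x)
  spec <- fitted$spec
  m <- fitted$model
  sc <- switch(
    spec$name,
    logistic = {
      df <- data.frame(x)
      suppressWarnings(as.numeric(predict(m, newdata = df, type = "link")))
    },
    knn = {
      pred <- class::knn(train = m$x, test = x, cl = m$y, k = m$k,
                         prob = TRUE, use.all = TRUE)
      p_win <- attr(pred, "prob")
      ifelse(pred == "case", p_win, 1 - p_win)
    },
    ridge = {
      xr <- if (fitted$p == 1) cbind(x, 0) else x
      as.numeric(predict(m, newx = xr, type = "link"))
    },
    gnb = {
      pr <- predict(m, x, type = "raw")
      pr[, "case"]
    },
    svm_linear = ,
    svm_rbf = {
      dv <- attr(predict(m, x, decision.values = TRUE), "decision.values")
      as.numeric(dv[, 1])
    },
    rf = {
      pr <- predict(m, data = x, num.threads = 1)$predictions
      pr[, "case"]
    },
    gbt = as.numeric(predict(m, xgboost::xgb.DMatrix(x, nthread = 1))),
    adaboost = predict_adaboost(m, x)
  )
  if (isTRUE(fitted$flip)) sc <- -sc
  sc
}

# Discrete AdaBoost with depth-1 rpart stumps (SAMME with two classes).
fit_adaboost <- function(x, y01, n_rounds) {
  n <- nrow(x)
  wts <- rep(1 / n, n)
  y_pm <- ifelse(y01 == 1, 1, -1)
  stumps <- list()
  alphas <- numeric(0)
  df <- data.frame(y = factor(y01), x)
  for (mrd in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = wts,
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = -1, minsplit = 2,
                          xval = 0, maxcompete = 0, maxsurrogate = 0))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(wts * (pred != y_pm))
    if (err <= 1e-12) {
      stumps[[length(stumps) + 1]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    wts <- wts * exp(-alpha * y_pm * pred)
    wts <- wts / sum(wts)
  }
  if (length(stumps) == 0) {
    # Degenerate: no weak learner beats chance; fall back to the prior.
    return(list(stumps = list(), alphas = numeric(0),
                prior = mean(y01)))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y01))
}

predict_adaboost <- function(m, x) {
  if (length(m$stumps) == 0) return(rep(m$prior, nrow(x)))
  df <- data.frame(x)
  votes <- rep(0, nrow(x))
  for (k in seq_along(m$stumps)) {
    pred <- ifelse(predict(m$stumps[[k]], df, type = "class") == "1", 1, -1)
    votes <- votes + m$alphas[k] * pred
  }
  votes
}
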