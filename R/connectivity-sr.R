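#' Sparse-representation functional connectivity
#'
#' Four convex network estimators that model each ROI's signal as a sparse
#' linear combination of the other ROIs' signals:
#'
#' * SR: per-subject lasso, `1/2 ||X - XW||_F^2 + lambda ||W||_1` with
#'   `diag(W) = 0`;
#' * SLR: adds a trace-norm (nuclear-norm) penalty `lambda2 ||W||_*` that
#'   favours low-rank, modular networks;
#' * GSR: couples all subjects of a cohort through an l2,1 penalty on the
#'   per-ROI coefficient matrix, enforcing a shared sparsity support;
#' * SSGSR: weights the l2,1 penalty by the strength of the subject's
#'   low-order connectivity (`b = exp(-w0^2)`, penalizing weak links) and
#'   adds an inter-subject smoothing quadratic weighted by LOFC-pattern
#'   similarity `l^{pq} = exp(-||w0^p - w0^q||^2)`.
#'
#' All solvers are proximal methods with closed-form prox operators,
#' initialized at zero so that analytic null thresholds produce exactly
#' zero solutions.
#'
#' @name connectivity_sr
NULL

#' Solver settings for the sparse-representation estimators
#'
#' @param lambda1 Nonnegative sparsity weight (the single `lambda` of SR
#'   and GSR).
#' @param lambda2 Nonnegative second weight: trace norm for SLR,
#'   inter-subject smoothing for SSGSR; ignored by SR/GSR.
#' @param tol Relative objective-change stopping tolerance.
#' @param max_iter Iteration cap.
#' @return An `sr_params` list.
#' @export
sr_params <- function(lambda1 = 0.01, lambda2 = 0, tol = 1e-6,
                      max_iter = 5000L) {
  if (lambda1 < 0 || lambda2 < 0) abort("regularization weights must be >= 0")
  if (tol <= 0) abort("`tol` must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "sr_params")
}

# Zero-mean, unit-l2-norm columns; puts the lambda grids on a comparable
# scale across instances.
standardize_columns <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  nrm <- sqrt(colSums(x^2))
  if (any(nrm == 0)) abort("constant ROI signal cannot be standardized")
  sweep(x, 2, nrm, "/")
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

row_group_soft_threshold <- function(m, thr) {
  nrm <- sqrt(rowSums(m^2))
  scale <- ifelse(nrm > thr, 1 - thr / pmax(nrm, .Machine$double.eps), 0)
  m * scale
}

# Monotone FISTA: accelerated proximal gradient with a descent safeguard
# (falls back to the plain proximal step whenever the accelerated point
# would increase the objective), so the recorded objective trace is
# non-increasing.
fista <- function(w0, smooth_fn, grad_fn, prox_fn, penalty_fn, lipschitz,
                  tol, max_iter) {
  objective <- function(w) smooth_fn(w) + penalty_fn(w)
  w <- w0
  y <- w0
  t_acc <- 1
  obj <- objective(w)
  trace <- obj
  converged <- FALSE
  step <- 1 / lipschitz
  for (iter in seq_len(max_iter)) {
    cand <- prox_fn(y - step * grad_fn(y), step)
    obj_cand <- objective(cand)
    if (obj_cand > obj) {
      cand <- prox_fn(w - step * grad_fn(w), step)
      obj_cand <- objective(cand)
      t_acc <- 1
    }
    t_next <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- cand + ((t_acc - 1) / t_next) * (cand - w)
    t_acc <- t_next
    rel <- abs(obj - obj_cand) / max(abs(obj), 1e-12)
    if (obj_cand <= obj) {
      w <- cand
      obj <- obj_cand
    }
    trace <- c(trace, obj)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  list(w = w, objective = obj, converged = converged, trace = trace)
}

sr_objective <- function(x, w, lambda1) {
  0.5 * sum((x - x %*% w)^2) + lambda1 * sum(abs(w))
}

#' Sparse-representation (SR) connectivity
#'
#' Solves `min_W 1/2 ||X - XW||_F^2 + lambda ||W||_1` with `diag(W) = 0`
#' by per-column proximal gradient (FISTA) after standardizing columns to
#' zero mean and unit norm. Initialization at zero makes the lasso null
#' threshold exact: `lambda >= max_j ||X^T x_j||_inf` returns `W = 0`.
#'
#' @param series A [roi_timeseries()] or T x N matrix.
#' @param params An [sr_params()]; `lambda1` is the sparsity weight.
#' @return An `fc_matrix` with method `"SR"`; attributes carry the
#'   objective value and convergence flag.
#' @export
solve_sr <- function(series, params = sr_params()) {
  x <- standardize_columns(as_ts_matrix(series))
  n <- ncol(x)
  gram <- crossprod(x)
  lip <- max(eigen(gram, symmetric = TRUE, only.values = TRUE)$values)
  w <- matrix(0, n, n)
  converged <- TRUE
  obj_total <- 0
  for (j in seq_len(n)) {
    others <- setdiff(seq_len(n), j)
    xj <- x[, j]
    xo <- x[, others, drop = FALSE]
    gxo <- gram[others, others, drop = FALSE]
    gxj <- gram[others, j]
    fit <- fista(
      w0 = rep(0, n - 1),
      smooth_fn = function(b) 0.5 * sum((xj - xo %*% b)^2),
      grad_fn = function(b) as.numeric(gxo %*% b - gxj),
      prox_fn = function(b, step) soft_threshold(b, step * params$lambda1),
      penalty_fn = function(b) params$lambda1 * sum(abs(b)),
      lipschitz = lip, tol = params$tol, max_iter = params$max_iter
    )
    w[others, j] <- fit$w
    converged <- converged && fit$converged
    obj_total <- obj_total + fit$objective
  }
  labels <- if (inherits(series, "roi_timeseries")) series$roi_labels else NULL
  res <- new_fc_matrix(w, "SR", labels)
  res$objective <- obj_total
  res$converged <- converged
  res$params <- params
  res
}

# Singular-value soft-threshold (prox of the nuclear norm).
svt <- function(m, thr) {
  sv <- svd(m)
  d <- pmax(sv$d - thr, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

slr_objective <- function(x, w, lambda1, lambda2) {
  0.5 * sum((x - x %*% w)^2) + lambda1 * sum(abs(w)) +
    lambda2 * sum(svd(w)$d)
}

#' Sparse low-rank (SLR) connectivity
#'
#' Solves `min_W 1/2 ||X - XW||_F^2 + lambda1 ||W||_1 + lambda2 ||W||_*`
#' with `diag(W) = 0` by consensus ADMM: two auxiliary copies of `W`
#' carry the closed-form l1 prox (with diagonal projection) and the
#' singular-value soft-threshold, while the smooth least-squares block is
#' solved exactly through a cached eigendecomposition of the Gram matrix.
#' The sparse copy is returned; with `lambda2 = 0` the solution matches
#' [solve_sr()].
#'
#' @inheritParams solve_sr
#' @return An `fc_matrix` with method `"SLR"`.
#' @export
solve_slr <- function(series, params = sr_params(lambda1 = 0.05,
                                                 lambda2 = 0.08)) {
  x <- standardize_columns(as_ts_matrix(series))
  n <- ncol(x)
  gram <- crossprod(x)
  eg <- eigen(gram, symmetric = TRUE)
  rho <- 1
  scale_w <- 1 / (eg$values + 2 * rho)
  solve_w <- function(rhs) {
    eg$vectors %*% (scale_w * crossprod(eg$vectors, rhs))
  }
  z1 <- matrix(0, n, n)
  z2 <- matrix(0, n, n)
  u1 <- matrix(0, n, n)
  u2 <- matrix(0, n, n)
  obj_old <- slr_objective(x, z1, params$lambda1, params$lambda2)
  converged <- FALSE
  for (iter in seq_len(params$max_iter)) {
    w <- solve_w(gram + rho * (z1 - u1 + z2 - u2))
    z1 <- soft_threshold(w + u1, params$lambda1 / rho)
    diag(z1) <- 0
    z2 <- svt(w + u2, params$lambda2 / rho)
    u1 <- u1 + w - z1
    u2 <- u2 + w - z2
    obj <- slr_objective(x, z1, params$lambda1, params$lambda2)
    gap <- max(max(abs(w - z1)), max(abs(w - z2)))
    if (abs(obj - obj_old) / max(abs(obj_old), 1e-12) < params$tol &&
        gap < sqrt(params$tol)) {
      converged <- TRUE
      obj_old <- obj
      break
    }
    obj_old <- obj
  }
  labels <- if (inherits(series, "roi_timeseries")) series$roi_labels else NULL
  res <- new_fc_matrix(z1, "SLR", labels)
  res$objective <- obj_old
  res$converged <- converged
  res$params <- params
  res
}

cohort_matrices <- function(cohort) {
  if (inherits(cohort, "cohort")) {
    lapply(cohort$subjects, function(s) s$data)
  } else if (is.list(cohort)) {
    lapply(cohort, as_ts_matrix)
  } else {
    abort("expected a cohort or list of subjects")
  }
}

#' Per-ROI group problem for the guided group estimator
#'
#' Assembles, for one ROI, the stacked per-subject designs together with
#' the link-strength weights `b_{i,j}^s = exp(-(w0_{i,j}^s)^2)` and the
#' inter-subject similarities `l_i^{p,q} = exp(-||w0_i^p - w0_i^q||^2)`
#' computed from each subject's Pearson LOFC.
#'
#' @param cohort A `cohort` or list of subjects.
#' @param roi_index ROI index i.
#' @return A list: `x_i` (per-subject target vectors), `design`
#'   (per-subject T x (N-1) matrices), `b` ((N-1) x S weight matrix),
#'   `similarity` (S x S symmetric matrix), `others` (indices of the
#'   retained ROIs).
#' @export
build_group_problem <- function(cohort, roi_index) {
  mats <- lapply(cohort_matrices(cohort), standardize_columns)
  n <- ncol(mats[[1]])
  s_count <- length(mats)
  others <- setdiff(seq_len(n), roi_index)
  lofc <- lapply(mats, cor)
  b <- sapply(lofc, function(w0) exp(-w0[roi_index, others]^2))
  b <- matrix(b, nrow = n - 1)
  profiles <- sapply(lofc, function(w0) w0[roi_index, others])
  profiles <- matrix(profiles, nrow = n - 1)
  similarity <- matrix(1, s_count, s_count)
  if (s_count > 1) {
    for (p in seq_len(s_count - 1)) {
      for (q in (p + 1):s_count) {
        d2 <- sum((profiles[, p] - profiles[, q])^2)
        similarity[p, q] <- similarity[q, p] <- exp(-d2)
      }
    }
  }
  list(
    x_i = lapply(mats, function(m) m[, roi_index]),
    design = lapply(mats, function(m) m[, others, drop = FALSE]),
    b = b, similarity = similarity, others = others
  )
}

assemble_subject_fc <- function(coefs, n, method, labels = NULL) {
  # coefs: list over ROIs; each element an (N-1) x S matrix of weights.
  s_count <- ncol(coefs[[1]])
  lapply(seq_len(s_count), function(s) {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      w[setdiff(seq_len(n), i), i] <- coefs[[i]][, s]
    }
    new_fc_matrix(w, method, labels)
  })
}

#' Group sparse representation (GSR)
#'
#' For each ROI i, jointly solves the per-subject regressions
#' `sum_s 1/2 ||x_i^s - X_i^s w_i^s||^2 + lambda ||W_i||_{2,1}` where the
#' l2,1 norm sums the l2 norms of coefficient rows across subjects,
#' forcing every subject to select the same connections. Proximal
#' gradient with the row-group soft-threshold; zero initialization makes
#' the group null threshold exact. With a single subject the penalty
#' reduces to the l1 norm and GSR coincides with SR.
#'
#' @param cohort A `cohort` or list of [roi_timeseries()]/matrices.
#' @param params An [sr_params()]; `lambda1` is the group sparsity weight.
#' @return List of `fc_matrix` (method `"GSR"`), one per subject, with
#'   attributes `objective` (summed over ROIs) and `converged`.
#' @export
solve_gsr <- function(cohort, params = sr_params(lambda1 = 0.01)) {
  mats <- lapply(cohort_matrices(cohort), standardize_columns)
  n <- ncol(mats[[1]])
  s_count <- length(mats)
  grams <- lapply(mats, crossprod)
  lip_all <- max(vapply(grams, function(g) {
    max(eigen(g, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1)))
  coefs <- vector("list", n)
  obj_total <- 0
  converged <- TRUE
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    xs <- lapply(mats, function(m) m[, i])
    gs <- lapply(grams, function(g) g[others, others, drop = FALSE])
    gx <- lapply(seq_len(s_count), function(s) grams[[s]][others, i])
    smooth_fn <- function(w) {
      sum(vapply(seq_len(s_count), function(s) {
        0.5 * sum((xs[[s]] - mats[[s]][, others, drop = FALSE] %*%
                     w[, s])^2)
      }, numeric(1)))
    }
    grad_fn <- function(w) {
      g <- w
      for (s in seq_len(s_count)) {
        g[, s] <- gs[[s]] %*% w[, s] - gx[[s]]
      }
      g
    }
    fit <- fista(
      w0 = matrix(0, n - 1, s_count),
      smooth_fn = smooth_fn, grad_fn = grad_fn,
      prox_fn = function(w, step) {
        row_group_soft_threshold(w, step * params$lambda1)
      },
      penalty_fn = function(w) params$lambda1 * sum(sqrt(rowSums(w^2))),
      lipschitz = lip_all, tol = params$tol, max_iter = params$max_iter
    )
    coefs[[i]] <- fit$w
    obj_total <- obj_total + fit$objective
    converged <- converged && fit$converged
  }
  labels <- if (inherits(cohort, "cohort")) {
    cohort$subjects[[1]]$roi_labels
  } else {
    NULL
  }
  out <- assemble_subject_fc(coefs, n, "GSR", labels)
  attr(out, "objective") <- obj_total
  attr(out, "converged") <- converged
  attr(out, "params") <- params
  out
}

# Largest eigenvalue of a symmetric PSD operator given as a function, by
# power iteration (used where forming the Hessian would be wasteful).
power_iteration_norm <- function(apply_fn, dim, iters = 60L, seed = 7L) {
  v <- with_seed(seed, rnorm(dim))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (k in seq_len(iters)) {
    av <- apply_fn(v)
    lam <- sqrt(sum(av^2))
    if (lam == 0) return(0)
    v <- av / lam
  }
  lam
}

#' Strength- and similarity-guided GSR (SSGSR)
#'
#' For each ROI i, solves
#' `sum_s 1/2 ||x_i^s - X_i^s w_i^s||^2 + lambda1 ||B_i (*) W_i||_{2,1}
#'  + lambda2 sum_{p,q} l_i^{p,q} ||w_i^p - w_i^q||^2`,
#' where `B_i` down-weights the penalty on strong low-order connections
#' and the similarity-weighted quadratic shrinks similar subjects toward
#' each other. The weighted l2,1 term is handled by the exact change of
#' variables `v = B (*) w` (valid because every `b = exp(-w0^2) > 0`),
#' which rescales the design columns and reduces the penalty to a plain
#' row-group prox; the similarity quadratic stays in the smooth part.
#'
#' @inheritParams solve_gsr
#' @param params An [sr_params()]; `lambda1` weights the guided sparsity,
#'   `lambda2` the inter-subject smoothing.
#' @return List of `fc_matrix` (method `"SSGSR"`), one per subject.
#' @export
solve_ssgsr <- function(cohort, params = sr_params(lambda1 = 0.06,
                                                   lambda2 = 0.01)) {
  mats <- lapply(cohort_matrices(cohort), standardize_columns)
  n <- ncol(mats[[1]])
  s_count <- length(mats)
  coefs <- vector("list", n)
  obj_total <- 0
  converged <- TRUE
  for (i in seq_len(n)) {
    gp <- build_group_problem(mats, i)
    b <- gp$b
    l_sim <- gp$similarity
    # Scaled designs: columns divided by b so the penalty is || V ||_{2,1}.
    designs <- lapply(seq_len(s_count), function(s) {
      sweep(gp$design[[s]], 2, b[, s], "/")
    })
    grams <- lapply(designs, crossprod)
    # Graph Laplacian of the similarity quadratic in the original w
    # variables: sum_{p,q} l^{pq} ||w^p - w^q||^2 = 2 tr(W L W^T).
    lap <- diag(rowSums(l_sim)) - l_sim
    smooth_fn <- function(v) {
      w <- v / b
      fit <- sum(vapply(seq_len(s_count), function(s) {
        0.5 * sum((gp$x_i[[s]] - designs[[s]] %*% v[, s])^2)
      }, numeric(1)))
      smoothness <- 2 * params$lambda2 * sum((w %*% lap) * w)
      fit + smoothness
    }
    grad_fn <- function(v) {
      g <- v
      for (s in seq_len(s_count)) {
        g[, s] <- grams[[s]] %*% v[, s] -
          crossprod(designs[[s]], gp$x_i[[s]])
      }
      w <- v / b
      g + (4 * params$lambda2) * ((w %*% lap) / b)
    }
    dim_v <- (n - 1) * s_count
    hess_apply <- function(vec) {
      v <- matrix(vec, n - 1, s_count)
      g <- v
      for (s in seq_len(s_count)) g[, s] <- grams[[s]] %*% v[, s]
      w <- v / b
      as.numeric(g + (4 * params$lambda2) * ((w %*% lap) / b))
    }
    lip <- power_iteration_norm(hess_apply, dim_v) * 1.05 + 1e-9
    fit <- fista(
      w0 = matrix(0, n - 1, s_count),
      smooth_fn = smooth_fn, grad_fn = grad_fn,
      prox_fn = function(v, step) {
        row_group_soft_threshold(v, step * params$lambda1)
      },
      penalty_fn = function(v) params$lambda1 * sum(sqrt(rowSums(v^2))),
      lipschitz = lip, tol = params$tol, max_iter = params$max_iter
    )
    coefs[[i]] <- fit$w / b
    obj_total <- obj_total + fit$objective
    converged <- converged && fit$converged
  }
  labels <- if (inherits(cohort, "cohort")) {
    cohort$subjects[[1]]$roi_labels
  } else {
    NULL
  }
  out <- assemble_subject_fc(coefs, n, "SSGSR", labels)
  attr(out, "objective") <- obj_total
  attr(out, "converged") <- converged
  attr(out, "params") <- params
  out
}

#' Symmetrize an asymmetric connectivity estimate
#'
#' The sparse-representation objectives yield directed coefficient
#' matrices; reported connections are undirected, so features are read
#' from `(W + W^T) / 2`.
#'
#' @param fc An `fc_matrix`.
#' @return An `fc_matrix` with symmetric values and the method tag kept.
#' @export
symmetrize <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  fc$values <- (fc$values + t(fc$values)) / 2
  fc
}

#' Analytic null thresholds for the sparse estimators
#'
#' Smallest sparsity weight at which the zero matrix is optimal:
#' `max_j ||X_{-j}^T x_j||_inf` for SR/SLR, and the maximum over
#' coefficient rows of the l2 norm of the stacked per-subject gradients
#' for GSR.
#'
#' @param series_or_cohort A single subject (SR) or cohort (GSR).
#' @param group For `TRUE`, the group (l2,1) threshold.
#' @return The threshold value.
#' @export
lambda_null_threshold <- function(series_or_cohort, group = FALSE) {
  if (!group) {
    x <- standardize_columns(as_ts_matrix(series_or_cohort))
    gram <- crossprod(x)
    diag(gram) <- 0
    max(abs(gram))
  } else {
    mats <- lapply(cohort_matrices(series_or_cohort), standardize_columns)
    n <- ncol(mats[[1]])
    grams <- lapply(mats, crossprod)
    thr <- 0
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      g <- sapply(grams, function(gr) gr[others, i])
      g <- matrix(g, nrow = n - 1)
      thr <- max(thr, sqrt(rowSums(g^2)))
    }
    thr
  }
}
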