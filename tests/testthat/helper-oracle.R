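# Independent oracles: brute-force statistics and a generic smoothed
# convex-programming solver (L-BFGS-B on an epsilon-smoothed objective)
# used to certify the sparse-representation solvers. Everything here is
# written from the definitions, not from the package internals.

oracle_standardize <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  sweep(x, 2, sqrt(colSums(x^2)), "/")
}

# --- brute-force high-order FC -------------------------------------------

oracle_thofc <- function(w) {
  n <- nrow(w)
  out <- diag(1, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      keep <- setdiff(1:n, c(i, j))
      out[i, j] <- stats::cor(w[i, keep], w[j, keep])
    }
  }
  out
}

oracle_windowed_pair_cor <- function(x, l, s) {
  n <- ncol(x)
  t_points <- nrow(x)
  theta <- floor((t_points - l) / s) + 1
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  out <- matrix(NA_real_, nrow(pairs), theta)
  for (th in 1:theta) {
    idx <- ((th - 1) * s + 1):((th - 1) * s + l)
    cm <- stats::cor(x[idx, ])
    out[, th] <- cm[pairs]
  }
  out
}

oracle_dhofc_network <- function(window_series, assignments) {
  k <- max(assignments)
  means <- t(sapply(1:k, function(cl) {
    colMeans(window_series[assignments == cl, , drop = FALSE])
  }))
  if (k == 1) return(matrix(1, 1, 1))
  net <- diag(1, k)
  for (p in 1:(k - 1)) {
    for (q in (p + 1):k) {
      net[p, q] <- net[q, p] <- stats::cor(means[p, ], means[q, ])
    }
  }
  net
}

# Textbook rank-sum KCC of m judges ranking T items.
oracle_kcc <- function(series_mat) {
  m <- ncol(series_mat)
  t_points <- nrow(series_mat)
  r <- apply(series_mat, 2, rank)
  ri <- rowSums(r)
  s <- sum((ri - mean(ri))^2)
  12 * s / (m^2 * (t_points^3 - t_points))
}

# --- generic smoothed convex oracle --------------------------------------

# True (nonsmooth) objectives, evaluated at candidate solutions.
oracle_obj_sr <- function(x, w, lam) {
  0.5 * sum((x - x %*% w)^2) + lam * sum(abs(w))
}
oracle_obj_slr <- function(x, w, lam1, lam2) {
  0.5 * sum((x - x %*% w)^2) + lam1 * sum(abs(w)) + lam2 * sum(svd(w)$d)
}
oracle_obj_gsr <- function(mats, coef_list, lam) {
  # coef_list: per ROI i, an (N-1) x S matrix.
  n <- ncol(mats[[1]])
  fit <- 0
  pen <- 0
  for (i in 1:n) {
    others <- setdiff(1:n, i)
    w <- coef_list[[i]]
    for (s in seq_along(mats)) {
      fit <- fit + 0.5 * sum((mats[[s]][, i] -
                                mats[[s]][, others, drop = FALSE] %*%
                                w[, s])^2)
    }
    pen <- pen + lam * sum(sqrt(rowSums(w^2)))
  }
  fit + pen
}
oracle_ssgsr_parts <- function(mats, roi) {
  n <- ncol(mats[[1]])
  s_count <- length(mats)
  others <- setdiff(1:n, roi)
  lofc <- lapply(mats, stats::cor)
  b <- sapply(lofc, function(w0) exp(-w0[roi, others]^2))
  b <- matrix(b, nrow = n - 1)
  prof <- sapply(lofc, function(w0) w0[roi, others])
  prof <- matrix(prof, nrow = n - 1)
  l_sim <- matrix(1, s_count, s_count)
  for (p in 1:s_count) for (q in 1:s_count) {
    l_sim[p, q] <- exp(-sum((prof[, p] - prof[, q])^2))
  }
  list(others = others, b = b, l_sim = l_sim)
}
oracle_obj_ssgsr <- function(mats, coef_list, lam1, lam2) {
  n <- ncol(mats[[1]])
  s_count <- length(mats)
  total <- 0
  for (i in 1:n) {
    parts <- oracle_ssgsr_parts(mats, i)
    w <- coef_list[[i]]
    for (s in 1:s_count) {
      total <- total + 0.5 * sum((mats[[s]][, i] -
                                    mats[[s]][, parts$others, drop = FALSE] %*%
                                    w[, s])^2)
    }
    total <- total + lam1 * sum(sqrt(rowSums((parts$b * w)^2)))
    for (p in 1:s_count) for (q in 1:s_count) {
      total <- total + lam2 * parts$l_sim[p, q] *
        sum((w[, p] - w[, q])^2)
    }
  }
  total
}

# L-BFGS-B on the epsilon-smoothed objective; returns the minimizer.
smoothed_lbfgs <- function(par0, fn, gr, maxit = 4000) {
  res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e3))
  res$par
}

# SR oracle: per-column smoothed lasso.
oracle_solve_sr <- function(x, lam, eps = 1e-9) {
  x <- oracle_standardize(x)
  n <- ncol(x)
  w <- matrix(0, n, n)
  for (j in 1:n) {
    others <- setdiff(1:n, j)
    xo <- x[, others, drop = FALSE]
    xj <- x[, j]
    fn <- function(b) {
      0.5 * sum((xj - xo %*% b)^2) + lam * sum(sqrt(b^2 + eps))
    }
    gr <- function(b) {
      as.numeric(crossprod(xo, xo %*% b - xj)) + lam * b / sqrt(b^2 + eps)
    }
    w[others, j] <- smoothed_lbfgs(rep(0, n - 1), fn, gr)
  }
  w
}

# SLR oracle: smoothed l1 + smoothed nuclear norm over off-diagonal W.
oracle_solve_slr <- function(x, lam1, lam2, eps = 1e-9) {
  x <- oracle_standardize(x)
  n <- ncol(x)
  off <- which(diag(n) == 0)
  to_w <- function(par) {
    w <- matrix(0, n, n)
    w[off] <- par
    w
  }
  fn <- function(par) {
    w <- to_w(par)
    sv <- svd(w)$d
    0.5 * sum((x - x %*% w)^2) + lam1 * sum(sqrt(par^2 + eps)) +
      lam2 * sum(sqrt(sv^2 + eps))
  }
  gr <- function(par) {
    w <- to_w(par)
    g_fit <- crossprod(x, x %*% w - x)
    sv <- svd(w)
    g_nuc <- sv$u %*% diag(sv$d / sqrt(sv$d^2 + eps)) %*% t(sv$v)
    g <- g_fit + lam2 * g_nuc
    g[off] + lam1 * par / sqrt(par^2 + eps)
  }
  to_w(smoothed_lbfgs(rep(0, length(off)), fn, gr))
}

# GSR oracle: per-ROI smoothed l2,1 over the (N-1) x S coefficient block.
oracle_solve_gsr <- function(mats, lam, eps = 1e-9) {
  mats <- lapply(mats, oracle_standardize)
  n <- ncol(mats[[1]])
  s_count <- length(mats)
  lapply(1:n, function(i) {
    others <- setdiff(1:n, i)
    fn <- function(par) {
      w <- matrix(par, n - 1, s_count)
      fit <- sum(sapply(1:s_count, function(s) {
        0.5 * sum((mats[[s]][, i] -
                     mats[[s]][, others, drop = FALSE] %*% w[, s])^2)
      }))
      fit + lam * sum(sqrt(rowSums(w^2) + eps))
    }
    gr <- function(par) {
      w <- matrix(par, n - 1, s_count)
      g <- w
      for (s in 1:s_count) {
        xo <- mats[[s]][, others, drop = FALSE]
        g[, s] <- crossprod(xo, xo %*% w[, s] - mats[[s]][, i])
      }
      rn <- sqrt(rowSums(w^2) + eps)
      as.numeric(g + lam * w / rn)
    }
    matrix(smoothed_lbfgs(rep(0, (n - 1) * s_count), fn, gr),
           n - 1, s_count)
  })
}

# SSGSR oracle: adds the b-weighted smoothed l2,1 and the similarity
# quadratic.
oracle_solve_ssgsr <- function(mats, lam1, lam2, eps = 1e-9) {
  mats <- lapply(mats, oracle_standardize)
  n <- ncol(mats[[1]])
  s_count <- length(mats)
  lapply(1:n, function(i) {
    parts <- oracle_ssgsr_parts(mats, i)
    others <- parts$others
    b <- parts$b
    l_sim <- parts$l_sim
    fn <- function(par) {
      w <- matrix(par, n - 1, s_count)
      fit <- sum(sapply(1:s_count, function(s) {
        0.5 * sum((mats[[s]][, i] -
                     mats[[s]][, others, drop = FALSE] %*% w[, s])^2)
      }))
      pen <- lam1 * sum(sqrt(rowSums((b * w)^2) + eps))
      sm <- 0
      for (p in 1:s_count) for (q in 1:s_count) {
        sm <- sm + l_sim[p, q] * sum((w[, p] - w[, q])^2)
      }
      fit + pen + lam2 * sm
    }
    gr <- function(par) {
      w <- matrix(par, n - 1, s_count)
      g <- w
      for (s in 1:s_count) {
        xo <- mats[[s]][, others, drop = FALSE]
        g[, s] <- crossprod(xo, xo %*% w[, s] - mats[[s]][, i])
      }
      bw <- b * w
      rn <- sqrt(rowSums(bw^2) + eps)
      g <- g + lam1 * (b * bw) / rn
      for (p in 1:s_count) {
        acc <- 0
        for (q in 1:s_count) {
          acc <- acc + (l_sim[p, q] + l_sim[q, p]) * (w[, p] - w[, q])
        }
        g[, p] <- g[, p] + 2 * lam2 * acc
      }
      as.numeric(g)
    }
    matrix(smoothed_lbfgs(rep(0, (n - 1) * s_count), fn, gr),
           n - 1, s_count)
  })
}

# Per-ROI coefficient blocks of the package's per-subject FC matrices,
# for plugging into the group objectives above.
coef_blocks_from_fcs <- function(fc_list) {
  n <- nrow(fc_list[[1]]$values)
  lapply(1:n, function(i) {
    sapply(fc_list, function(fc) fc$values[setdiff(1:n, i), i])
  })
}
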