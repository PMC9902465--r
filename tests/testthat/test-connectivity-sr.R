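test_that("analytic null thresholds zero the solutions exactly", {
  x <- rand_instance(1)
  lam_max <- lambda_null_threshold(x)
  fc <- solve_sr(x, sr_params(lambda1 = lam_max * 1.0001))
  expect_true(all(fc$values == 0))

  fc2 <- solve_slr(x, sr_params(lambda1 = lam_max * 1.1,
                                lambda2 = lam_max * 1.1))
  expect_true(all(fc2$values == 0))

  mats <- rand_cohort_mats(2)
  lam_g <- lambda_null_threshold(mats, group = TRUE)
  fcs <- solve_gsr(mats, sr_params(lambda1 = lam_g * 1.0001))
  expect_true(all(vapply(fcs, function(f) all(f$values == 0), logical(1))))
})

test_that("SR matches the convex oracle and an independent lasso solver", {
  for (s in 1:3) {
    x <- rand_instance(s)
    lam <- 0.01
    fc <- solve_sr(x, sr_params(lambda1 = lam, tol = 1e-10))
    w_oracle <- oracle_solve_sr(x, lam)
    xs <- oracle_standardize(x)
    obj_impl <- oracle_obj_sr(xs, fc$values, lam)
    obj_orc <- oracle_obj_sr(xs, w_oracle, lam)
    expect_lt(abs(obj_impl - obj_orc) / abs(obj_orc), 1e-4)
    expect_true(fc$converged)
  }

  # cross-check one column against glmnet's lasso path
  x <- rand_instance(7)
  xs <- oracle_standardize(x)
  lam <- 0.02
  fc <- solve_sr(x, sr_params(lambda1 = lam, tol = 1e-12))
  t_points <- nrow(x)
  g <- glmnet::glmnet(xs[, -1], xs[, 1], alpha = 1,
                      lambda = lam / t_points, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_equal(fc$values[-1, 1], as.numeric(g$beta), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("duplicate ROIs attract the coefficient mass under SR", {
  x <- rand_instance(11)
  x[, 4] <- x[, 2] + rnorm(nrow(x), sd = 1e-6)
  fc <- solve_sr(x, sr_params(lambda1 = 0.05))
  w <- abs(fc$values[, 4])
  expect_gt(w[2], max(w[-c(2, 4)]))
})

test_that("SLR reduces to SR at lambda2 = 0 and matches the oracle", {
  x <- rand_instance(3)
  sr <- solve_sr(x, sr_params(lambda1 = 0.05, tol = 1e-10))
  slr0 <- solve_slr(x, sr_params(lambda1 = 0.05, lambda2 = 0, tol = 1e-10))
  xs <- oracle_standardize(x)
  expect_lt(abs(oracle_obj_sr(xs, slr0$values, 0.05) -
                  oracle_obj_sr(xs, sr$values, 0.05)) /
              oracle_obj_sr(xs, sr$values, 0.05), 1e-6)

  for (s in 4:6) {
    x <- rand_instance(s)
    xs <- oracle_standardize(x)
    fc <- solve_slr(x, sr_params(lambda1 = 0.05, lambda2 = 0.08,
                                 tol = 1e-10))
    w_orc <- oracle_solve_slr(x, 0.05, 0.08)
    obj_impl <- oracle_obj_slr(xs, fc$values, 0.05, 0.08)
    obj_orc <- oracle_obj_slr(xs, w_orc, 0.05, 0.08)
    expect_lt(abs(obj_impl - obj_orc) / abs(obj_orc), 1e-4)

    # the trace-norm penalty shrinks the nuclear norm
    slr_no <- solve_slr(x, sr_params(lambda1 = 0.05, lambda2 = 0,
                                     tol = 1e-10))
    expect_lte(sum(svd(fc$values)$d), sum(svd(slr_no$values)$d) + 1e-8)
  }
})

test_that("GSR matches the oracle, shares support, and reduces to SR at S=1", {
  mats <- rand_cohort_mats(5)
  lam <- 0.01
  fcs <- solve_gsr(mats, sr_params(lambda1 = lam, tol = 1e-10))
  blocks <- coef_blocks_from_fcs(fcs)
  orc <- oracle_solve_gsr(mats, lam)
  mats_std <- lapply(mats, oracle_standardize)
  obj_impl <- oracle_obj_gsr(mats_std, blocks, lam)
  obj_orc <- oracle_obj_gsr(mats_std, orc, lam)
  expect_lt(abs(obj_impl - obj_orc) / abs(obj_orc), 1e-4)

  # joint support: a row is zero for all subjects or none
  for (blk in blocks) {
    rn <- rowSums(abs(blk) > 0)
    expect_true(all(rn == 0 | rn == ncol(blk)))
  }

  # S = 1: l2,1 becomes l1, so GSR equals SR
  single <- solve_gsr(mats[1], sr_params(lambda1 = 0.03, tol = 1e-10))
  sr <- solve_sr(mats[[1]], sr_params(lambda1 = 0.03, tol = 1e-10))
  xs <- oracle_standardize(mats[[1]])
  expect_lt(abs(oracle_obj_sr(xs, single[[1]]$values, 0.03) -
                  oracle_obj_sr(xs, sr$values, 0.03)) /
              oracle_obj_sr(xs, sr$values, 0.03), 1e-6)
})

test_that("SSGSR matches the oracle and its guidance formulas", {
  mats <- rand_cohort_mats(8)
  fcs <- solve_ssgsr(mats, sr_params(lambda1 = 0.06, lambda2 = 0.01,
                                     tol = 1e-10))
  blocks <- coef_blocks_from_fcs(fcs)
  orc <- oracle_solve_ssgsr(mats, 0.06, 0.01)
  mats_std <- lapply(mats, oracle_standardize)
  obj_impl <- oracle_obj_ssgsr(mats_std, blocks, 0.06, 0.01)
  obj_orc <- oracle_obj_ssgsr(mats_std, orc, 0.06, 0.01)
  expect_lt(abs(obj_impl - obj_orc) / abs(obj_orc), 1e-4)

  # printed guidance weights: b = exp(-w0^2), l^{pq} = exp(-||dw0||^2)
  gp <- build_group_problem(mats, 1)
  lofc <- lapply(lapply(mats, oracle_standardize), cor)
  expect_equal(gp$b[1, 1], exp(-lofc[[1]][1, 2]^2), tolerance = 1e-12)
  expect_true(isSymmetric(gp$similarity))
  expect_true(all(gp$b > 0 & gp$b <= 1))
  expect_true(all(gp$similarity > 0 & gp$similarity <= 1))
  # identical LOFC rows across two copies of one subject -> similarity 1
  gp2 <- build_group_problem(list(mats[[1]], mats[[1]]), 2)
  expect_equal(gp2$similarity[1, 2], 1)

  # exact anchor points of the link weights: an uncorrelated pair gives
  # b = 1, a perfectly correlated pair gives b = exp(-1) ~ 0.3679
  z <- cbind(rep(c(1, -1), 8), rep(c(1, 1, -1, -1), 4), rnorm(16))
  z[, 3] <- z[, 1] * 2                      # duplicate of column 1
  gp3 <- build_group_problem(list(z), 1)    # ROI 1 vs ROIs {2, 3}
  expect_equal(gp3$b[1, 1], 1, tolerance = 1e-12)          # w0 = 0
  expect_equal(gp3$b[2, 1], 0.3679, tolerance = 1e-4)      # w0 = 1
  # consensus limit: huge lambda2 equalizes subjects
  fcs_big <- solve_ssgsr(mats, sr_params(lambda1 = 0.01, lambda2 = 1000,
                                         tol = 1e-12))
  for (i in 2:length(fcs_big)) {
    expect_lt(max(abs(fcs_big[[i]]$values - fcs_big[[1]]$values)), 1e-4)
  }
})

test_that("sparsity is non-increasing along the lambda path", {
  x <- rand_instance(13)
  nnz <- vapply(c(0.01, 0.03, 0.05, 0.08, 0.12), function(lam) {
    sum(solve_sr(x, sr_params(lambda1 = lam))$values != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("symmetrize averages the two directions and is idempotent", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- 0.4
  fc <- structure(list(values = w, method = "SR",
                       roi_labels = paste0("ROI", 1:3)),
                  class = "fc_matrix")
  sym <- symmetrize(fc)
  expect_equal(sym$values[1, 2], 0.2)
  expect_equal(sym$values[2, 1], 0.2)
  expect_equal(symmetrize(sym)$values, sym$values)
  expect_identical(sym$method, "SR")
})
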