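test_that("pearson_fc matches hand-computed values and handles degenerate input", {
  # 4 x 3 integer fixture; correlations computed by hand from the
  # definition (printed here for auditability).
  x <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                4, 3, 2, 1), nrow = 4)
  fc <- pearson_fc(x)
  expect_equal(fc$values[1, 2], 1, tolerance = 1e-12)
  expect_equal(fc$values[1, 3], -1, tolerance = 1e-12)
  expect_true(isSymmetric(fc$values))
  expect_equal(diag(fc$values), setNames(rep(1, 3), fc$roi_labels))

  y <- cbind(x, 5)
  expect_error(pearson_fc(y), "constant")
})

test_that("tHOFC equals the brute-force correlation-of-correlation", {
  withr::with_seed(21, {
    x <- matrix(rnorm(50 * 8), 50, 8)
  })
  lofc <- pearson_fc(x)
  ho <- thofc(lofc)
  expect_lt(max(abs(ho$values - oracle_thofc(lofc$values))), 1e-12)
  expect_equal(diag(ho$values), setNames(rep(1, 8), ho$roi_labels))

  # rows identical off the exclusions -> correlation 1
  w <- diag(1, 5)
  prof <- c(0.3, -0.2, 0.5, 0.1, 0.4)
  for (k in 3:5) w[1, k] <- w[k, 1] <- w[2, k] <- w[k, 2] <- prof[k]
  w[1, 2] <- w[2, 1] <- 0.9
  fake <- structure(list(values = w, method = "PC",
                         roi_labels = paste0("ROI", 1:5)),
                    class = "fc_matrix")
  expect_equal(thofc(fake)$values[1, 2], 1, tolerance = 1e-12)

  expect_error(thofc(pearson_fc(matrix(rnorm(30), 10, 3))), "at least 4")
})

test_that("tHOFC flags zero-variance profiles instead of returning NaN", {
  w <- diag(1, 5)
  # ROI 1 and 2 have flat profiles over the remaining ROIs
  w[1, 3:5] <- w[3:5, 1] <- 0.2
  w[2, 3:5] <- w[3:5, 2] <- 0.2
  fake <- structure(list(values = w, method = "PC",
                         roi_labels = paste0("ROI", 1:5)),
                    class = "fc_matrix")
  ho <- thofc(fake)
  expect_equal(ho$values[1, 2], 0)
  expect_true(ho$degenerate[1, 2])
  expect_true(all(is.finite(ho$values)))
})

test_that("sliding windows obey the window-count formula", {
  withr::with_seed(3, x <- matrix(rnorm(370 * 3), 370, 3))
  dyn <- sliding_window_fc(x, window_length = 50, step = 1)
  expect_equal(dyn$n_windows, 321)
  expect_equal(dim(dyn$window_series), c(3, 321))
  expect_lt(max(abs(dyn$window_series -
                      oracle_windowed_pair_cor(x, 50, 1))), 1e-12)

  # L = T: the single window reproduces the full-series correlation
  small <- x[1:10, ]
  one <- sliding_window_fc(small, window_length = 10, step = 1)
  expect_equal(one$n_windows, 1)
  fc <- pearson_fc(small)
  idx <- pair_index_of(3)
  expect_equal(as.numeric(one$window_series[, 1]),
               fc$values[cbind(idx[, 1], idx[, 2])], tolerance = 1e-12)
  expect_true(all(abs(dyn$window_series) <= 1 + 1e-12))
})

test_that("Ward clustering recovers planted pair groupings", {
  # duplicated rows, K = 2: exact separation
  a <- rep(c(0.9, -0.9), each = 3)
  ws <- rbind(matrix(rep(c(1, 0, 1, 0), 3), 3, byrow = TRUE),
              matrix(rep(c(0, 1, 0, 1), 3), 3, byrow = TRUE))
  dyn <- structure(list(window_series = ws, pair_index = pair_index_of(4),
                        window_length = 3, step = 1, n_windows = 4,
                        roi_labels = paste0("ROI", 1:4),
                        degenerate = matrix(FALSE, 6, 4)),
                   class = "dynamic_fc")
  cl <- ward_cluster_pairs(dyn, 2)
  expect_equal(length(unique(cl[1:3])), 1)
  expect_equal(length(unique(cl[4:6])), 1)
  expect_false(cl[1] == cl[4])

  # K = P: singleton clusters
  expect_equal(ward_cluster_pairs(dyn, 6), 1:6)

  # 12 rows from 3 well-separated templates: perfect recovery, 20 seeds
  for (s in 1:20) {
    withr::with_seed(s, {
      templates <- matrix(rnorm(3 * 30, sd = 1), 3, 30)
      truth <- rep(1:3, each = 4)
      rows <- templates[truth, ] + matrix(rnorm(12 * 30, sd = 0.01), 12)
    })
    dyn2 <- structure(list(window_series = rows,
                           pair_index = pair_index_of(6)[1:12, ],
                           window_length = 3, step = 1, n_windows = 30,
                           roi_labels = paste0("ROI", 1:5),
                           degenerate = matrix(FALSE, 12, 30)),
                      class = "dynamic_fc")
    cl2 <- ward_cluster_pairs(dyn2, 3)
    expect_equal(length(unique(paste(cl2, truth))), 3)
  }

  expect_error(ward_cluster_pairs(dyn, 10), "exceeds")
})

test_that("dHOFC network equals the brute-force cluster-mean correlations", {
  withr::with_seed(8, x <- matrix(rnorm(120 * 6), 120, 6))
  dyn <- sliding_window_fc(x, window_length = 30, step = 2)
  cl <- ward_cluster_pairs(dyn, 4)
  res <- dhofc_network(dyn, cl)
  expect_lt(max(abs(res$network -
                      oracle_dhofc_network(dyn$window_series, cl))), 1e-12)
  expect_true(isSymmetric(res$network))
  expect_equal(diag(res$network), rep(1, 4))

  # K = 1 degenerate case
  one <- dhofc_network(dyn, rep(1L, nrow(dyn$window_series)))
  expect_equal(one$network, matrix(1, 1, 1))

  # identical cluster-mean series -> off-diagonal 1
  ws <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  dyn2 <- structure(list(window_series = ws,
                         pair_index = pair_index_of(3)[1:2, ],
                         window_length = 3, step = 1, n_windows = 4,
                         roi_labels = paste0("ROI", 1:3),
                         degenerate = matrix(FALSE, 2, 4)),
                    class = "dynamic_fc")
  two <- dhofc_network(dyn2, c(1L, 2L))
  expect_equal(two$network[1, 2], 1, tolerance = 1e-12)
})

test_that("correlation measures are invariant to per-ROI affine rescaling", {
  withr::with_seed(12, x <- matrix(rnorm(80 * 5), 80, 5))
  a <- c(2, 0.5, 3, 1.5, 10)
  b <- c(-1, 4, 0, 2, -7)
  y <- sweep(sweep(x, 2, a, "*"), 2, b, "+")
  expect_equal(pearson_fc(y)$values, pearson_fc(x)$values,
               tolerance = 1e-12)
  expect_equal(thofc(pearson_fc(y))$values, thofc(pearson_fc(x))$values,
               tolerance = 1e-12)
  d1 <- sliding_window_fc(x, 20, 4)$window_series
  d2 <- sliding_window_fc(y, 20, 4)$window_series
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("full dhofc pipeline is deterministic", {
  withr::with_seed(5, x <- matrix(rnorm(100 * 5), 100, 5))
  r1 <- dhofc(x, window_length = 25, k_clusters = 3)
  r2 <- dhofc(x, window_length = 25, k_clusters = 3)
  expect_identical(r1, r2)
})
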