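fake_report <- function(selected) {
  structure(list(selected = selected, metrics = tibble::tibble(),
                 chosen = list(), outer_k = length(selected),
                 inner_k = 5, seed = 1, folds = integer(0),
                 modality = "PC"),
            class = "cv_report")
}

test_that("stable candidates are the intersection of fold selections", {
  sel <- replicate(10, c("a", "b", "c"), simplify = FALSE)
  sel[[4]] <- c("a", "c")   # b drops out in one fold
  st <- stable_candidates(fake_report(sel))
  expect_setequal(st, c("a", "c"))

  sel2 <- c(sel[1:9], list(character(0)))
  expect_length(stable_candidates(fake_report(sel2)), 0)
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  # hand-evaluated: q = (0.04, 0.04, 0.0533..., 0.5) for m = 4
  p <- c(0.01, 0.02, 0.04, 0.5)
  expect_equal(p.adjust(p, "BH"),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)

  withr::with_seed(3, {
    x <- matrix(rnorm(40 * 12), 40)
    colnames(x) <- paste0("f", 1:12)
    labels <- factor(rep(c("control", "case"), each = 20),
                     levels = c("control", "case"))
  })
  rows <- group_ttest_fdr(x, labels)
  expect_equal(rows$q, p.adjust(rows$p, "BH"))
  # q monotone in p
  ord <- order(rows$p)
  expect_true(all(diff(rows$q[ord]) >= -1e-15))
  expect_true(all(rows$q >= rows$p))
})

test_that("the pooled t-test flags strong planted shifts and degenerate features", {
  ok <- vapply(1:20, function(s) {
    tab <- signal_table(n_per_group = 100, n_signal = 1, n_noise = 30,
                        shift = 1.5, seed = s)
    rows <- group_ttest_fdr(tab)
    rows$q[rows$feature == "sig1"] < 0.001
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  # direction matches the sign of the group difference
  tab <- signal_table(n_per_group = 50, n_signal = 1, n_noise = 2,
                      shift = 2, seed = 7)
  rows <- group_ttest_fdr(tab)
  expect_equal(rows$direction[rows$feature == "sig1"], "case>control")
  expect_gt(rows$t[rows$feature == "sig1"], 0)

  # zero variance in both groups -> p = 1 with flag
  x <- cbind(flat = rep(1, 20), ok = rnorm(20))
  labels <- factor(rep(c("control", "case"), each = 10),
                   levels = c("control", "case"))
  rows2 <- group_ttest_fdr(x, labels)
  expect_equal(rows2$p[rows2$feature == "flat"], 1)
  expect_true(rows2$degenerate[rows2$feature == "flat"])
})

test_that("reporting rules apply the per-modality conventions", {
  withr::with_seed(5, {
    rows <- tibble::tibble(
      feature = paste0("SLR|ROI", 1:30, "-ROI", 2:31),
      t = rnorm(30), p = runif(30, 0, 0.01))
  })
  rows$q <- p.adjust(rows$p, "BH")
  rows$direction <- ifelse(rows$t > 0, "case>control", "case<control")
  rows$significant <- TRUE
  out <- rank_and_report(rows, "SLR")
  expect_equal(nrow(out), 20)
  expect_true(all(diff(out$p) >= 0))

  out2 <- rank_and_report(rows[1:15, ], "SSGSR")
  expect_equal(nrow(out2), 15)

  # dHOFC cluster counting on the toy pair set
  dh <- tibble::tibble(
    feature = c("dHOFC|C1-C2", "dHOFC|C1-C3", "dHOFC|C2-C3", "dHOFC|C1-C4"),
    t = c(1, 2, -1, 3), p = c(0.001, 0.002, 0.003, 0.004))
  dh$q <- p.adjust(dh$p, "BH")
  dh$direction <- "case>control"
  dh$significant <- TRUE
  res <- rank_and_report(dh, "dHOFC")
  expect_equal(res$clusters$cluster, c(1, 2, 3, 4))
  expect_equal(res$clusters$count, c(3, 2, 2, 1))
  expect_equal(res$clusters$rank, 1:4)
})

test_that("feature-level FDR is controlled under the global null", {
  any_disc <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      x <- matrix(rnorm(40 * 20), 40)
      colnames(x) <- paste0("f", 1:20)
      labels <- factor(rep(c("control", "case"), each = 20),
                       levels = c("control", "case"))
    })
    any(group_ttest_fdr(x, labels)$significant)
  }, logical(1))
  rate <- mean(any_disc)
  mc_se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(rate, 0.05 + 2 * mc_se)
})

test_that("voxel cluster correction finds planted effects and is deterministic", {
  shape <- c(8, 8, 8)
  mask <- array(TRUE, dim = shape)
  n_per <- 10
  make_maps <- function(seed, effect) {
    withr::with_seed(seed, {
      lapply(1:n_per, function(i) {
        v <- array(rnorm(prod(shape)), dim = shape)
        if (effect) v[3:5, 3:5, 3:5] <- v[3:5, 3:5, 3:5] + 3
        v
      })
    })
  }
  case_maps <- sapply(make_maps(1, TRUE), function(m) m[mask])
  ctrl_maps <- sapply(make_maps(2, FALSE), function(m) m[mask])
  res <- voxel_cluster_test(case_maps, ctrl_maps, mask = mask,
                            voxel_p = 0.001, cluster_p = 0.05,
                            n_perm = 200, seed = 9)
  expect_gte(nrow(res$clusters), 1)
  top <- res$clusters[which.max(res$clusters$size), ]
  expect_true(top$x >= 3 && top$x <= 5)
  expect_equal(top$sign, "case>control")

  # determinism: identical inputs give the identical t-map
  res2 <- voxel_cluster_test(case_maps, ctrl_maps, mask = mask,
                             voxel_p = 0.001, cluster_p = 0.05,
                             n_perm = 200, seed = 9)
  expect_identical(res$t_map, res2$t_map)
  expect_identical(res$clusters, res2$clusters)

  # no suprathreshold voxels: empty table is valid
  null_res <- voxel_cluster_test(ctrl_maps[, 1:5], ctrl_maps[, 6:10],
                                 mask = mask, voxel_p = 1e-6,
                                 n_perm = 100, seed = 2)
  expect_equal(nrow(null_res$clusters), 0)
})

test_that("26-connectivity labeling groups diagonal neighbours", {
  m <- array(FALSE, dim = c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE   # corner-diagonal neighbour
  m[3, 3, 3] <- TRUE
  labs <- fcfusion:::connected_components_26(m)
  expect_equal(length(unique(labs[m])), 1)

  m2 <- array(FALSE, dim = c(5, 1, 1))
  m2[1, 1, 1] <- TRUE
  m2[5, 1, 1] <- TRUE
  labs2 <- fcfusion:::connected_components_26(m2)
  expect_equal(length(unique(labs2[m2])), 2)
})
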