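make_vseries <- function(signal_fn, shape = c(3, 3, 3), t_points = 500,
                         tr = 0.8) {
  tt <- (seq_len(t_points) - 1) * tr
  dat <- array(0, dim = c(shape, t_points))
  nx <- prod(shape)
  base <- signal_fn(tt)
  for (v in seq_len(nx)) {
    idx <- arrayInd(v, shape)
    dat[idx[1], idx[2], idx[3], ] <- base
  }
  voxel_series(dat, tr_seconds = tr)
}

test_that("ideal band-pass keeps in-band and rejects out-of-band sinusoids", {
  tr <- 0.8
  t_points <- 500
  tt <- (seq_len(t_points) - 1) * tr
  in_band <- sin(2 * pi * 0.05 * tt)
  out_band <- sin(2 * pi * 0.2 * tt)

  vs <- make_vseries(function(t) in_band + 3)
  filt <- bandpass(vs, 0.01, 0.1)
  expect_lt(max(abs(filt$data[1, 1, 1, ] - (in_band - mean(in_band)))) /
              max(abs(in_band)), 1e-8)

  vs2 <- make_vseries(function(t) out_band)
  filt2 <- bandpass(vs2, 0.01, 0.1)
  expect_lt(max(abs(filt2$data[1, 1, 1, ])) / max(abs(out_band)), 1e-8)

  # linearity: the filtered sum equals the in-band component alone
  vs3 <- make_vseries(function(t) in_band + out_band)
  filt3 <- bandpass(vs3, 0.01, 0.1)
  expect_lt(max(abs(filt3$data[2, 2, 2, ] - (in_band - mean(in_band)))),
            1e-8)

  expect_error(bandpass(vs, 0.01, 0.9), "Nyquist")
})

test_that("ALFF is zero for constants and homogeneous of degree one", {
  vs_const <- make_vseries(function(t) rep(5, length(t)), t_points = 64)
  expect_equal(max(abs(alff(vs_const)$values)), 0)

  tt <- (seq_len(500) - 1) * 0.8
  a1 <- make_vseries(function(t) 1.3 * sin(2 * pi * 0.05 * t))
  a2 <- make_vseries(function(t) 2.6 * sin(2 * pi * 0.05 * t))
  r <- alff(a2)$values[1, 1, 1] / alff(a1)$values[1, 1, 1]
  expect_equal(r, 2, tolerance = 1e-6)

  # white noise: two disjoint equal-width bands carry equal amplitude in
  # expectation (paired comparison over voxels)
  withr::with_seed(30, {
    dat <- array(rnorm(200 * 256), dim = c(200, 1, 1, 256))
  })
  vs <- voxel_series(dat, tr_seconds = 0.5)
  b1 <- alff(vs, band = c(0.1, 0.3))$values[, 1, 1]
  b2 <- alff(vs, band = c(0.5, 0.7))$values[, 1, 1]
  expect_gt(stats::t.test(b1, b2, paired = TRUE)$p.value, 0.01)
})

test_that("fALFF is the in-band fraction of total spectral amplitude", {
  tt <- (seq_len(500) - 1) * 0.8
  all_in <- make_vseries(function(t) sin(2 * pi * 0.05 * t))
  expect_equal(falff(all_in)$values[1, 1, 1], 1, tolerance = 1e-8)

  all_out <- make_vseries(function(t) sin(2 * pi * 0.25 * t))
  expect_lt(falff(all_out)$values[1, 1, 1], 1e-6)

  # equal-amplitude in- and out-of-band lines -> 0.5 (frequencies on
  # exact Fourier bins: 0.05 = 20/400 s, 0.25 = 100/400 s)
  both <- make_vseries(function(t) sin(2 * pi * 0.05 * t) +
                         sin(2 * pi * 0.25 * t))
  expect_equal(falff(both)$values[1, 1, 1], 0.5, tolerance = 0.01)

  # global gain invariance
  gained <- make_vseries(function(t) 7 * (sin(2 * pi * 0.05 * t) +
                                            sin(2 * pi * 0.25 * t)))
  expect_equal(falff(gained)$values[1, 1, 1], falff(both)$values[1, 1, 1],
               tolerance = 1e-10)

  flat <- make_vseries(function(t) rep(2, length(t)), t_points = 64)
  expect_warning(fl <- falff(flat), "flat")
  expect_equal(fl$values[1, 1, 1], 0)
})

test_that("ReHo equals the textbook rank-formula KCC", {
  # all series identical -> KCC 1
  vs <- make_vseries(function(t) sin(t), t_points = 50)
  expect_equal(reho(vs)$values[2, 2, 2], 1, tolerance = 1e-12)

  # two series, one increasing one decreasing -> KCC 0
  dat <- array(0, dim = c(2, 1, 1, 20))
  dat[1, 1, 1, ] <- 1:20
  dat[2, 1, 1, ] <- 20:1
  v2 <- voxel_series(dat)
  expect_equal(reho(v2)$values[1, 1, 1], 0, tolerance = 1e-12)

  # random volume: every interior voxel matches the brute-force formula
  withr::with_seed(44, {
    dat <- array(rnorm(5 * 5 * 5 * 40), dim = c(5, 5, 5, 40))
  })
  v3 <- voxel_series(dat)
  rh <- reho(v3)
  for (x in 2:4) for (y in 2:4) for (z in 2:4) {
    nb <- dat[(x - 1):(x + 1), (y - 1):(y + 1), (z - 1):(z + 1), ]
    mat <- t(matrix(nb, nrow = 27))
    expect_equal(rh$values[x, y, z], oracle_kcc(mat), tolerance = 1e-10)
  }
  expect_true(all(rh$values >= 0 & rh$values <= 1))

  # fewer than two in-mask series -> 0 with flag
  mask <- array(FALSE, dim = c(5, 5, 5))
  mask[1, 1, 1] <- TRUE
  v4 <- voxel_series(dat, mask = mask)
  r4 <- reho(v4)
  expect_equal(r4$values[1, 1, 1], 0)
  expect_true(r4$flags[1, 1, 1])
})

test_that("Gaussian smoothing preserves constants and has the right width", {
  vals <- array(1, dim = c(7, 7, 7))
  mask <- array(TRUE, dim = c(7, 7, 7))
  m <- structure(list(values = vals, mask = mask, measure = "ALFF",
                      flags = array(FALSE, dim = c(7, 7, 7))),
                 class = "voxel_map")
  sm <- smooth_gaussian(m, fwhm_mm = 4)
  expect_lt(max(abs(sm$values - 1)), 1e-10)

  expect_identical(smooth_gaussian(m, fwhm_mm = 0), m)

  # impulse response: half-max width within half a voxel of FWHM/voxel
  imp <- m
  imp$values <- array(0, dim = c(7, 7, 7))
  imp$values[4, 4, 4] <- 1
  attr(imp, "voxel_size_mm") <- c(1, 1, 1)
  smi <- smooth_gaussian(imp, fwhm_mm = 4)
  profile <- smi$values[, 4, 4]
  half <- max(profile) / 2
  above <- which(profile >= half)
  expect_lt(abs((max(above) - min(above) + 1) - 4), 1.5)
})

test_that("nuisance regression leaves residuals orthogonal to regressors", {
  withr::with_seed(9, {
    t_points <- 100
    motion <- rnorm(t_points)
    signal <- rnorm(t_points)
  })
  # series equal to a regressor -> zero residual
  x <- matrix(motion, ncol = 1)
  res <- nuisance_regress(x, regressors = cbind(motion))
  expect_lt(max(abs(res)), 1e-10)

  # contaminated series: residual uncorrelated with motion
  y <- matrix(signal + 2 * motion, ncol = 1)
  res2 <- nuisance_regress(y, regressors = cbind(motion))
  expect_lt(abs(sum(res2 * motion)) /
              (sqrt(sum(res2^2)) * sqrt(sum(motion^2))), 1e-8)

  # no regressors: demeaned and detrended only
  res3 <- nuisance_regress(y)
  expect_lt(abs(mean(res3)), 1e-10)

  # rank-deficient regressors dropped with a warning
  expect_warning(nuisance_regress(y, regressors = cbind(motion, motion)),
                 "dependent")
})

test_that("the measure pipeline applies the smoothing and filter exceptions", {
  withr::with_seed(50, {
    dat <- array(rnorm(4 * 4 * 4 * 64), dim = c(4, 4, 4, 64))
  })
  vs <- voxel_series(dat)
  out <- voxel_measures(vs, fwhm_mm = 2)
  expect_named(out, c("ALFF", "fALFF", "ReHo"))
  expect_true(all(out$ReHo$values >= 0 & out$ReHo$values <= 1))
  expect_true(all(out$fALFF$values >= 0 & out$fALFF$values <= 1 + 1e-12))
  expect_true(all(out$ALFF$values >= 0))

  # ReHo path must not smooth: identical to computing reho directly on
  # the band-passed unsmoothed data
  direct <- reho(bandpass(nuisance_regress(vs), 0.01, 0.1))
  expect_equal(out$ReHo$values, direct$values, tolerance = 1e-12)

  # fALFF path must not band-pass: equal to falff on the smoothed data
  direct_f <- falff(smooth_gaussian(nuisance_regress(vs), 2))
  expect_equal(out$fALFF$values, direct_f$values, tolerance = 1e-12)
})

test_that("NIfTI round-trip preserves voxel data", {
  withr::with_seed(60, {
    dat <- array(rnorm(3 * 3 * 3 * 64), dim = c(3, 3, 3, 64))
  })
  vs <- voxel_series(dat, tr_seconds = 0.8)
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(dat), path)
  back <- read_voxel_nifti(path, tr_seconds = 0.8)
  expect_equal(back$data, dat, tolerance = 1e-6, ignore_attr = TRUE)

  map <- alff(vs)
  out_path <- tempfile(fileext = ".nii.gz")
  write_voxel_map_nifti(map, out_path)
  expect_true(file.exists(out_path))
  expect_equal(as.array(RNifti::readNifti(out_path)), map$values,
               tolerance = 1e-6, ignore_attr = TRUE)
})
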