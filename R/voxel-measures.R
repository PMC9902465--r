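#' Voxel-level containers
#'
#' `voxel_series` holds a subject's 4D functional volume (X x Y x Z x T)
#' with its acquisition interval, binary brain mask and voxel size;
#' `voxel_map` holds one 3D summary map (ALFF, fALFF or ReHo) on the same
#' grid.
#'
#' @param data 4D numeric array, spatial dims then time.
#' @param tr_seconds Sampling interval in seconds.
#' @param mask 3D logical array matching the spatial dims; default all-in.
#' @param voxel_size_mm Length-3 voxel edge lengths in mm.
#' @return An object of class `voxel_series`.
#' @export
voxel_series <- function(data, tr_seconds = 0.8, mask = NULL,
                         voxel_size_mm = c(3, 3, 3)) {
  if (length(dim(data)) != 4L) abort("`data` must be a 4D array")
  spatial <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = spatial)
  if (!all(dim(mask) == spatial)) abort("mask shape must match spatial dims")
  if (dim(data)[4] < 2L) abort("need at least 2 timepoints")
  structure(
    list(data = data, tr_seconds = tr_seconds, mask = as.array(mask) > 0,
         voxel_size_mm = voxel_size_mm),
    class = "voxel_series"
  )
}

new_voxel_map <- function(values, mask, measure, flags = NULL) {
  structure(
    list(values = values, mask = mask, measure = measure,
         flags = flags %||% array(FALSE, dim = dim(values))),
    class = "voxel_map"
  )
}

#' @export
print.voxel_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_series> %d x %d x %d x %d, TR = %gs, %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, sum(x$mask)))
  invisible(x)
}

#' @export
print.voxel_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_map> %s, %d x %d x %d, %d in-mask voxels\n",
              x$measure, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

# Flatten the time dimension to a T x V matrix over in-mask voxels.
mask_matrix <- function(vs) {
  d <- dim(vs$data)
  flat <- matrix(aperm(vs$data, c(4, 1, 2, 3)), nrow = d[4])
  flat[, as.vector(vs$mask), drop = FALSE]
}

unmask_matrix <- function(vs, mat) {
  d <- dim(vs$data)
  flat <- matrix(0, nrow = d[4], ncol = prod(d[1:3]))
  flat[, as.vector(vs$mask)] <- mat
  aperm(array(flat, dim = c(d[4], d[1:3])), c(2, 3, 4, 1))
}

unmask_map <- function(mask, values_vec) {
  out <- array(0, dim = dim(mask))
  out[as.vector(mask)] <- values_vec
  out
}

# Ideal (frequency-domain) band-pass on a T x V matrix: zero every Fourier
# bin whose frequency lies outside [low, high]; the DC bin is always
# zeroed so the mean is removed.
bandpass_matrix <- function(mat, tr_seconds, low_hz, high_hz) {
  t_points <- nrow(mat)
  nyquist <- 1 / (2 * tr_seconds)
  if (low_hz < 0 || high_hz <= low_hz || high_hz > nyquist + 1e-12) {
    abort(sprintf("band must satisfy 0 <= low < high <= %.4g Hz (Nyquist)",
                  nyquist))
  }
  k <- seq_len(t_points) - 1
  freq <- pmin(k, t_points - k) / (t_points * tr_seconds)
  keep <- freq >= low_hz - 1e-12 & freq <= high_hz + 1e-12
  keep[1] <- FALSE
  ft <- stats::mvfft(mat)
  ft[!keep, ] <- 0
  Re(stats::mvfft(ft, inverse = TRUE)) / t_points
}

#' Temporal band-pass filter
#'
#' Ideal frequency-domain filter: Fourier bins outside `[low_hz, high_hz]`
#' are zeroed (the mean always is), exactly preserving in-band components.
#'
#' @param series A [voxel_series()], [roi_timeseries()] or T x N matrix.
#' @param low_hz,high_hz Band edges in Hz; `0 <= low < high <= Nyquist`.
#' @return The same type as the input, filtered.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1) {
  if (inherits(series, "voxel_series")) {
    mat <- mask_matrix(series)
    out <- bandpass_matrix(mat, series$tr_seconds, low_hz, high_hz)
    series$data <- unmask_matrix(series, out)
    series
  } else if (inherits(series, "roi_timeseries")) {
    series$data[] <- bandpass_matrix(series$data, series$tr_seconds,
                                     low_hz, high_hz)
    series
  } else {
    bandpass_matrix(as.matrix(series), attr(series, "tr_seconds") %||% 0.8,
                    low_hz, high_hz)
  }
}

# One-sided amplitude spectrum of each column of a demeaned T x V matrix:
# sqrt of the periodogram power per positive-frequency bin, scaled so a
# unit sinusoid at an exact bin has amplitude 1.
amplitude_spectrum <- function(mat, tr_seconds) {
  t_points <- nrow(mat)
  mat <- sweep(mat, 2, colMeans(mat))
  ft <- stats::mvfft(mat)
  n_pos <- floor(t_points / 2)
  amp <- 2 * Mod(ft[1 + seq_len(n_pos), , drop = FALSE]) / t_points
  freq <- seq_len(n_pos) / (t_points * tr_seconds)
  list(amplitude = amp, freq = freq)
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per voxel, the mean of the amplitude spectrum (square root of
#' periodogram power) over the frequency bins inside the band, classically
#' 0.01-0.1 Hz.
#'
#' @param series A [voxel_series()].
#' @param band Length-2 frequency band in Hz.
#' @return A `voxel_map` with measure tag `"ALFF"` (nonnegative values).
#' @export
alff <- function(series, band = c(0.01, 0.1)) {
  stopifnot(inherits(series, "voxel_series"))
  if (dim(series$data)[4] < 8) abort("ALFF needs at least 8 timepoints")
  sp <- amplitude_spectrum(mask_matrix(series), series$tr_seconds)
  in_band <- sp$freq >= band[1] - 1e-12 & sp$freq <= band[2] + 1e-12
  if (!any(in_band)) abort("band contains no frequency bins at this T and TR")
  vals <- colMeans(sp$amplitude[in_band, , drop = FALSE])
  new_voxel_map(unmask_map(series$mask, vals), series$mask, "ALFF")
}

#' Fractional ALFF (fALFF)
#'
#' Per voxel, the in-band amplitude sum divided by the amplitude sum over
#' the full detectable range (all positive frequencies up to Nyquist,
#' excluding DC). Computed on unfiltered data. Flat voxels (zero total
#' amplitude) get 0 and a flag.
#'
#' @inheritParams alff
#' @return A `voxel_map` with measure tag `"fALFF"`, values in `[0, 1]`.
#' @export
falff <- function(series, band = c(0.01, 0.1)) {
  stopifnot(inherits(series, "voxel_series"))
  if (dim(series$data)[4] < 8) abort("fALFF needs at least 8 timepoints")
  sp <- amplitude_spectrum(mask_matrix(series), series$tr_seconds)
  in_band <- sp$freq >= band[1] - 1e-12 & sp$freq <= band[2] + 1e-12
  if (!any(in_band)) abort("band contains no frequency bins at this T and TR")
  total <- colSums(sp$amplitude)
  flat <- total == 0
  if (any(flat)) warn(sprintf("%d flat voxel(s): fALFF set to 0", sum(flat)))
  vals <- colSums(sp$amplitude[in_band, , drop = FALSE]) /
    ifelse(flat, 1, total)
  vals[flat] <- 0
  flags <- unmask_map(series$mask, flat) > 0
  new_voxel_map(unmask_map(series$mask, vals), series$mask, "fALFF", flags)
}

# Kendall's coefficient of concordance of m rank-transformed series of
# length T (average ranks for ties, no tie correction term).
kcc <- function(series_mat) {
  m <- ncol(series_mat)
  t_points <- nrow(series_mat)
  ranks <- apply(series_mat, 2, rank)
  r_sum <- rowSums(ranks)
  s <- sum((r_sum - m * (t_points + 1) / 2)^2)
  12 * s / (m^2 * (t_points^3 - t_points))
}

neighborhood_offsets <- function(size) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(offs))
  switch(as.character(size),
         "7"  = offs[d <= 1, , drop = FALSE],
         "19" = offs[d <= 2, , drop = FALSE],
         "27" = offs,
         abort("`neighborhood` must be 7, 19 or 27"))
}

#' Regional homogeneity (ReHo)
#'
#' Per voxel, Kendall's coefficient of concordance of the voxel's time
#' series with its in-mask neighbors (27-, 19- or 7-voxel neighborhood).
#' Computed on band-passed, unsmoothed data by convention. Boundary voxels
#' use whatever in-mask neighbors exist; voxels with fewer than two
#' in-mask series get 0 and a flag.
#'
#' @param series A [voxel_series()].
#' @param neighborhood Neighborhood size: 7 (faces), 19 (faces + edges) or
#'   27 (full 3 x 3 x 3 cube).
#' @return A `voxel_map` with measure tag `"ReHo"`, values in `[0, 1]`.
#' @export
reho <- function(series, neighborhood = 27) {
  stopifnot(inherits(series, "voxel_series"))
  offs <- neighborhood_offsets(neighborhood)
  d <- dim(series$data)
  mask <- series$mask
  # Pre-rank every in-mask series once; KCC only needs ranks.
  flat <- matrix(aperm(series$data, c(4, 1, 2, 3)), nrow = d[4])
  in_idx <- which(as.vector(mask))
  ranks <- matrix(0, d[4], prod(d[1:3]))
  ranks[, in_idx] <- apply(flat[, in_idx, drop = FALSE], 2, rank)
  lin <- function(x, y, z) x + (y - 1) * d[1] + (z - 1) * d[1] * d[2]

  vals <- array(0, dim = d[1:3])
  flags <- array(FALSE, dim = d[1:3])
  coords <- which(mask, arr.ind = TRUE)
  t_points <- d[4]
  denom_base <- t_points^3 - t_points
  for (v in seq_len(nrow(coords))) {
    xyz <- coords[v, ]
    nb <- sweep(offs, 2, xyz, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    li <- lin(nb[, 1], nb[, 2], nb[, 3])
    li <- li[mask[li]]
    m <- length(li)
    if (m < 2) {
      flags[xyz[1], xyz[2], xyz[3]] <- TRUE
      next
    }
    r_sum <- rowSums(ranks[, li, drop = FALSE])
    s <- sum((r_sum - m * (t_points + 1) / 2)^2)
    vals[xyz[1], xyz[2], xyz[3]] <- 12 * s / (m^2 * denom_base)
  }
  new_voxel_map(vals, mask, "ReHo", flags)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  radius <- max(1L, ceiling(4 * sigma_vox))
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1) return(arr)
  radius <- (length(kernel) - 1) / 2
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  dm <- dim(a)
  mat <- matrix(a, nrow = dm[1])
  n <- dm[1]
  padded <- rbind(matrix(0, radius, ncol(mat)), mat,
                  matrix(0, radius, ncol(mat)))
  out <- matrix(0, n, ncol(mat))
  for (o in seq_along(kernel)) {
    out <- out + kernel[o] * padded[(o - 1) + seq_len(n), , drop = FALSE]
  }
  res <- array(out, dim = dm)
  aperm(res, order(perm))
}

smooth_array3d <- function(arr, mask, sigma_vox) {
  kx <- gaussian_kernel_1d(sigma_vox[1])
  ky <- gaussian_kernel_1d(sigma_vox[2])
  kz <- gaussian_kernel_1d(sigma_vox[3])
  m <- array(as.numeric(mask), dim = dim(mask))
  num <- arr * m
  for (ax in 1:3) {
    k <- list(kx, ky, kz)[[ax]]
    num <- convolve_axis(num, k, ax)
    m <- convolve_axis(m, k, ax)
  }
  out <- array(0, dim = dim(arr))
  inside <- mask & m > 0
  out[inside] <- num[inside] / m[inside]
  out
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian convolution with `sigma = FWHM / (2 sqrt(2 ln 2))`
#' per axis in voxel units, renormalized against the smoothed mask so that
#' constant images are preserved at mask edges.
#'
#' @param x A `voxel_map` or [voxel_series()].
#' @param fwhm_mm Full width at half maximum in mm (0 = identity).
#' @return The same type as the input, smoothed.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 4) {
  if (fwhm_mm == 0) return(x)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  if (inherits(x, "voxel_map")) {
    vox <- attr(x, "voxel_size_mm") %||% c(3, 3, 3)
    x$values <- smooth_array3d(x$values, x$mask, sigma_mm / vox)
    x
  } else if (inherits(x, "voxel_series")) {
    sigma_vox <- sigma_mm / x$voxel_size_mm
    d <- dim(x$data)
    for (t in seq_len(d[4])) {
      x$data[, , , t] <- smooth_array3d(x$data[, , , t, drop = TRUE],
                                        x$mask, sigma_vox)
    }
    x
  } else {
    abort("`x` must be a voxel_map or voxel_series")
  }
}

# OLS residualization of a T x V response matrix on [intercept, trend,
# regressors], dropping rank-deficient columns.
residualize_matrix <- function(mat, regressors = NULL) {
  t_points <- nrow(mat)
  design <- cbind(intercept = 1, trend = seq_len(t_points) - (t_points + 1) / 2)
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != t_points) {
      abort("regressors must have one row per timepoint")
    }
    design <- cbind(design, regressors)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warn(sprintf("dropping %d linearly dependent regressor column(s)",
                 ncol(design) - qrd$rank))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  qr.resid(qrd, mat)
}

#' Nuisance regression
#'
#' Removes nuisance structure by ordinary least squares: each voxel or ROI
#' series is replaced by its residual on an intercept, a linear trend and
#' the supplied regressor columns (e.g. head-motion parameters, WM and CSF
#' signals). Residuals are exactly orthogonal to every regressor.
#'
#' @param series A [voxel_series()], [roi_timeseries()] or T x N matrix.
#' @param regressors Optional T x p numeric matrix of nuisance regressors.
#' @return The same type as the input, residualized.
#' @export
nuisance_regress <- function(series, regressors = NULL) {
  if (inherits(series, "voxel_series")) {
    mat <- mask_matrix(series)
    series$data <- unmask_matrix(series, residualize_matrix(mat, regressors))
    series
  } else if (inherits(series, "roi_timeseries")) {
    series$data[] <- residualize_matrix(series$data, regressors)
    series
  } else {
    residualize_matrix(as.matrix(series), regressors)
  }
}

#' Voxel-measure extraction pipeline
#'
#' Applies the conventional processing order around each measure:
#' nuisance regression first, then spatial smoothing for ALFF/fALFF (ReHo
#' is computed on unsmoothed data), then temporal band-pass for ALFF and
#' ReHo (fALFF needs the unfiltered spectrum), then the measure itself.
#'
#' @param series A [voxel_series()].
#' @param measures Character subset of `c("ALFF", "fALFF", "ReHo")`.
#' @param band Low-frequency band in Hz.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param regressors Optional nuisance regressor matrix.
#' @param neighborhood ReHo neighborhood size.
#' @return Named list of `voxel_map`s.
#' @export
voxel_measures <- function(series, measures = c("ALFF", "fALFF", "ReHo"),
                           band = c(0.01, 0.1), fwhm_mm = 4,
                           regressors = NULL, neighborhood = 27) {
  stopifnot(inherits(series, "voxel_series"))
  measures <- match.arg(measures, several.ok = TRUE)
  cleaned <- nuisance_regress(series, regressors)
  smoothed <- if (fwhm_mm > 0) smooth_gaussian(cleaned, fwhm_mm) else cleaned
  out <- list()
  if ("ALFF" %in% measures) {
    out$ALFF <- alff(bandpass(smoothed, band[1], band[2]), band)
  }
  if ("fALFF" %in% measures) {
    out$fALFF <- falff(smoothed, band)
  }
  if ("ReHo" %in% measures) {
    out$ReHo <- reho(bandpass(cleaned, band[1], band[2]), neighborhood)
  }
  out
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers over RNifti for the package's voxel containers. The TR is
#' taken from the NIfTI header's fourth pixdim unless overridden.
#'
#' @param path Path to a 4D NIfTI file.
#' @param mask_path Optional path to a 3D binary mask NIfTI.
#' @param tr_seconds Optional TR override in seconds.
#' @return `read_voxel_nifti()`: a [voxel_series()].
#' @export
read_voxel_nifti <- function(path, mask_path = NULL, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) abort("expected a 4D NIfTI volume")
  pix <- RNifti::pixdim(img)
  mask <- if (!is.null(mask_path)) {
    as.array(RNifti::readNifti(mask_path)) > 0
  } else {
    NULL
  }
  voxel_series(arr,
               tr_seconds = tr_seconds %||%
                 (if (length(pix) >= 4 && pix[4] > 0) pix[4] else 0.8),
               mask = mask,
               voxel_size_mm = pix[1:3])
}

#' @rdname read_voxel_nifti
#' @param map A `voxel_map`.
#' @return `write_voxel_map_nifti()`: the path, invisibly.
#' @export
write_voxel_map_nifti <- function(map, path) {
  stopifnot(inherits(map, "voxel_map"))
  img <- RNifti::asNifti(map$values)
  RNifti::writeNifti(img, path)
  invisible(path)
}
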