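#' Synthetic two-group resting-state cohorts with planted effects
#'
#' The generator draws each subject's ROI time series as a stationary
#' Gaussian AR(1) process pushed through the Cholesky factor of a
#' group-specific correlation matrix, so both the cross-correlation
#' structure and the temporal autocorrelation are controlled exactly.
#' Group differences are planted as correlation shifts on a known set of
#' edges (static scenario) or as state-switching covariance dynamics
#' (dynamic scenario), and the planted structure is recorded on the cohort
#' so that downstream feature selection and biomarker identification can
#' be scored against ground truth.
#'
#' @name synthetic_cohort
NULL

#' Construct a pair of group connectivity models
#'
#' Builds two correlation models that are identical except at
#' `n_effect_edges` randomly chosen ROI pairs, where the case model's
#' correlation is shifted by `effect_delta`. With `n_states > 0` the case
#' model additionally receives `n_states` state covariance matrices whose
#' correlations at the effect edges alternate in sign, giving the case
#' group genuinely dynamic connectivity while the control group stays
#' stationary.
#'
#' @param n_rois Number of ROIs (N).
#' @param n_effect_edges Number of planted discriminative edges.
#' @param effect_delta Correlation-scale shift per effect edge, in (-1, 1).
#' @param n_states Number of covariance states for the dynamic scenario
#'   (0 = static).
#' @param seed Integer seed; fully determines the models.
#' @param base_strength Scale of the shared latent structure behind the
#'   base correlations (larger gives stronger baseline correlations).
#' @param dwell_mean Mean dwell time (timepoints) of each covariance state.
#' @return A list with elements `control` and `case`, each a `group_model`
#'   with fields `n_rois`, `base_cov`, `effect_edges`, `effect_delta`,
#'   `state_covs`, `dwell_mean`.
#' @export
make_group_models <- function(n_rois, n_effect_edges, effect_delta,
                              n_states = 0L, seed = 1L,
                              base_strength = 0.3, dwell_mean = 40) {
  n_rois <- check_count(n_rois, "n_rois", min = 2L)
  n_effect_edges <- check_count(n_effect_edges, "n_effect_edges", min = 0L)
  max_edges <- n_rois * (n_rois - 1) / 2
  if (n_effect_edges > max_edges) {
    abort("more effect edges requested than ROI pairs available")
  }
  if (abs(effect_delta) >= 1) abort("`effect_delta` must lie in (-1, 1)")

  with_seed(derive_seed(seed, 1L), {
    lat <- matrix(rnorm(n_rois * 3L), n_rois, 3L) * base_strength
    raw <- tcrossprod(lat) + diag(n_rois)
    base <- cov2cor(raw)
    # cov2cor is not bit-symmetric; fix once so both groups share the
    # exact same baseline entries.
    base <- (base + t(base)) / 2
    diag(base) <- 1

    pairs <- pair_index(n_rois)
    eff <- pairs[sample.int(nrow(pairs), n_effect_edges), , drop = FALSE]

    case_cov <- base
    if (n_effect_edges > 0) {
      shifted <- pmin(pmax(base[eff] + effect_delta, -0.95), 0.95)
      case_cov[eff] <- shifted
      case_cov[eff[, c(2, 1), drop = FALSE]] <- shifted
      case_cov <- ensure_spd(case_cov)
    }

    control_states <- NULL
    case_states <- NULL
    if (n_states > 0) {
      control_states <- replicate(n_states, base, simplify = FALSE)
      case_states <- lapply(seq_len(n_states), function(k) {
        sgn <- if (k %% 2 == 1) 1 else -1
        st <- base
        if (n_effect_edges > 0) {
          v <- pmin(pmax(base[eff] + sgn * effect_delta, -0.95), 0.95)
          st[eff] <- v
          st[eff[, c(2, 1), drop = FALSE]] <- v
        }
        ensure_spd(st)
      })
    }

    control <- new_group_model(n_rois, base, eff[0, , drop = FALSE], 0,
                               control_states, dwell_mean)
    case <- new_group_model(n_rois, case_cov, eff, effect_delta,
                            case_states, dwell_mean)
    list(control = control, case = case,
         effect_edges = eff, effect_delta = effect_delta)
  })
}

new_group_model <- function(n_rois, base_cov, effect_edges, effect_delta,
                            state_covs, dwell_mean) {
  structure(
    list(n_rois = n_rois, base_cov = base_cov, effect_edges = effect_edges,
         effect_delta = effect_delta, state_covs = state_covs,
         dwell_mean = dwell_mean),
    class = "group_model"
  )
}

# Nearest-SPD surrogate: clip eigenvalues at 1e-6, then renormalize to a
# unit-diagonal correlation matrix.
ensure_spd <- function(m, floor = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < floor) {
    m <- e$vectors %*% diag(pmax(e$values, floor)) %*% t(e$vectors)
    m <- cov2cor(m)
  }
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    abort("covariance model is not positive definite after repair")
  }
  m
}

#' Cohort simulation settings
#'
#' @param n_subjects_per_group Length-2 integer vector `(controls, cases)`.
#' @param t_points Number of timepoints per subject (default 370).
#' @param tr_seconds Sampling interval in seconds (default 0.8).
#' @param ar_coefficient Lag-1 temporal autocorrelation in `[0, 1)`.
#' @param covariate_model List of nuisance-covariate parameters:
#'   `sex_imbalance`, `manufacturer_imbalance` (probability shifts between
#'   groups), `n_sites`, `motion_group_shift` (log-scale mean shift of the
#'   head-motion scalar in the case group), `motion_sdlog`.
#' @param seed Integer seed; fully determines the cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects_per_group = c(50L, 50L),
                        t_points = 370L, tr_seconds = 0.8,
                        ar_coefficient = 0.3,
                        covariate_model = list(), seed = 1L) {
  if (length(n_subjects_per_group) == 1L) {
    n_subjects_per_group <- rep(n_subjects_per_group, 2L)
  }
  t_points <- check_count(t_points, "t_points", min = 2L)
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    abort("`ar_coefficient` must lie in [0, 1)")
  }
  cm <- modifyList(
    list(sex_imbalance = 0, manufacturer_imbalance = 0, n_sites = 4L,
         motion_group_shift = 0, motion_sdlog = 0.3),
    covariate_model
  )
  structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         t_points = t_points, tr_seconds = tr_seconds,
         ar_coefficient = ar_coefficient, covariate_model = cm,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate one subject's ROI time series
#'
#' Static scenario: Gaussian AR(1) innovations (unit marginal variance)
#' mapped through the Cholesky factor of the model's base correlation.
#' Dynamic scenario (the model carries state covariances): piecewise
#' stationary segments whose state follows a cycle with geometric dwell
#' times of the configured mean.
#'
#' @param model A `group_model`.
#' @param spec A [cohort_spec()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier stored on the result.
#' @return A [roi_timeseries()] with `spec$t_points` rows.
#' @export
simulate_subject <- function(model, spec, subject_seed,
                             subject_id = "sub") {
  t_points <- spec$t_points
  n <- model$n_rois
  phi <- spec$ar_coefficient
  with_seed(subject_seed, {
    z <- matrix(rnorm(t_points * n), t_points, n)
    if (phi > 0) {
      scale <- sqrt(1 - phi^2)
      for (t in 2:t_points) {
        z[t, ] <- phi * z[t - 1, ] + scale * z[t, ]
      }
    }
    if (is.null(model$state_covs)) {
      x <- z %*% chol(model$base_cov)
    } else {
      n_states <- length(model$state_covs)
      chols <- lapply(model$state_covs, chol)
      x <- matrix(0, t_points, n)
      t0 <- 1L
      state <- sample.int(n_states, 1L)
      while (t0 <= t_points) {
        dwell <- rgeom(1L, prob = 1 / model$dwell_mean) + 1L
        t1 <- min(t_points, t0 + dwell - 1L)
        x[t0:t1, ] <- z[t0:t1, , drop = FALSE] %*% chols[[state]]
        state <- state %% n_states + 1L
        t0 <- t1 + 1L
      }
    }
    roi_timeseries(x, tr_seconds = spec$tr_seconds, subject_id = subject_id)
  })
}

#' Simulate a small 4D voxel volume with planted group effects
#'
#' Baseline voxels carry independent Gaussian noise. Amplitude effects add
#' band-limited (0.01-0.1 Hz) oscillatory power inside the active regions;
#' homogeneity effects mix a shared latent signal into every voxel of a
#' region so that regional rank concordance (ReHo) rises with the shared
#' fraction (fraction 1 gives identical series, concordance 1).
#'
#' @param shape Length-3 integer vector of spatial dimensions.
#' @param active_regions List of regions, each
#'   `list(lo = c(x,y,z), hi = c(x,y,z))` (inclusive voxel boxes).
#' @param effect_type `"amplitude"` or `"homogeneity"`.
#' @param spec A [cohort_spec()]; supplies `t_points` and `tr_seconds`.
#' @param seed Integer seed.
#' @param effect_strength Amplitude of the planted oscillation (amplitude
#'   effect) or shared-signal fraction in `[0, 1]` (homogeneity effect).
#' @param mask Optional 3D logical array; defaults to all-in.
#' @return A [voxel_series()].
#' @export
simulate_voxel_volume <- function(shape, active_regions = list(),
                                  effect_type = c("amplitude", "homogeneity"),
                                  spec = cohort_spec(), seed = 1L,
                                  effect_strength = 1,
                                  mask = NULL) {
  effect_type <- match.arg(effect_type)
  shape <- as.integer(shape)
  if (length(shape) != 3L) abort("`shape` must have length 3")
  t_points <- spec$t_points
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  for (reg in active_regions) {
    lo <- as.integer(reg$lo)
    hi <- as.integer(reg$hi)
    if (any(lo < 1L) || any(hi > shape) || any(lo > hi)) {
      abort("active region lies outside the volume")
    }
    sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    if (!all(sub)) abort("active region lies outside the mask")
  }
  with_seed(seed, {
    dat <- array(rnorm(prod(shape) * t_points), dim = c(shape, t_points))
    tt <- (seq_len(t_points) - 1) * spec$tr_seconds
    for (reg in active_regions) {
      lo <- as.integer(reg$lo)
      hi <- as.integer(reg$hi)
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      if (effect_type == "amplitude") {
        freq <- runif(1, 0.02, 0.08)
        phase <- runif(1, 0, 2 * pi)
        boost <- effect_strength * sin(2 * pi * freq * tt + phase)
        for (x in xs) for (y in ys) for (z in zs) {
          dat[x, y, z, ] <- dat[x, y, z, ] + boost
        }
      } else {
        f <- min(max(effect_strength, 0), 1)
        shared <- rnorm(t_points)
        for (x in xs) for (y in ys) for (z in zs) {
          dat[x, y, z, ] <- sqrt(1 - f) * dat[x, y, z, ] + sqrt(f) * shared
        }
      }
    }
    voxel_series(dat, tr_seconds = spec$tr_seconds, mask = mask)
  })
}

#' Assemble a full synthetic cohort
#'
#' Simulates every subject of both groups with per-subject seeds derived
#' from the spec seed, samples nuisance covariates (sex, scanner
#' manufacturer, site, head motion) under the configured group imbalance,
#' and attaches the ground-truth record of planted edges.
#'
#' @param models Output of [make_group_models()].
#' @param spec A [cohort_spec()].
#' @return A `cohort`: list with `subjects` (list of `roi_timeseries`),
#'   `labels` (factor control/case), `covariates` (tibble), and
#'   `ground_truth` (planted edge list and effect size).
#' @export
make_cohort <- function(models, spec) {
  n_ctrl <- spec$n_subjects_per_group[1]
  n_case <- spec$n_subjects_per_group[2]
  if (n_ctrl < 1 || n_case < 1) abort("both groups must be non-empty")
  n_total <- n_ctrl + n_case
  labels <- factor(rep(c("control", "case"), c(n_ctrl, n_case)),
                   levels = c("control", "case"))
  ids <- sprintf("sub%03d", seq_len(n_total))

  subjects <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    model <- if (labels[s] == "control") models$control else models$case
    subjects[[s]] <- simulate_subject(
      model, spec, subject_seed = derive_seed(spec$seed, s + 1000L),
      subject_id = ids[s]
    )
  }

  cm <- spec$covariate_model
  covariates <- with_seed(derive_seed(spec$seed, 999L), {
    is_case <- labels == "case"
    p_sex <- ifelse(is_case, 0.5 + cm$sex_imbalance / 2,
                    0.5 - cm$sex_imbalance / 2)
    p_man <- ifelse(is_case, 0.5 + cm$manufacturer_imbalance / 2,
                    0.5 - cm$manufacturer_imbalance / 2)
    tibble::tibble(
      subject_id = ids,
      sex = factor(ifelse(rbinom(n_total, 1, p_sex) == 1, "F", "M")),
      manufacturer = factor(ifelse(rbinom(n_total, 1, p_man) == 1,
                                   "vendorA", "vendorB")),
      site = factor(sample(paste0("site", seq_len(cm$n_sites)), n_total,
                           replace = TRUE)),
      motion = rlnorm(n_total,
                      meanlog = -1 + ifelse(is_case, cm$motion_group_shift, 0),
                      sdlog = cm$motion_sdlog)
    )
  })

  structure(
    list(subjects = subjects, labels = labels, covariates = covariates,
         spec = spec,
         ground_truth = list(effect_edges = models$effect_edges,
                             effect_delta = models$effect_delta,
                             dynamic = !is.null(models$case$state_covs))),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects (%d control / %d case), %d ROIs, T = %d, TR = %gs\n",
    length(x$subjects), sum(x$labels == "control"), sum(x$labels == "case"),
    ncol(x$subjects[[1]]$data), nrow(x$subjects[[1]]$data),
    x$subjects[[1]]$tr_seconds
  ))
  if (nrow(x$ground_truth$effect_edges) > 0) {
    cat(sprintf("  planted: %d effect edges at delta = %g%s\n",
                nrow(x$ground_truth$effect_edges),
                x$ground_truth$effect_delta,
                if (x$ground_truth$dynamic) " (dynamic)" else ""))
  }
  invisible(x)
}
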