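# Small in-code fixtures shared across tests.

tiny_cohort <- function(n_rois = 6, n_per_group = 10, t_points = 60,
                        n_effect_edges = 2, effect_delta = 0.5,
                        seed = 42, ar = 0.2, n_states = 0,
                        covariate_model = list()) {
  models <- make_group_models(n_rois, n_effect_edges, effect_delta,
                              n_states = n_states, seed = seed)
  make_cohort(models, cohort_spec(
    n_subjects_per_group = c(n_per_group, n_per_group),
    t_points = t_points, ar_coefficient = ar,
    covariate_model = covariate_model, seed = seed))
}

# Feature table with `n_signal` features carrying a standardized group
# shift and `n_noise` pure-noise features.
signal_table <- function(n_per_group = 50, n_signal = 3, n_noise = 20,
                         shift = 1, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    labels <- factor(rep(c("control", "case"), each = n_per_group),
                     levels = c("control", "case"))
    x <- matrix(rnorm(n * (n_signal + n_noise)), n)
    x[labels == "case", seq_len(n_signal)] <-
      x[labels == "case", seq_len(n_signal)] + shift
    colnames(x) <- c(paste0("sig", seq_len(n_signal), recycle0 = TRUE),
                     paste0("noise", seq_len(n_noise), recycle0 = TRUE))
    feature_table(x, labels,
                  tibble::tibble(subject_id = sprintf("s%03d", 1:n)))
  })
}

# A hand-built 2-ROI model with a fixed correlation, bypassing the random
# base-structure generator.
fixed_corr_model <- function(r, n_rois = 2) {
  cov <- diag(n_rois)
  cov[1, 2] <- cov[2, 1] <- r
  structure(
    list(n_rois = n_rois, base_cov = cov,
         effect_edges = matrix(integer(0), 0, 2), effect_delta = 0,
         state_covs = NULL, dwell_mean = 40),
    class = "group_model"
  )
}

# Row-major upper-triangle pair index (i < j).
pair_index_of <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

rand_instance <- function(seed, t_points = 30, n = 5) {
  withr::with_seed(seed, matrix(rnorm(t_points * n), t_points, n))
}

rand_cohort_mats <- function(seed, s = 3, t_points = 30, n = 5) {
  withr::with_seed(seed, {
    lapply(seq_len(s), function(i) matrix(rnorm(t_points * n), t_points, n))
  })
}

two_modality_tables <- function(n_per_group = 30, shift = 1.2, seed = 1) {
  info <- signal_table(n_per_group, n_signal = 4, n_noise = 4,
                       shift = shift, seed = seed)
  info$modality <- "informative"
  noise <- signal_table(n_per_group, n_signal = 0, n_noise = 8,
                        shift = 0, seed = seed + 1000)
  noise$labels <- info$labels
  noise$covariates <- info$covariates
  noise$modality <- "noise"
  list(info = info, noise = noise)
}

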