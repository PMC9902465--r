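#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()],
#' with a compact synthetic demonstration cohort as the default input
#' (20 ROIs, 60 + 60 subjects, 8 planted edges at correlation shift 0.4,
#' T = 370, TR = 0.8 s).
#'
#' @param ... Named overrides merged into the defaults (nested lists are
#'   merged recursively).
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input = list(
      mode = "synthetic",
      n_rois = 20L, n_effect_edges = 8L, effect_delta = 0.4,
      n_states = 0L, n_subjects_per_group = c(60L, 60L),
      t_points = 370L, tr_seconds = 0.8, ar_coefficient = 0.3,
      covariate_model = list(),
      manifest = NULL
    ),
    measures = c("PC"),
    measure_params = list(
      dHOFC = list(window_length = 50L, k_clusters = 10L),
      SR = list(lambda1 = 0.01),
      GSR = list(lambda1 = 0.01),
      SSGSR = list(lambda1 = 0.06, lambda2 = 0.01),
      SLR = list(lambda1 = 0.05, lambda2 = 0.08)
    ),
    sensitivity = NULL,
    cv = list(outer_k = 10L, inner_k = 5L,
              classifiers = "svm_rbf",
              selector = "boruta",
              selector_args = list(n_trees = 150, max_rounds = 25L)),
    fusion = list(enabled = FALSE, methods = c("early", "mkl"),
                  regularization = 1),
    biomarkers = list(alpha = 0.05),
    seed = 1L,
    cache = TRUE
  )
  overrides <- list(...)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(over[[nm]]))) {
        base[[nm]] <- merge_rec(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  merge_rec(cfg, overrides)
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$input), !is.null(cfg$seed))
  if (!cfg$input$mode %in% c("synthetic", "files")) {
    abort("input mode must be 'synthetic' or 'files'")
  }
  bad <- setdiff(cfg$measures,
                 c("PC", "tHOFC", "dHOFC", "SR", "SLR", "GSR", "SSGSR"))
  if (length(bad) > 0) {
    abort(sprintf("unknown measure(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

pipeline_log <- function(out_dir, stage, msg) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(out_dir, "pipeline.log"),
      append = TRUE)
}

stage_cached <- function(out_dir, cfg, stage, enabled, compute) {
  key <- rlang::hash(list(stage = stage, cfg = cfg))
  path <- file.path(out_dir, "cache", paste0(stage, "-", key, ".rds"))
  if (enabled && file.exists(path)) {
    pipeline_log(out_dir, stage, "reusing cached result")
    return(readRDS(path))
  }
  res <- compute()
  if (enabled) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    saveRDS(res, path)
  }
  res
}

#' Load a cohort from delimited text files
#'
#' Reads a manifest TSV (columns `subject_id`, `file`, `label`, plus
#' covariates) whose `file` column names one TSV per subject: T rows x N
#' columns of ROI signals with a header of ROI labels.
#'
#' @param manifest Path to the manifest TSV; per-subject paths are
#'   resolved relative to it.
#' @param tr_seconds Sampling interval.
#' @return A `cohort` (with an empty ground-truth record).
#' @export
read_cohort_tsv <- function(manifest, tr_seconds = 0.8) {
  man <- utils::read.delim(manifest, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "file", "label")
  if (!all(need %in% names(man))) {
    abort("manifest must have columns subject_id, file, label")
  }
  base <- dirname(manifest)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    path <- man$file[i]
    if (!file.exists(path)) path <- file.path(base, man$file[i])
    m <- as.matrix(utils::read.delim(path, sep = "\t", check.names = FALSE))
    roi_timeseries(m, roi_labels = colnames(m), tr_seconds = tr_seconds,
                   subject_id = man$subject_id[i])
  })
  covs <- tibble::as_tibble(man[, setdiff(names(man), c("file", "label")),
                                drop = FALSE])
  covs[] <- lapply(covs, function(col) {
    if (is.character(col) && length(unique(col)) < length(col)) {
      factor(col)
    } else {
      col
    }
  })
  covs$subject_id <- as.character(man$subject_id)
  structure(
    list(subjects = subjects,
         labels = factor(man$label, levels = c("control", "case")),
         covariates = covs,
         spec = NULL,
         ground_truth = list(effect_edges = matrix(integer(0), 0, 2),
                             effect_delta = 0, dynamic = FALSE)),
    class = "cohort"
  )
}

#' Write an FC matrix as a labeled TSV
#'
#' @param fc An `fc_matrix`.
#' @param path Output path.
#' @export
write_fc_tsv <- function(fc, path) {
  utils::write.table(fc$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Run the full study pipeline
#'
#' Orchestrates the whole design: simulate (or load) a cohort, extract
#' the configured measures, optionally run the parameter-sensitivity
#' protocol, evaluate each measure with nested cross-validation, fuse
#' modalities, identify biomarkers, and write every stage's tables plus a
#' config echo and a line-oriented log into the output directory. Fully
#' deterministic given `config$seed`; stage outputs are cached by config
#' hash so partial reruns resume.
#'
#' @param config A configuration list (see [default_config()]) or path
#'   to a YAML file of overrides.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the cohort, feature tables, CV
#'   reports, sensitivity and biomarker results, and `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config)) {
    config <- do.call(default_config, yaml::read_yaml(config))
  }
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  seed <- config$seed

  pipeline_log(out_dir, "cohort", "building cohort")
  cohort <- stage_cached(out_dir, config["input"], "cohort", config$cache,
                         function() {
    if (config$input$mode == "synthetic") {
      inp <- config$input
      models <- make_group_models(inp$n_rois, inp$n_effect_edges,
                                  inp$effect_delta, inp$n_states,
                                  seed = seed)
      make_cohort(models, cohort_spec(
        n_subjects_per_group = inp$n_subjects_per_group,
        t_points = inp$t_points, tr_seconds = inp$tr_seconds,
        ar_coefficient = inp$ar_coefficient,
        covariate_model = inp$covariate_model, seed = seed))
    } else {
      read_cohort_tsv(config$input$manifest,
                      tr_seconds = config$input$tr_seconds %||% 0.8)
    }
  })

  sens_results <- list()
  if (!is.null(config$sensitivity)) {
    for (measure in names(config$sensitivity)) {
      pipeline_log(out_dir, "sensitivity", measure)
      sens <- stage_cached(
        out_dir, config[c("input", "sensitivity", "seed")],
        paste0("sensitivity-", measure), config$cache,
        function() parameter_sensitivity(
          cohort, measure, config$sensitivity[[measure]], seed = seed))
      sens_results[[measure]] <- sens
      write.csv(sens$table,
                file.path(out_dir, sprintf("sensitivity_%s.csv", measure)),
                row.names = FALSE)
    }
  }

  tables <- list()
  for (measure in config$measures) {
    pipeline_log(out_dir, "extract", measure)
    tab <- stage_cached(
      out_dir, config[c("input", "measure_params", "seed")],
      paste0("features-", measure), config$cache,
      function() {
        mp <- config$measure_params[[measure]] %||% list()
        residualize(do.call(cohort_features,
                            c(list(cohort = cohort, measure = measure),
                              if (measure %in% c("SR", "GSR")) {
                                list(params = sr_params(mp$lambda1 %||% 0.01))
                              } else if (measure %in% c("SLR", "SSGSR")) {
                                list(params = sr_params(
                                  lambda1 = mp$lambda1 %||% 0.05,
                                  lambda2 = mp$lambda2 %||% 0.08))
                              } else if (measure == "dHOFC") {
                                list(window_length = mp$window_length %||% 50L,
                                     k_clusters = mp$k_clusters %||% 10L)
                              } else {
                                list()
                              })))
      })
    tables[[measure]] <- tab
    utils::write.csv(cbind(subject_id = tab$covariates$subject_id,
                           label = as.character(tab$labels),
                           as.data.frame(tab$features)),
                     file.path(out_dir, sprintf("features_%s.csv", measure)),
                     row.names = FALSE)
  }

  reports <- list()
  specs <- lapply(config$cv$classifiers, classifier_spec)
  for (measure in config$measures) {
    pipeline_log(out_dir, "classify", measure)
    rep <- stage_cached(
      out_dir, config[c("input", "measure_params", "cv", "seed")],
      paste0("cv-", measure), config$cache,
      function() nested_cv(
        tables[[measure]], specs,
        outer_k = config$cv$outer_k, inner_k = config$cv$inner_k,
        seed = seed, selector = config$cv$selector,
        selector_args = config$cv$selector_args))
    reports[[measure]] <- rep
    write.csv(tidy(rep),
              file.path(out_dir, sprintf("cv_metrics_%s.csv", measure)),
              row.names = FALSE)
  }

  fusion_report <- NULL
  if (isTRUE(config$fusion$enabled) && length(tables) >= 2) {
    pipeline_log(out_dir, "fuse", paste(names(tables), collapse = "+"))
    fusion_report <- stage_cached(
      out_dir, config, "fusion", config$cache,
      function() fusion_cv(
        unname(tables), methods = config$fusion$methods,
        outer_k = config$cv$outer_k, inner_k = config$cv$inner_k,
        seed = seed, selector = config$cv$selector,
        selector_args = config$cv$selector_args,
        regularization = config$fusion$regularization))
    write.csv(tidy(fusion_report),
              file.path(out_dir, "cv_metrics_fusion.csv"),
              row.names = FALSE)
  }

  biomarker_tables <- list()
  for (measure in names(reports)) {
    pipeline_log(out_dir, "biomarkers", measure)
    stable <- stable_candidates(reports[[measure]])
    if (length(stable) == 0) next
    rows <- group_ttest_fdr(tables[[measure]], features = stable,
                            alpha = config$biomarkers$alpha)
    biomarker_tables[[measure]] <- rows
    write.csv(rows,
              file.path(out_dir, sprintf("biomarkers_%s.csv", measure)),
              row.names = FALSE)
  }

  summary <- dplyr::bind_rows(lapply(names(reports), function(m) {
    g <- glance(reports[[m]])
    g$measure <- m
    g
  }))
  if (!is.null(fusion_report)) {
    g <- glance(fusion_report)
    g$measure <- "fusion"
    summary <- dplyr::bind_rows(summary, g)
  }
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  pipeline_log(out_dir, "done", sprintf("outputs in %s", out_dir))
  invisible(list(cohort = cohort, tables = tables, reports = reports,
                 sensitivity = sens_results, fusion = fusion_report,
                 biomarkers = biomarker_tables, summary = summary,
                 out_dir = out_dir))
}
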