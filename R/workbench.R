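#' Configure an end-to-end benchmark experiment
#'
#' @param profiles named list of [cohort_profile()]s (or a path to a YAML
#'   file readable by [read_profiles_yaml()]).
#' @param architectures architectures to benchmark.
#' @param horizons_min prediction horizons in minutes (divisible by 5).
#' @param history_min input history length in minutes (divisible by 5;
#'   default 120 = a 2-hour sliding window).
#' @param train a [train_config()].
#' @param out_dir output directory for report tables, or `NULL` to skip
#'   writing.
#' @param master_seed master seed; all per-stage seeds derive from it.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(profiles, architectures = c("FFN", "LSTM"),
                              horizons_min = c(30, 60), history_min = 120,
                              train = train_config(), out_dir = NULL,
                              master_seed = 1L) {
  if (is.character(profiles)) profiles <- read_profiles_yaml(profiles)
  if (any(horizons_min %% 5 != 0)) stop("horizons must be divisible by 5")
  if (history_min %% 5 != 0) stop("history length must be divisible by 5")
  lapply(profiles, validate_profile)
  structure(list(profiles = profiles, architectures = architectures,
                 horizons_min = horizons_min, history_min = history_min,
                 train = train, out_dir = out_dir,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

stage_log <- function(log, stage, t0) {
  elapsed <- as.numeric(Sys.time()) - t0
  message(sprintf("[cgmbench] %-14s %7.1fs", stage, elapsed))
  rbind(log, data.frame(stage = stage, seconds = elapsed))
}

#' Run the full benchmark experiment
#'
#' Executes simulate, preprocess, train (with repetitions), analytical and
#' clinical evaluation, and cross-cohort generalization for every
#' (architecture, cohort, horizon) combination, and writes report tables
#' (metrics, Clarke Error Grid, generalization matrix, demographic slices,
#' complexity) as CSV files when `out_dir` is set. Fully reproducible from
#' `(config, master_seed)`.
#'
#' @param config an [experiment_config()].
#' @param residual_stride subsampling stride for KS residual comparisons
#'   (see [residuals_of()]).
#' @return a report bundle: list with `cohorts` (prepared data), `runs`
#'   (per arch/cohort/horizon training results), `metrics`, `ceg`,
#'   `generalization`, `demographics`, `complexity` and `log`.
#' @export
run_experiment <- function(config, residual_stride = 1L) {
  t0 <- as.numeric(Sys.time())
  log <- data.frame(stage = character(0), seconds = numeric(0))
  L <- config$history_min %/% 5L
  horizons <- config$horizons_min %/% 5L

  cohort_traces <- list()
  for (i in seq_along(config$profiles)) {
    p <- config$profiles[[i]]
    cohort_traces[[p$name]] <-
      simulate_cohort(p, derive_seed(config$master_seed, 100000L + i))
  }
  log <- stage_log(log, "simulate", t0)

  cohorts <- lapply(cohort_traces, function(traces) {
    prepare_cohort(traces, L = L, horizons = horizons,
                   split_seed = config$master_seed)
  })
  log <- stage_log(log, "preprocess", t0)

  runs <- list()
  metric_rows <- list()
  ceg_rows <- list()
  for (arch in config$architectures) {
    for (co in names(cohorts)) {
      for (h in horizons) {
        hkey <- as.character(h)
        spec <- model_spec(arch, input_length = L)
        tc <- config$train
        if (is.null(tc$batch_size)) {
          tc$batch_size <- batch_size_for_cohort(co, arch)
        }
        ws <- list(train = cohorts[[co]]$windows$train[[hkey]],
                   val = cohorts[[co]]$windows$val[[hkey]],
                   test = cohorts[[co]]$windows$test[[hkey]])
        rr <- repeat_runs(spec, ws, tc, cohorts[[co]]$params)
        runs[[arch]][[co]][[hkey]] <- rr
        sm <- rr$summary
        metric_rows[[length(metric_rows) + 1L]] <- data.frame(
          arch = arch, cohort = co, horizon_min = h * 5L,
          metric = sm$metric, mean = sm$mean, sd = sm$sd)
        # CEG pooled over repetitions
        pooled <- do.call(rbind, lapply(rr$models, function(m) {
          ps <- predict(m, ws$test, cohorts[[co]]$params)
          cbind(ps$refs, ps$preds)
        }))
        ceg <- ceg_analysis(prediction_set(pooled[, 1L], pooled[, 2L]),
                            clamp = TRUE)
        ceg_rows[[length(ceg_rows) + 1L]] <- data.frame(
          arch = arch, cohort = co, horizon_min = h * 5L,
          safe_ab = ceg$safe_percent, unsafe_cde = ceg$unsafe_percent,
          t(ceg$percent))
      }
    }
  }
  log <- stage_log(log, "train+evaluate", t0)

  gen_rows <- list()
  demo_rows <- list()
  for (h in horizons) {
    hkey <- as.character(h)
    models_h <- lapply(config$architectures, function(arch) {
      lapply(cohorts, function(cd) NULL)
    })
    names(models_h) <- config$architectures
    for (arch in config$architectures) {
      models_h[[arch]] <- lapply(names(cohorts), function(co) {
        runs[[arch]][[co]][[hkey]]$models[[1L]]
      })
      names(models_h[[arch]]) <- names(cohorts)
    }
    test_sets <- lapply(cohorts, function(cd) {
      list(windows = cd$windows$test[[hkey]], params = cd$params)
    })
    gm <- cross_evaluate(models_h, test_sets, residual_stride)
    gm$horizon <- NULL
    gm$horizon_min <- h * 5L
    gen_rows[[length(gen_rows) + 1L]] <- gm
    for (arch in config$architectures) {
      for (co in names(cohorts)) {
        ps <- predict(models_h[[arch]][[co]], test_sets[[co]]$windows,
                      test_sets[[co]]$params)
        if (length(unique(ps$sex)) < 2L) next
        d <- demographic_slices(ps, residual_stride)
        demo_rows[[length(demo_rows) + 1L]] <- data.frame(
          arch = arch, cohort = co, horizon_min = h * 5L,
          rmse_fm = d$rmse["FM"], rmse_m = d$rmse["M"],
          rmse_f = d$rmse["F"], p_fm_f = d$ks_p["FM_vs_F"],
          p_fm_m = d$ks_p["FM_vs_M"], p_f_m = d$ks_p["F_vs_M"],
          row.names = NULL)
      }
    }
  }
  log <- stage_log(log, "generalize", t0)

  complexity <- do.call(rbind, lapply(config$architectures, function(arch) {
    m <- build_model(model_spec(arch, input_length = L), seed = 1L)
    data.frame(arch = arch, n_params = count_parameters(m),
               flops = as.numeric(estimate_flops(m)))
  }))

  bundle <- list(
    cohorts = cohorts,
    runs = runs,
    metrics = do.call(rbind, metric_rows),
    ceg = do.call(rbind, ceg_rows),
    generalization = do.call(rbind, gen_rows),
    demographics = if (length(demo_rows)) do.call(rbind, demo_rows),
    complexity = complexity,
    log = log,
    config = config
  )
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  invisible(bundle)
}

#' Write the report tables of an experiment bundle
#'
#' @param bundle a [run_experiment()] result.
#' @param dir output directory.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(obj, name) {
    if (!is.null(obj)) write.csv(obj, file.path(dir, name), row.names = FALSE)
  }
  emit(bundle$metrics, "metrics.csv")
  emit(bundle$ceg, "ceg.csv")
  emit(bundle$generalization, "generalization.csv")
  emit(bundle$demographics, "demographics.csv")
  emit(bundle$complexity, "complexity.csv")
  emit(bundle$log, "log.csv")
  for (arch in unique(bundle$generalization$arch)) {
    for (hm in unique(bundle$generalization$horizon_min)) {
      g <- bundle$generalization[bundle$generalization$horizon_min == hm, ]
      class(g) <- c("generalization_matrix", "data.frame")
      piv <- pivot_generalization(g, arch)
      write.csv(piv, file.path(dir, sprintf("generalization_%s_%dmin.csv",
                                            arch, hm)))
    }
  }
  manifest <- list(
    architectures = bundle$config$architectures,
    horizons_min = bundle$config$horizons_min,
    history_min = bundle$config$history_min,
    master_seed = bundle$config$master_seed,
    cohorts = names(bundle$cohorts),
    epochs = bundle$config$train$epochs,
    repetitions = bundle$config$train$repetitions
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
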