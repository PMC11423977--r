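# Cohort CSV interchange: one file per patient with columns
# timestamp_min,glucose_mgdl plus a manifest listing patient metadata.

#' Write and read cohorts as per-patient CSV files
#'
#' `write_cohort()` writes one `<patient_id>.csv` per trace with columns
#' `timestamp_min,glucose_mgdl` and a `manifest.csv` with columns
#' `patient_id,cohort,age_group,sex`. `read_cohort()` reads them back.
#'
#' @param traces list of `glucose_trace` objects.
#' @param dir output (input) directory; created if needed.
#' @return `write_cohort()` the directory invisibly; `read_cohort()` a list
#'   of `glucose_trace` objects.
#' @export
write_cohort <- function(traces, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(patient_id = tr$patient_id, cohort = tr$cohort,
               age_group = tr$age_group, sex = tr$sex,
               stringsAsFactors = FALSE)
  }))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (tr in traces) {
    write.csv(data.frame(timestamp_min = tr$time_min,
                         glucose_mgdl = tr$glucose),
              file.path(dir, paste0(tr$patient_id, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    d <- read.csv(file.path(dir, paste0(manifest$patient_id[i], ".csv")))
    structure(list(patient_id = manifest$patient_id[i],
                   cohort = manifest$cohort[i],
                   age_group = manifest$age_group[i], sex = manifest$sex[i],
                   time_min = d$timestamp_min, glucose = d$glucose_mgdl,
                   nominal_interval = 5L),
              class = "glucose_trace")
  })
}

#' Read cohort profiles from YAML
#'
#' Each top-level YAML key names a cohort; its fields are passed to
#' [cohort_profile()] (with `age_groups` given as a name-to-proportion
#' mapping).
#'
#' @param path YAML file path.
#' @return named list of `cohort_profile` objects.
#' @export
read_profiles_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    fields <- raw[[nm]]
    if (!is.null(fields$age_groups)) {
      fields$age_groups <- unlist(fields$age_groups)
    }
    do.call(cohort_profile, c(list(name = nm), fields))
  })
  names(out) <- names(raw)
  out
}

#' @rdname read_profiles_yaml
#' @param profiles named list of `cohort_profile` objects.
#' @export
write_profiles_yaml <- function(profiles, path) {
  raw <- lapply(profiles, function(p) {
    p <- unclass(p)
    p$name <- NULL
    p$age_groups <- as.list(p$age_groups)
    p
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Write and read prediction sets as CSV
#'
#' Columns `ref_mgdl,pred_mgdl` (plus `sex` when labeled), with the context
#' stored in a JSON sidecar `<path>.json`.
#'
#' @param ps a [prediction_set()].
#' @param path CSV path.
#' @export
write_prediction_set <- function(ps, path) {
  d <- data.frame(ref_mgdl = ps$refs, pred_mgdl = ps$preds)
  if (!is.null(ps$sex)) d$sex <- ps$sex
  write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(ps$context, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prediction_set
#' @export
read_prediction_set <- function(path) {
  d <- read.csv(path)
  side <- paste0(path, ".json")
  ctx <- if (file.exists(side)) jsonlite::read_json(side) else list()
  prediction_set(d$ref_mgdl, d$pred_mgdl, context = ctx,
                 sex = if ("sex" %in% names(d)) d$sex)
}
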