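#' Align an irregular CGM trace to the 5-minute grid
#'
#' Establishes a 5-minute grid spanning the first to the last timestamp of
#' the trace and maps every observed sample to its nearest grid slot, with
#' ties resolved toward the earlier slot. Slots receiving no sample are
#' marked missing. If two samples land in the same slot the earlier one is
#' kept.
#'
#' @param trace a `glucose_trace`.
#' @return an object of class `aligned_series`: metadata plus `start_min`
#'   and `values` (glucose on the grid, `NA` where missing).
#' @export
align_to_grid <- function(trace) {
  t <- trace$time_min
  if (length(t) == 0) stop("trace has no samples")
  if (any(diff(t) <= 0)) {
    stop(sprintf("duplicate or non-increasing timestamps for patient %s",
                 trace$patient_id))
  }
  step <- trace$nominal_interval
  slot <- as.integer(ceiling((t - t[1L]) / step - 0.5 - 1e-9))
  first <- !duplicated(slot)
  values <- rep(NA_real_, max(slot) + 1L)
  values[slot[first] + 1L] <- trace$glucose[first]
  structure(list(patient_id = trace$patient_id, cohort = trace$cohort,
                 age_group = trace$age_group, sex = trace$sex,
                 start_min = t[1L], interval = step, values = values),
            class = "aligned_series")
}

#' Impute short gaps and split on long ones
#'
#' Missing runs of at most `max_gap_min` are filled by linear interpolation
#' between the flanking observed values; runs strictly longer than
#' `max_gap_min` split the series into separate contiguous segments with no
#' values fabricated inside the gap. Leading and trailing missing slots are
#' dropped.
#'
#' @param aligned an [align_to_grid()] result.
#' @param max_gap_min largest gap, in minutes, that is still interpolated
#'   (default 60; anything longer is discarded).
#' @return list of `cgm_segment` objects, each with gap-free `values` on a
#'   strict 5-minute grid and a logical `imputed` mask.
#' @export
impute_and_segment <- function(aligned, max_gap_min = 60) {
  step <- aligned$interval
  max_run <- floor(max_gap_min / step)
  v <- aligned$values
  miss <- is.na(v)
  if (all(miss)) return(list())
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # segment boundaries: long missing runs (plus the series ends)
  breaks <- which(r$values & r$lengths > max_run)
  seg_bounds <- rbind(c(1L, length(v)))
  if (length(breaks)) {
    cuts <- cbind(starts[breaks], ends[breaks])
    pieces <- list()
    lo <- 1L
    for (i in seq_len(nrow(cuts))) {
      if (cuts[i, 1L] > lo) pieces[[length(pieces) + 1L]] <- c(lo, cuts[i, 1L] - 1L)
      lo <- cuts[i, 2L] + 1L
    }
    if (lo <= length(v)) pieces[[length(pieces) + 1L]] <- c(lo, length(v))
    seg_bounds <- do.call(rbind, pieces)
  }
  segments <- list()
  for (i in seq_len(nrow(seg_bounds))) {
    idx <- seg_bounds[i, 1L]:seg_bounds[i, 2L]
    sv <- v[idx]
    obs <- which(!is.na(sv))
    if (length(obs) == 0) next
    idx <- idx[obs[1L]:obs[length(obs)]]     # trim leading/trailing NA
    sv <- v[idx]
    mask <- is.na(sv)
    if (any(mask)) {
      obs2 <- which(!mask)
      sv[mask] <- approx(obs2, sv[obs2], xout = which(mask))$y
    }
    segments[[length(segments) + 1L]] <- structure(list(
      patient_id = aligned$patient_id, cohort = aligned$cohort,
      age_group = aligned$age_group, sex = aligned$sex,
      start_min = aligned$start_min + (idx[1L] - 1L) * step,
      interval = step, values = sv, imputed = mask
    ), class = "cgm_segment")
  }
  segments
}

#' Fit and apply z-score normalization
#'
#' `fit_normalizer()` pools the values of all training segments of a cohort
#' and returns the mean and the population (divide-by-n) standard
#' deviation. `apply_normalizer()` maps glucose to z-scores
#' `(G - mu) / sigma`; `invert_normalizer()` maps back to mg/dL. The same
#' training-derived parameters are applied to training, validation and test
#' data.
#'
#' @param segments list of `cgm_segment` objects (training data only).
#' @return `fit_normalizer()`: an object of class `norm_params` with fields
#'   `mu` and `sigma`.
#' @export
fit_normalizer <- function(segments) {
  values <- unlist(lapply(segments, `[[`, "values"))
  if (length(values) == 0) stop("no training values")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) stop("constant training data: sigma = 0")
  structure(list(mu = mu, sigma = sigma), class = "norm_params")
}

#' @rdname fit_normalizer
#' @param params a `norm_params` object.
#' @param values numeric glucose values (mg/dL) or z-scores.
#' @export
apply_normalizer <- function(params, values) {
  (values - params$mu) / params$sigma
}

#' @rdname fit_normalizer
#' @param z normalized values.
#' @export
invert_normalizer <- function(params, z) {
  z * params$sigma + params$mu
}

#' Patient-level train/test split with chronological validation tail
#'
#' In cohort mode, patients are partitioned into a training pool and a test
#' set (no patient appears in both); within each training-pool patient the
#' chronologically last fraction of their data becomes validation. In
#' `ohio_mode`, each trace must carry a predefined `partition` field
#' (`"train"` or `"test"`) which is respected as-is, with validation still
#' carved chronologically from the training part.
#'
#' @param traces list of `glucose_trace` objects.
#' @param test_frac fraction of patients held out for testing (default 0.2).
#' @param val_frac chronological fraction of each training patient's data
#'   used for validation (default 0.2).
#' @param ohio_mode honor predefined per-trace partitions.
#' @param seed seed for the patient-level draw.
#' @return an object of class `split_plan`.
#' @export
split_cohort <- function(traces, test_frac = 0.2, val_frac = 0.2,
                         ohio_mode = FALSE, seed = 1L) {
  ids <- vapply(traces, `[[`, "", "patient_id")
  if (anyDuplicated(ids) && !ohio_mode) stop("duplicate patient ids")
  if (ohio_mode) {
    part <- vapply(traces, function(tr) {
      if (is.null(tr$partition)) stop("ohio_mode requires a partition field per trace")
      tr$partition
    }, "")
    train <- unique(ids[part == "train"])
    test <- unique(ids[part == "test"])
  } else {
    if (length(ids) < 2L) stop("cohort mode needs at least 2 patients")
    set.seed(seed)
    n_test <- max(1L, round(test_frac * length(ids)))
    test <- sort(sample(ids, n_test))
    train <- setdiff(ids, test)
  }
  structure(list(train_patients = train, test_patients = test,
                 val_frac = val_frac, ohio_mode = ohio_mode, seed = seed),
            class = "split_plan")
}

# Split a list of segments chronologically so that the last `tail_frac` of
# the total slot count forms the tail; a segment straddling the boundary is
# cut in two.
chronological_split <- function(segments, tail_frac) {
  lens <- vapply(segments, function(s) length(s$values), 0L)
  total <- sum(lens)
  n_tail <- floor(tail_frac * total)
  if (n_tail == 0L) return(list(head = segments, tail = list()))
  cum_from_end <- rev(cumsum(rev(lens)))
  head_segs <- list(); tail_segs <- list()
  taken <- 0L
  for (i in rev(seq_along(segments))) {
    s <- segments[[i]]
    if (taken >= n_tail) {
      head_segs <- c(list(s), head_segs)
    } else if (taken + lens[i] <= n_tail) {
      tail_segs <- c(list(s), tail_segs)
      taken <- taken + lens[i]
    } else {
      cut <- lens[i] - (n_tail - taken)
      s_head <- s; s_tail <- s
      s_head$values <- s$values[seq_len(cut)]
      s_head$imputed <- s$imputed[seq_len(cut)]
      s_tail$values <- s$values[(cut + 1L):lens[i]]
      s_tail$imputed <- s$imputed[(cut + 1L):lens[i]]
      s_tail$start_min <- s$start_min + cut * s$interval
      head_segs <- c(list(s_head), head_segs)
      tail_segs <- c(list(s_tail), tail_segs)
      taken <- n_tail
    }
  }
  list(head = head_segs, tail = tail_segs)
}

#' Build supervised sliding windows from segments
#'
#' For each segment of length `N` and each horizon `p`, emits
#' `max(0, N - L - p + 1)` windows whose input is the `L` consecutive
#' normalized values ending at step `t` and whose target is the normalized
#' value at step `t + p`. Windows never cross segment boundaries.
#'
#' @param segments list of `cgm_segment` objects.
#' @param L history length in 5-minute steps (default 24 = 2 h).
#' @param horizons vector of horizons in steps (default `c(6, 12)` = 30 and
#'   60 minutes).
#' @param params a `norm_params` used to normalize inputs and targets.
#' @return named list (one `window_set` per horizon) with fields `inputs`
#'   (n x L matrix), `targets`, `L`, `horizon` and a `provenance` data frame
#'   (`patient_id`, `segment`, `start`, `sex`, `age_group`).
#' @export
make_windows <- function(segments, L = 24L, horizons = c(6L, 12L), params) {
  if (L <= 0) stop("L must be positive")
  if (any(horizons <= 0)) stop("horizons must be positive")
  out <- lapply(horizons, function(p) {
    inputs <- list(); targets <- list(); prov <- list()
    for (si in seq_along(segments)) {
      s <- segments[[si]]
      n <- length(s$values)
      nw <- n - L - p + 1L
      if (nw < 1L) next
      z <- apply_normalizer(params, s$values)
      emb <- embed(z, L)[, L:1, drop = FALSE]
      inputs[[length(inputs) + 1L]] <- emb[seq_len(nw), , drop = FALSE]
      targets[[length(targets) + 1L]] <- z[(L + p):n]
      prov[[length(prov) + 1L]] <- data.frame(
        patient_id = s$patient_id, segment = si, start = seq_len(nw),
        sex = s$sex, age_group = s$age_group, stringsAsFactors = FALSE)
    }
    structure(list(
      inputs = if (length(inputs)) do.call(rbind, inputs)
               else matrix(numeric(0), 0L, L),
      targets = if (length(targets)) unlist(targets) else numeric(0),
      L = as.integer(L), horizon = as.integer(p),
      provenance = if (length(prov)) do.call(rbind, prov)
                   else data.frame(patient_id = character(0),
                                   segment = integer(0), start = integer(0),
                                   sex = character(0),
                                   age_group = character(0))
    ), class = "window_set")
  })
  names(out) <- as.character(horizons)
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows, L = %d, horizon = %d steps\n",
              nrow(x$inputs), x$L, x$horizon))
  invisible(x)
}

#' Run the full preprocessing pipeline on one cohort
#'
#' Splits patients, aligns every trace to the grid, imputes and segments,
#' fits the normalizer on training segments only, and builds per-horizon
#' window sets for the training, validation and test parts.
#'
#' @param traces list of `glucose_trace` objects for one cohort.
#' @param L history length in steps.
#' @param horizons horizons in steps.
#' @param max_gap_min gap-discard threshold in minutes.
#' @param test_frac,val_frac,split_seed,ohio_mode passed to [split_cohort()].
#' @return an object of class `cohort_data`: `cohort`, `params`
#'   (`norm_params`), `plan`, and `windows` (a list with `train`, `val`,
#'   `test`, each a per-horizon list of `window_set`s).
#' @export
prepare_cohort <- function(traces, L = 24L, horizons = c(6L, 12L),
                           max_gap_min = 60, test_frac = 0.2, val_frac = 0.2,
                           split_seed = 1L, ohio_mode = FALSE) {
  plan <- split_cohort(traces, test_frac, val_frac, ohio_mode, split_seed)
  ids <- vapply(traces, `[[`, "", "patient_id")
  seg_of <- function(tr) impute_and_segment(align_to_grid(tr), max_gap_min)
  train_segs <- list(); val_segs <- list(); test_segs <- list()
  for (tr in traces) {
    in_test <- tr$patient_id %in% plan$test_patients &&
      (!ohio_mode || identical(tr$partition, "test"))
    in_train <- tr$patient_id %in% plan$train_patients &&
      (!ohio_mode || identical(tr$partition, "train"))
    segs <- seg_of(tr)
    if (in_test) test_segs <- c(test_segs, segs)
    if (in_train) {
      sp <- chronological_split(segs, plan$val_frac)
      train_segs <- c(train_segs, sp$head)
      val_segs <- c(val_segs, sp$tail)
    }
  }
  params <- fit_normalizer(train_segs)
  cohort <- traces[[1L]]$cohort
  structure(list(
    cohort = cohort, params = params, plan = plan,
    segments = list(train = train_segs, val = val_segs, test = test_segs),
    windows = list(train = make_windows(train_segs, L, horizons, params),
                   val = make_windows(val_segs, L, horizons, params),
                   test = make_windows(test_segs, L, horizons, params))
  ), class = "cohort_data")
}
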