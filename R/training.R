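#' Training protocol configuration
#'
#' Fixes the optimization protocol of the benchmark: Adam minimizing RMSE
#' for up to `epochs` epochs, learning-rate decay by `lr_decay_factor` after
#' `lr_decay_patience` epochs without validation improvement, early
#' stopping after `early_stop_patience` epochs without improvement, and
#' `repetitions` independently seeded runs. The optimal learning rate is
#' architecture-specific (0.01 for FFN, 0.001 otherwise) and the optimal
#' batch size cohort-specific; `NULL` means resolve from the architecture
#' and cohort at training time.
#'
#' @param epochs maximum epochs (benchmark protocol: 100).
#' @param batch_size minibatch size, or `NULL` to resolve per cohort.
#' @param learning_rate Adam step size, or `NULL` to resolve per
#'   architecture.
#' @param lr_decay_factor,lr_decay_patience learning-rate decay rule.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param repetitions number of seeded repetitions for [repeat_runs()].
#' @param base_seed first seed; repetition k uses `base_seed + k - 1`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = NULL,
                         learning_rate = NULL, lr_decay_factor = 0.1,
                         lr_decay_patience = 10L, early_stop_patience = 30L,
                         repetitions = 5L, base_seed = 1L) {
  stopifnot(epochs >= 0, lr_decay_patience >= 1, early_stop_patience >= 1,
            repetitions >= 1)
  if (epochs > 0 && (lr_decay_patience > epochs || early_stop_patience > epochs)) {
    # patience larger than the epoch budget simply never fires; allowed
  }
  structure(list(epochs = as.integer(epochs), batch_size = batch_size,
                 learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_patience = as.integer(lr_decay_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 repetitions = as.integer(repetitions),
                 base_seed = as.integer(base_seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param architecture architecture name.
#' @export
default_learning_rate <- function(architecture) {
  if (architecture == "FFN") 0.01 else 0.001
}

#' @rdname train_config
#' @param cohort cohort name; matched by family (`ohio` 16, `rt` 512,
#'   `dclp` 1024, otherwise 512). CNN and TCN always use 16.
#' @export
batch_size_for_cohort <- function(cohort, architecture = "LSTM") {
  if (architecture %in% c("CNN", "TCN")) return(16L)
  if (grepl("ohio", cohort, ignore.case = TRUE)) 16L
  else if (grepl("dclp", cohort, ignore.case = TRUE)) 1024L
  else if (grepl("rt", cohort, ignore.case = TRUE)) 512L
  else 512L
}

# ---- patience scheduler: strict-decrease improvement resets both the
# decay counter and the stop counter; the two counters run independently
# and the decay counter restarts after each decay event.

sched_init <- function(lr, decay_factor, decay_patience, stop_patience) {
  list(lr = lr, best = Inf, best_epoch = 0L, epoch = 0L,
       decay_wait = 0L, stop_wait = 0L, decay_factor = decay_factor,
       decay_patience = decay_patience, stop_patience = stop_patience,
       stop = FALSE)
}

sched_step <- function(state, val) {
  state$epoch <- state$epoch + 1L
  if (val < state$best) {
    state$best <- val
    state$best_epoch <- state$epoch
    state$decay_wait <- 0L
    state$stop_wait <- 0L
  } else {
    state$decay_wait <- state$decay_wait + 1L
    state$stop_wait <- state$stop_wait + 1L
    if (state$decay_wait >= state$decay_patience) {
      state$lr <- state$lr * state$decay_factor
      state$decay_wait <- 0L
    }
    if (state$stop_wait >= state$stop_patience) state$stop <- TRUE
  }
  state
}

# ---- Adam (framework-default moments 0.9 / 0.999, eps 1e-8) on the nested
# parameter structure.

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  params <- map_params(function(p, m, v) {
    p - lr * (m * c1) / (sqrt(v * c2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

model_predict_norm <- function(model, inputs, chunk = 4096L) {
  n <- nrow(inputs)
  if (n == 0L) return(numeric(0))
  fused <- model$spec$architecture == "LSTM"
  out <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    xc <- inputs[lo:hi, , drop = FALSE]
    out[lo:hi] <- if (fused) lstm_net_step(model, xc)$yhat
                  else model_forward(model, xc)$yhat
  }
  out
}

val_rmse_of <- function(model, ws) {
  sqrt(mean((model_predict_norm(model, ws$inputs) - ws$targets)^2))
}

#' Train one model under the benchmark protocol
#'
#' Minibatch Adam minimizing per-batch RMSE on normalized targets; after
#' each epoch the validation RMSE is computed, the learning rate is decayed
#' by `lr_decay_factor` after `lr_decay_patience` epochs without strict
#' improvement, training stops early after `early_stop_patience` epochs
#' without improvement, and the returned checkpoint is the parameters with
#' the lowest validation RMSE.
#'
#' @param spec a [model_spec()].
#' @param windows list with `train` and `val` elements, each a `window_set`
#'   for one horizon.
#' @param config a [train_config()].
#' @param seed seed controlling initialization and batch shuffling.
#' @return an object of class `cgm_trained_model` with the best parameters,
#'   a `history` data frame (epoch, train RMSE, validation RMSE, learning
#'   rate), `best_epoch` and `stop_epoch`.
#' @export
train_model <- function(spec, windows, config, seed) {
  tr <- windows$train; va <- windows$val
  if (is.null(tr) || nrow(tr$inputs) == 0L) stop("empty training split")
  if (is.null(va) || nrow(va$inputs) == 0L) stop("empty validation split")
  if (tr$L != spec$input_length) {
    stop(sprintf("window L = %d does not match spec input_length = %d",
                 tr$L, spec$input_length))
  }
  model <- build_model(spec, seed)
  lr <- if (is.null(config$learning_rate)) {
    default_learning_rate(spec$architecture)
  } else config$learning_rate
  bs <- if (is.null(config$batch_size)) 512L else as.integer(config$batch_size)
  n <- nrow(tr$inputs)
  hist <- data.frame(epoch = integer(0), train_rmse = numeric(0),
                     val_rmse = numeric(0), lr = numeric(0))
  best_params <- model$params
  if (config$epochs == 0L) {
    return(structure(list(spec = spec, params = best_params, seed = seed,
                          config = config, history = hist, best_epoch = 0L,
                          stop_epoch = 0L,
                          n_params = count_parameters(model)),
                     class = c("cgm_trained_model", "cgm_model")))
  }
  sstate <- sched_init(lr, config$lr_decay_factor, config$lr_decay_patience,
                       config$early_stop_patience)
  astate <- adam_init(model$params)
  fused <- spec$architecture == "LSTM"
  set.seed(seed + 10007L)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(n, starts[bi] + bs - 1L)]
      x <- tr$inputs[idx, , drop = FALSE]
      y <- tr$targets[idx]
      if (fused) {
        st <- lstm_net_step(model, x, y)
        loss <- st$loss
        grads <- st$grads
      } else {
        fw <- model_forward(model, x)
        err <- fw$yhat - y
        loss <- sqrt(mean(err^2))
        dy <- if (loss > 0) err / (length(err) * loss) else err
        grads <- model_backward(model, fw$cache, x, dy)
      }
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d", epoch))
      }
      batch_losses[bi] <- loss
      upd <- adam_step(model$params, grads, astate, sstate$lr)
      model$params <- upd$params
      astate <- upd$state
    }
    vr <- val_rmse_of(model, va)
    if (!is.finite(vr)) stop(sprintf("non-finite validation loss at epoch %d", epoch))
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_rmse = mean(batch_losses),
                                   val_rmse = vr, lr = sstate$lr))
    improved <- vr < sstate$best
    sstate <- sched_step(sstate, vr)
    if (improved) best_params <- model$params
    if (sstate$stop) break
  }
  structure(list(spec = spec, params = best_params, seed = seed,
                 config = config, history = hist,
                 best_epoch = sstate$best_epoch,
                 stop_epoch = nrow(hist),
                 n_params = count_parameters(model)),
            class = c("cgm_trained_model", "cgm_model"))
}

#' @export
print.cgm_trained_model <- function(x, ...) {
  cat(sprintf(
    "<cgm_trained_model> %s: stopped at epoch %d (best %d, val RMSE %.4f)\n",
    x$spec$architecture, x$stop_epoch, x$best_epoch,
    if (nrow(x$history)) min(x$history$val_rmse) else NA))
  invisible(x)
}

#' Construct a prediction set
#'
#' Pairs reference and predicted glucose values (mg/dL) for one evaluation.
#'
#' @param refs,preds equal-length numeric vectors, mg/dL.
#' @param context optional named list (model, cohort, horizon, repetition).
#' @param sex optional per-window sex labels (for demographic slices).
#' @return an object of class `prediction_set` with `refs`, `preds`, `N`.
#' @export
prediction_set <- function(refs, preds, context = list(), sex = NULL) {
  if (length(refs) != length(preds)) stop("refs and preds must have equal length")
  structure(list(refs = as.numeric(refs), preds = as.numeric(preds),
                 N = length(refs), context = context, sex = sex),
            class = "prediction_set")
}

#' Predict glucose values for a window set
#'
#' Runs the trained model over the window inputs and de-normalizes both
#' predictions and reference targets back to mg/dL.
#'
#' @param object a `cgm_trained_model` (or `cgm_model`).
#' @param windows a `window_set` built with the model's input length.
#' @param norm_params the cohort's `norm_params`.
#' @param ... unused.
#' @return a [prediction_set()].
#' @export
predict.cgm_trained_model <- function(object, windows, norm_params, ...) {
  if (windows$L != object$spec$input_length) {
    stop(sprintf("window L = %d does not match model input_length = %d",
                 windows$L, object$spec$input_length))
  }
  z <- model_predict_norm(object, windows$inputs)
  prediction_set(invert_normalizer(norm_params, windows$targets),
                 invert_normalizer(norm_params, z),
                 context = list(model = object$spec$architecture,
                                horizon = windows$horizon),
                 sex = if (nrow(windows$provenance)) windows$provenance$sex)
}

#' @export
predict.cgm_model <- predict.cgm_trained_model

#' Persistence (last observed value) baseline predictions
#'
#' Forecasts each window's final history value; the standard naive
#' competitor for short-horizon glucose forecasting.
#'
#' @param windows a `window_set`.
#' @param norm_params the cohort's `norm_params`.
#' @return a [prediction_set()].
#' @export
persistence_baseline <- function(windows, norm_params) {
  z <- windows$inputs[, windows$L]
  prediction_set(invert_normalizer(norm_params, windows$targets),
                 invert_normalizer(norm_params, z),
                 context = list(model = "persistence",
                                horizon = windows$horizon),
                 sex = if (nrow(windows$provenance)) windows$provenance$sex)
}

#' Repeat training runs over seeds and aggregate test metrics
#'
#' Trains `config$repetitions` models with seeds `base_seed`,
#' `base_seed + 1`, ... and reports per-repetition analytical metrics on
#' the test split plus their mean and standard deviation (0 for a single
#' repetition).
#'
#' @param spec a [model_spec()].
#' @param windows list with `train`, `val` and `test` `window_set`s.
#' @param config a [train_config()].
#' @param norm_params the cohort's `norm_params`.
#' @return list with `models` (per-repetition trained models), `per_run`
#'   (metric data frame, one row per repetition) and `summary` (mean and sd
#'   per metric).
#' @export
repeat_runs <- function(spec, windows, config, norm_params) {
  seeds <- config$base_seed + seq_len(config$repetitions) - 1L
  models <- vector("list", length(seeds))
  rows <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    models[[k]] <- train_model(spec, windows, config, seeds[k])
    ps <- predict(models[[k]], windows$test, norm_params)
    m <- evaluate_metrics(ps)
    rows[[k]] <- data.frame(repetition = k, seed = seeds[k], rmse = m$rmse,
                            mad = m$mad, cod = m$cod, fit = m$fit,
                            madp = m$madp)
  }
  per_run <- do.call(rbind, rows)
  metrics <- c("rmse", "mad", "cod", "fit", "madp")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_run[[m]]), 0),
    sd = vapply(metrics, function(m) {
      if (nrow(per_run) < 2L) 0 else sd(per_run[[m]])
    }, 0),
    row.names = NULL
  )
  list(models = models, per_run = per_run, summary = summary)
}
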