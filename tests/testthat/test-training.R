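test_that("patience scheduler decays after 10 stalled epochs and stops after 30", {
  cfg <- train_config()
  st <- cgmbench:::sched_init(0.001, cfg$lr_decay_factor,
                              cfg$lr_decay_patience, cfg$early_stop_patience)
  # improve for 5 epochs, then plateau
  e_plateau <- 5L
  vals <- c(seq(1, 0.6, length.out = e_plateau), rep(0.6, 40))
  lr_trace <- numeric(0)
  stop_at <- NA_integer_
  for (i in seq_along(vals)) {
    st <- cgmbench:::sched_step(st, vals[i])
    lr_trace <- c(lr_trace, st$lr)
    if (st$stop) { stop_at <- st$epoch; break }
  }
  expect_identical(stop_at, e_plateau + 30L)        # plateau from e -> stop e + 30
  expect_identical(st$best_epoch, e_plateau)
  # first decay 10 epochs into the plateau, second after 10 more
  expect_equal(lr_trace[e_plateau + 10], 0.001 * 0.1)
  expect_equal(lr_trace[e_plateau + 20], 0.001 * 0.01)
  # improvement resets both counters
  st2 <- cgmbench:::sched_init(0.1, 0.1, 10L, 30L)
  for (v in c(1, rep(0.9, 9), 0.8)) st2 <- cgmbench:::sched_step(st2, v)
  expect_equal(st2$lr, 0.1)
  expect_identical(st2$stop_wait, 0L)
})

test_that("zero-epoch training returns the initialization with empty history", {
  cd <- mini_cohort_data()
  ws <- list(train = cd$windows$train[["6"]], val = cd$windows$val[["6"]])
  tm <- train_model(model_spec("FFN"), ws, train_config(epochs = 0), seed = 4)
  expect_identical(tm$params, build_model(model_spec("FFN"), 4)$params)
  expect_identical(nrow(tm$history), 0L)
  expect_identical(tm$stop_epoch, 0L)
})

test_that("training is deterministic and checkpoints the best epoch", {
  cd <- mini_cohort_data()
  ws <- list(train = cd$windows$train[["6"]], val = cd$windows$val[["6"]])
  cfg <- train_config(epochs = 3, batch_size = 2048, repetitions = 1)
  t1 <- train_model(model_spec("FFN"), ws, cfg, seed = 2)
  t2 <- train_model(model_spec("FFN"), ws, cfg, seed = 2)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)
  expect_equal(t1$best_epoch, which.min(t1$history$val_rmse))
  # the stored checkpoint reproduces the best validation RMSE
  vr <- cgmbench:::val_rmse_of(t1, ws$val)
  expect_equal(vr, min(t1$history$val_rmse), tolerance = 1e-9)
  expect_error(train_model(model_spec("FFN"),
                           list(train = ws$train, val = NULL), cfg, 1),
               "validation")
})

test_that("an LSTM learns a noiseless sinusoid", {
  t <- seq(0, 200 * pi, length.out = 4000)
  seg <- make_segment(150 + 40 * sin(t))
  np <- fit_normalizer(list(seg))
  ws6 <- make_windows(list(seg), L = 24, horizons = 6, params = np)[["6"]]
  idx_val <- seq(floor(0.8 * nrow(ws6$inputs)) + 1L, nrow(ws6$inputs))
  val <- ws6; val$inputs <- ws6$inputs[idx_val, ]; val$targets <- ws6$targets[idx_val]
  val$provenance <- ws6$provenance[idx_val, ]
  tr <- ws6; tr$inputs <- ws6$inputs[-idx_val, ]; tr$targets <- ws6$targets[-idx_val]
  tr$provenance <- ws6$provenance[-idx_val, ]
  cfg <- train_config(epochs = 10, batch_size = 256, repetitions = 1)
  tm <- train_model(model_spec("LSTM"), list(train = tr, val = val), cfg, 1)
  expect_lt(tm$history$val_rmse[nrow(tm$history)], tm$history$val_rmse[1])
  expect_lt(min(tm$history$val_rmse), 0.1)
})

test_that("predictions de-normalize correctly and empty sets are allowed", {
  cd <- mini_cohort_data()
  ws <- cd$windows$test[["6"]]
  m <- identity_ffn()
  m$spec$input_length <- ws$L
  tm <- structure(list(spec = m$spec, params = m$params, seed = 1),
                  class = c("cgm_trained_model", "cgm_model"))
  ps <- predict(tm, ws, cd$params)
  # persistence probe: identity network forecasts each window's last value
  pb <- persistence_baseline(ws, cd$params)
  expect_equal(ps$preds, pb$preds, tolerance = 1e-9)
  # de-normalized references recover the original segment values
  seg_vals <- unlist(lapply(cd$segments$test, `[[`, "values"))
  expect_true(all(round(ps$refs, 6) %in% round(seg_vals, 6)))

  empty <- ws
  empty$inputs <- ws$inputs[0, , drop = FALSE]
  empty$targets <- numeric(0)
  empty$provenance <- ws$provenance[0, ]
  ps0 <- predict(tm, empty, cd$params)
  expect_identical(ps0$N, 0L)

  wrong <- ws; wrong$L <- 12L
  expect_error(predict(tm, wrong, cd$params), "does not match")
})

test_that("reference values round-trip through normalization to 1e-6 mg/dL", {
  seg <- make_segment(runif(60, 80, 300))
  np <- fit_normalizer(list(seg))
  ws <- make_windows(list(seg), L = 24, horizons = 6, params = np)[["6"]]
  refs <- invert_normalizer(np, ws$targets)
  expect_equal(refs, seg$values[30:60], tolerance = 1e-6)
})

test_that("repeated runs aggregate with exact mean and zero-sd degenerate case", {
  cd <- mini_cohort_data()
  ws <- list(train = cd$windows$train[["6"]], val = cd$windows$val[["6"]],
             test = cd$windows$test[["6"]])
  cfg <- train_config(epochs = 2, batch_size = 4096, repetitions = 3,
                      base_seed = 5)
  rr <- repeat_runs(model_spec("FFN"), ws, cfg, cd$params)
  expect_identical(nrow(rr$per_run), 3L)
  expect_identical(rr$per_run$seed, 5:7)
  m <- rr$summary
  expect_equal(m$mean[m$metric == "rmse"], mean(rr$per_run$rmse),
               tolerance = 1e-12)
  expect_equal(m$sd[m$metric == "fit"], sd(rr$per_run$fit), tolerance = 1e-12)

  cfg1 <- train_config(epochs = 1, batch_size = 4096, repetitions = 1)
  rr1 <- repeat_runs(model_spec("FFN"), ws, cfg1, cd$params)
  expect_identical(rr1$summary$sd, rep(0, 5))
})
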