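test_that("grid alignment maps samples to nearest slots, earlier on ties", {
  tr <- make_trace(c(0, 5, 15), c(100, 110, 130))
  al <- align_to_grid(tr)
  expect_equal(al$values, c(100, 110, NA, 130))

  # exactly on grid: identity, no missing
  tr2 <- make_trace(seq(0, 45, by = 5), 100:109)
  expect_equal(align_to_grid(tr2)$values, 100:109)

  # single sample: one-slot grid
  expect_equal(align_to_grid(make_trace(7, 140))$values, 140)

  # off-grid samples snap to nearest slot; ties go to the earlier slot
  tr3 <- make_trace(c(0, 7.5, 13), c(1, 2, 3))
  # 7.5 ties between slots 5 and 10 -> earlier slot 5; 13 snaps to 15
  expect_equal(align_to_grid(tr3)$values, c(1, 2, NA, 3))

  expect_error(align_to_grid(make_trace(c(0, 0, 5), c(1, 2, 3))), "hand")
})

test_that("short gaps are linearly interpolated, long gaps split segments", {
  al <- align_to_grid(make_trace(c(0, 15), c(100, 130)))
  segs <- impute_and_segment(al)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$values, c(100, 110, 120, 130))
  expect_equal(segs[[1]]$imputed, c(FALSE, TRUE, TRUE, FALSE))

  # a 60-min run (12 slots) is still interpolated
  al12 <- align_to_grid(make_trace(c(0, 65), c(100, 230)))
  segs12 <- impute_and_segment(al12)
  expect_length(segs12, 1)
  expect_equal(segs12[[1]]$values, seq(100, 230, by = 10))

  # a 65-min run (13 slots) splits; none of the 13 slots is present
  al13 <- align_to_grid(make_trace(c(0, 5, 75, 80), c(1, 2, 3, 4)))
  segs13 <- impute_and_segment(al13)
  expect_length(segs13, 2)
  expect_equal(segs13[[1]]$values, c(1, 2))
  expect_equal(segs13[[2]]$values, c(3, 4))
  expect_equal(segs13[[2]]$start_min, 75)

  # fully observed: no-op
  al0 <- align_to_grid(make_trace(seq(0, 20, 5), 1:5))
  segs0 <- impute_and_segment(al0)
  expect_length(segs0, 1)
  expect_false(any(segs0[[1]]$imputed))
})

test_that("interpolation is exact on affine signals with interior gaps", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    a <- runif(1, -2, 2); b <- runif(1, 80, 150)
    times <- seq(0, by = 5, length.out = n)
    full <- a * times + b
    drop_idx <- sample(2:(n - 1), sample(1:8, 1))
    tr <- make_trace(times[-drop_idx], full[-drop_idx])
    segs <- impute_and_segment(align_to_grid(tr))
    rebuilt <- unlist(lapply(segs, `[[`, "values"))
    if (length(rebuilt) == n) {
      expect_equal(rebuilt, full, tolerance = 1e-9)
    }
  }
})

test_that("sample counts are conserved through segmentation", {
  set.seed(7)
  prof <- cohort_profile("c", 1, 2)
  tr <- simulate_trace(prof, 3)
  al <- align_to_grid(tr)
  segs <- impute_and_segment(al)
  observed_in_segs <- sum(vapply(segs, function(s) sum(!s$imputed), 0L))
  dropped <- length(tr$glucose) - observed_in_segs
  expect_gte(dropped, 0)
  expect_equal(observed_in_segs + dropped, length(tr$glucose))
  # no fabricated values inside long gaps: total segment length never
  # exceeds the grid span
  expect_lte(sum(vapply(segs, function(s) length(s$values), 0L)),
             length(al$values))
})

test_that("normalizer matches the population convention and round-trips", {
  np <- fit_normalizer(list(make_segment(c(100, 150, 200))))
  expect_equal(np$mu, 150)
  expect_equal(np$sigma, 40.8248, tolerance = 1e-4)
  expect_equal(apply_normalizer(np, 190), 0.9798, tolerance = 1e-4)
  expect_equal(apply_normalizer(np, 150), 0)
  x <- c(55, 120, 333.3)
  expect_equal(invert_normalizer(np, apply_normalizer(np, x)), x,
               tolerance = 1e-9)
  expect_error(fit_normalizer(list(make_segment(rep(100, 5)))), "sigma")
})

test_that("normalized training data has mean 0 and unit sd", {
  cd <- mini_cohort_data()
  z <- unlist(lapply(cd$segments$train, function(s)
    apply_normalizer(cd$params, s$values)))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
})

test_that("patient split is disjoint and validation is the chronological tail", {
  traces <- simulate_cohort(cohort_profile("c", 10, 0.1), 17)
  plan <- split_cohort(traces)
  expect_length(plan$test_patients, 2)
  expect_length(plan$train_patients, 8)
  expect_length(intersect(plan$train_patients, plan$test_patients), 0)
  expect_error(split_cohort(traces[1]), "at least 2")

  segs <- list(make_segment(rep(1, 1000)))
  sp <- cgmbench:::chronological_split(segs, 0.2)
  expect_equal(length(sp$tail[[1]]$values), 200)
  expect_equal(length(sp$head[[1]]$values), 800)
  expect_equal(sp$tail[[1]]$start_min, 800 * 5)
})

test_that("ohio mode honors predefined per-patient partitions", {
  tr1 <- make_trace(seq(0, 495, 5), rnorm(100, 150, 10), patient_id = "p1")
  tr1$partition <- "train"
  tr2 <- make_trace(seq(0, 495, 5), rnorm(100, 150, 10), patient_id = "p1")
  tr2$partition <- "test"
  plan <- split_cohort(list(tr1, tr2), ohio_mode = TRUE)
  expect_identical(plan$train_patients, "p1")
  expect_identical(plan$test_patients, "p1")
  expect_error(split_cohort(list(tr1), ohio_mode = FALSE), "at least 2")
})

test_that("window counts follow max(0, N - L - p + 1) and never cross segments", {
  np <- identity_norm
  ws <- make_windows(list(make_segment(rnorm(30))), L = 24, horizons = 6,
                     params = np)[["6"]]
  expect_equal(nrow(ws$inputs), 1)
  ws2 <- make_windows(list(make_segment(rnorm(100))), L = 24, horizons = 12,
                      params = np)[["12"]]
  expect_equal(nrow(ws2$inputs), 65)
  ws3 <- make_windows(list(make_segment(rnorm(29))), L = 24, horizons = 6,
                      params = np)[["6"]]
  expect_equal(nrow(ws3$inputs), 0)

  set.seed(13)
  for (i in 1:25) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    L <- sample(2:30, 1); p <- sample(1:15, 1)
    segs <- list(make_segment(rnorm(n1)), make_segment(rnorm(n2)))
    ws <- make_windows(segs, L, p, np)[[1]]
    expect_equal(nrow(ws$inputs),
                 max(0, n1 - L - p + 1) + max(0, n2 - L - p + 1))
  }
  expect_error(make_windows(list(), L = 0, horizons = 6, np), "L must")
  expect_error(make_windows(list(), L = 5, horizons = -1, np), "horizons")
})

test_that("window inputs and targets index the right segment positions", {
  seg <- make_segment(1:40)
  ws <- make_windows(list(seg), L = 24, horizons = 6,
                     params = identity_norm)[["6"]]
  expect_equal(nrow(ws$inputs), 40 - 24 - 6 + 1)
  expect_equal(ws$inputs[1, ], 1:24)
  expect_equal(ws$targets[1], 30)
  expect_equal(ws$inputs[11, ], 11:34)
  expect_equal(ws$targets[11], 40)
})

test_that("no test patient contributes training windows", {
  cd <- mini_cohort_data()
  tr_pat <- unique(cd$windows$train[["6"]]$provenance$patient_id)
  te_pat <- unique(cd$windows$test[["6"]]$provenance$patient_id)
  expect_length(intersect(tr_pat, te_pat), 0)
  expect_setequal(te_pat, cd$plan$test_patients)
})
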