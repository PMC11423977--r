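test_that("identical (profile, seed) gives bit-identical traces; different seeds differ", {
  prof <- cohort_profile("c", 2, 1)
  t1 <- simulate_trace(prof, 99)
  t2 <- simulate_trace(prof, 99)
  expect_identical(t1, t2)
  c1 <- simulate_cohort(prof, 1)
  c2 <- simulate_cohort(prof, 2)
  expect_false(identical(lapply(c1, `[[`, "glucose"),
                         lapply(c2, `[[`, "glucose")))
})

test_that("traces respect the sensor reporting range and the grid", {
  for (s in 1:3) {
    tr <- simulate_trace(cohort_profile("c", 1, 2), s)
    expect_gte(min(tr$glucose), 40)
    expect_lte(max(tr$glucose), 400)
    expect_true(all(diff(tr$time_min) %% 5 == 0))
    expect_true(all(diff(tr$time_min) > 0))
  }
})

test_that("short-gap deletion fraction matches its Bernoulli rate", {
  prof <- cohort_profile("c", 1, 4, short_gap_prob = 0.05, long_gap_rate = 0)
  for (s in 1:3) {
    tr <- simulate_trace(prof, s)
    frac <- 1 - length(tr$glucose) / attr(tr, "n_grid")
    expect_lt(abs(frac - 0.05), 0.01)
  }
})

test_that("cohorts have the requested size, distinct ids and sex balance", {
  prof <- cohort_profile("c", 12, 0.1)
  traces <- simulate_cohort(prof, 5)
  expect_length(traces, 12)
  expect_length(unique(vapply(traces, `[[`, "", "patient_id")), 12)

  big <- cohort_profile("big", 400, 0.05, sex_ratio = 0.5)
  sexes <- vapply(simulate_cohort(big, 7), `[[`, "", "sex")
  expect_gte(mean(sexes == "F"), 0.44)
  expect_lte(mean(sexes == "F"), 0.56)
})

test_that("cohorts are extensible without reshuffling earlier patients", {
  small <- cohort_profile("c", 3, 0.2)
  large <- cohort_profile("c", 5, 0.2)
  c_small <- simulate_cohort(small, 11)
  c_large <- simulate_cohort(large, 11)
  expect_identical(c_small, c_large[1:3])
})

test_that("closed-loop therapy strictly reduces glucose variability", {
  open <- cohort_profile("x", 4, 2, closed_loop = FALSE, basal_mean = 145,
                         basal_sd = 38)
  closed <- cohort_profile("x", 4, 2, closed_loop = TRUE, basal_mean = 145,
                           basal_sd = 38)
  g_open <- unlist(lapply(simulate_cohort(open, 3), `[[`, "glucose"))
  g_closed <- unlist(lapply(simulate_cohort(closed, 3), `[[`, "glucose"))
  expect_lt(sd(g_closed), sd(g_open))
})

test_that("default cohorts place glucose mass realistically", {
  for (prof in default_profiles("mini")) {
    g <- unlist(lapply(simulate_cohort(prof, 21), `[[`, "glucose"))
    expect_gte(mean(g >= 70 & g <= 250), 0.60)
    expect_gte(mean(g > 250), 0.02)
  }
})

test_that("default traces contain both short and long gaps", {
  tr <- simulate_trace(cohort_profile("g", 1, 4), 11)
  gaps <- diff(tr$time_min)
  expect_gt(sum(gaps > 5 & gaps <= 60), 0)
  expect_gt(sum(gaps > 65), 0)
  # every deleted stretch is classifiable into one of the two kinds
  expect_true(all(gaps[gaps > 5] > 5))
})

test_that("density overview is normalized and finds the expected modes", {
  flat <- make_trace(seq(0, 495, by = 5), rep(120, 100))
  dv <- density_overview(flat)
  expect_equal(sum(dv$mass), 1, tolerance = 1e-9)
  expect_length(dv$modes, 1)
  expect_true(dv$dominant_mode >= 120 - 10 && dv$dominant_mode <= 120 + 10)

  traces <- unlist(lapply(default_profiles("mini"), simulate_cohort,
                          master_seed = 8), recursive = FALSE)
  dv2 <- density_overview(traces)
  expect_equal(sum(dv2$mass), 1, tolerance = 1e-9)
  expect_gte(dv2$dominant_mode, 100)
  expect_lte(dv2$dominant_mode, 200)
  expect_gte(length(dv2$modes), 2)       # bimodal: a minor high mode exists
  expect_gte(max(dv2$modes), 300)
  expect_error(density_overview(list()), "no glucose")
})

test_that("invalid profiles are rejected", {
  expect_error(cohort_profile("x", 0, 1), "n_patients")
  expect_error(cohort_profile("x", 1, 1, age_groups = c(adult = 0.5)),
               "sum to 1")
  expect_error(cohort_profile("x", 1, 1, basal_mean = 300), "basal_mean")
  expect_error(cohort_profile("x", 1, 1, sex_ratio = 1.2), "sex_ratio")
})

test_that("cohort CSV round trip preserves traces and metadata", {
  traces <- simulate_cohort(cohort_profile("io", 2, 0.2), 31)
  dir <- withr::local_tempdir()
  write_cohort(traces, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$glucose, traces[[i]]$glucose, tolerance = 1e-9)
    expect_identical(back[[i]]$time_min, as.integer(traces[[i]]$time_min))
    expect_identical(back[[i]]$sex, traces[[i]]$sex)
  }
})

test_that("profile YAML round trip reproduces the profile", {
  profs <- default_profiles("mini")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_profiles_yaml(profs, path)
  back <- read_profiles_yaml(path)
  expect_equal(back$dclp_mini$basal_mean, profs$dclp_mini$basal_mean)
  expect_equal(back$dclp_mini$age_groups, profs$dclp_mini$age_groups)
  expect_identical(back$dclp_mini$closed_loop, TRUE)
})
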