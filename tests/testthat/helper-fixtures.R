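# Shared fixtures, all generated in code.

# A hand-built trace on (or off) the 5-minute grid.
make_trace <- function(times, values, patient_id = "hand", cohort = "hand",
                       sex = "F", age_group = "adult") {
  structure(list(patient_id = patient_id, cohort = cohort,
                 age_group = age_group, sex = sex,
                 time_min = times, glucose = values, nominal_interval = 5L),
            class = "glucose_trace")
}

# A gap-free segment with given values.
make_segment <- function(values, patient_id = "hand", sex = "F",
                         age_group = "adult", start_min = 0) {
  structure(list(patient_id = patient_id, cohort = "hand",
                 age_group = age_group, sex = sex, start_min = start_min,
                 interval = 5L, values = values,
                 imputed = rep(FALSE, length(values))),
            class = "cgm_segment")
}

# Identity normalizer: z-scores equal to mg/dL values.
identity_norm <- structure(list(mu = 0, sigma = 1), class = "norm_params")

# Small cohort + prepared data shared by the training-level tests.
mini_cohort_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prof <- cohort_profile("dclp_tiny", 4, 1, closed_loop = TRUE,
                             basal_mean = 145, basal_sd = 38)
      traces <- simulate_cohort(prof, 404)
      cache <<- prepare_cohort(traces, L = 24L, horizons = c(6L))
    }
    cache
  }
})

# An FFN whose output equals the final history value: relu(x) - relu(-x) = x
# routed through the 1-32-64-1 stack.
identity_ffn <- function() {
  m <- build_model(model_spec("FFN"), seed = 1)
  m$params <- cgmbench:::map_params(function(p) p * 0, m$params)
  m$params$fc1$W[1, 1] <- 1
  m$params$fc1$W[1, 2] <- -1
  m$params$fc2$W[1, 1] <- 1
  m$params$fc2$W[2, 2] <- 1
  m$params$fc3$W[1, 1] <- 1
  m$params$fc3$W[2, 1] <- -1
  m
}

# Brute-force two-sample KS: exact p by enumeration over all C(n+m, n)
# assignments of the pooled order statistics.
ks_exact_bruteforce <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  d_of <- function(xa, xb) {
    grid <- sort(unique(c(xa, xb)))
    fa <- vapply(grid, function(g) mean(xa <= g), 0)
    fb <- vapply(grid, function(g) mean(xb <= g), 0)
    max(abs(fa - fb))
  }
  d_obs <- d_of(a, b)
  combs <- utils::combn(n + m, n)
  ge <- 0L
  for (j in seq_len(ncol(combs))) {
    ia <- combs[, j]
    if (d_of(pooled[ia], pooled[-ia]) >= d_obs - 1e-12) ge <- ge + 1L
  }
  list(statistic = d_obs, p.value = ge / ncol(combs))
}
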