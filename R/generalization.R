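#' Two-sample Kolmogorov-Smirnov test on residual sets
#'
#' Compares two residual distributions by the supremum distance between
#' their empirical CDFs. The p-value is exact (by enumeration over
#' orderings) when `n * m <= 10000` and uses the asymptotic Kolmogorov
#' distribution otherwise, mirroring the convention of
#' [stats::ks.test()], to which the computation is delegated. A distance of
#' exactly 0 (identical samples) reports p = 1.
#'
#' @param a,b non-empty numeric vectors of residuals (mg/dL).
#' @return list with `statistic` (D), `p.value` and `exact` (logical).
#' @export
#' @examples
#' ks_two_sample(c(0, 1, 2, 3), c(10, 11, 12, 13)) # D = 1, p = 2/70
ks_two_sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("empty residual sample")
  exact <- as.numeric(length(a)) * length(b) <= 10000
  kt <- suppressWarnings(ks.test(a, b, exact = exact))
  d <- unname(kt$statistic)
  p <- if (d == 0) 1 else unname(kt$p.value)
  list(statistic = d, p.value = p, exact = exact)
}

#' Residuals of a prediction set
#'
#' Reference minus predicted glucose, mg/dL.
#'
#' @param ps a [prediction_set()].
#' @param stride keep every `stride`-th residual (default 1 = all). A
#'   stride of several hours of windows yields approximately independent
#'   residuals for distributional tests on densely overlapping windows.
#' @return numeric vector.
#' @export
residuals_of <- function(ps, stride = 1L) {
  r <- ps$refs - ps$preds
  if (stride > 1L) r <- r[seq(1L, length(r), by = stride)]
  r
}

#' Cross-cohort generalization matrix
#'
#' Evaluates every trained model on every cohort's test set. Test data are
#' standardized with their own cohort's training parameters before being
#' fed to a foreign model (models consume z-scores; the normalization
#' travels with the data). Each cell reports the RMSE in mg/dL and the KS
#' p-value comparing that cell's residuals with the residuals of the
#' row's test cohort under its own (diagonal) model; diagonal cells report
#' p = 1 by the self-comparison convention.
#'
#' @param models nested list `models[[architecture]][[cohort]]` of trained
#'   models for one horizon.
#' @param test_sets list per cohort: `list(windows = <window_set>,
#'   params = <norm_params>)`.
#' @param residual_stride subsampling stride applied to residual vectors
#'   before the KS comparison (see [residuals_of()]).
#' @return an object of class `generalization_matrix`: a long-format data
#'   frame with columns `arch`, `train_cohort`, `test_cohort`, `horizon`,
#'   `rmse`, `ks_p`, `diagonal`.
#' @export
cross_evaluate <- function(models, test_sets, residual_stride = 1L) {
  cohorts <- names(test_sets)
  rows <- list()
  for (arch in names(models)) {
    # diagonal residuals first: the reference distribution per test cohort
    diag_res <- list()
    for (co in cohorts) {
      mdl <- models[[arch]][[co]]
      ts <- test_sets[[co]]
      if (is.null(mdl) || is.null(ts)) {
        stop(sprintf("missing model or test set for cell (%s, %s)", arch, co))
      }
      ps <- predict(mdl, ts$windows, ts$params)
      diag_res[[co]] <- list(ps = ps,
                             res = residuals_of(ps, residual_stride))
    }
    for (train_co in cohorts) {
      for (test_co in cohorts) {
        if (train_co == test_co) {
          ps <- diag_res[[test_co]]$ps
          ksp <- 1
        } else {
          ts <- test_sets[[test_co]]
          ps <- predict(models[[arch]][[train_co]], ts$windows, ts$params)
          ksp <- ks_two_sample(residuals_of(ps, residual_stride),
                               diag_res[[test_co]]$res)$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          arch = arch, train_cohort = train_co, test_cohort = test_co,
          horizon = ps$context$horizon %||% NA_integer_,
          rmse = evaluate_metrics(ps)$rmse, ks_p = ksp,
          diagonal = train_co == test_co, stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("generalization_matrix",
                                            "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pivot a generalization matrix into a train-by-test table
#'
#' @param gm a [cross_evaluate()] result.
#' @param arch architecture to display.
#' @return matrix of `"RMSE (p)"` strings, test cohorts in rows and train
#'   cohorts in columns.
#' @export
pivot_generalization <- function(gm, arch) {
  g <- gm[gm$arch == arch, ]
  cohorts <- unique(g$test_cohort)
  out <- matrix("", length(cohorts), length(cohorts),
                dimnames = list(test = cohorts, train = cohorts))
  for (i in seq_len(nrow(g))) {
    out[g$test_cohort[i], g$train_cohort[i]] <-
      sprintf("%.2f (%.3g)", g$rmse[i], g$ks_p[i])
  }
  out
}

#' Demographic-slice evaluation of a prediction set
#'
#' Splits a labeled prediction set into the full set (FM), the female
#' subset (F) and the male subset (M), reporting the RMSE of each and the
#' pairwise KS p-values between the three residual sets. A slice with
#' fewer than 2 windows is flagged and not computed.
#'
#' @param ps a [prediction_set()] with per-window `sex` labels.
#' @param residual_stride see [residuals_of()].
#' @return list with `rmse` (named FM/F/M), `ks_p` (named `FM_vs_F`,
#'   `FM_vs_M`, `F_vs_M`), `n` (named counts) and `flagged` (character
#'   vector of slices too small to evaluate).
#' @export
demographic_slices <- function(ps, residual_stride = 1L) {
  if (is.null(ps$sex)) stop("prediction set has no sex labels")
  sub_ps <- function(keep) {
    prediction_set(ps$refs[keep], ps$preds[keep], ps$context)
  }
  slices <- list(FM = rep(TRUE, ps$N), F = ps$sex == "F", M = ps$sex == "M")
  n <- vapply(slices, sum, 0L)
  flagged <- names(n)[n < 2L]
  rmse <- vapply(names(slices), function(k) {
    if (n[k] < 2L) return(NA_real_)
    sqrt(mean((ps$refs[slices[[k]]] - ps$preds[slices[[k]]])^2))
  }, 0)
  res <- lapply(names(slices), function(k) {
    if (n[k] < 2L) return(NULL)
    residuals_of(sub_ps(slices[[k]]), residual_stride)
  })
  names(res) <- names(slices)
  pairs <- list(FM_vs_F = c("FM", "F"), FM_vs_M = c("FM", "M"),
                F_vs_M = c("F", "M"))
  ks_p <- vapply(pairs, function(pr) {
    if (is.null(res[[pr[1L]]]) || is.null(res[[pr[2L]]])) return(NA_real_)
    ks_two_sample(res[[pr[1L]]], res[[pr[2L]]])$p.value
  }, 0)
  list(rmse = rmse, ks_p = ks_p, n = n, flagged = flagged)
}
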