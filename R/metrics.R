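#' Analytical forecast accuracy metrics
#'
#' Computes the five standard glucose-forecasting accuracy measures for a
#' prediction set with reference values \eqn{G_i} and predictions
#' \eqn{\hat G_i}:
#' \itemize{
#'   \item RMSE \eqn{= \sqrt{\sum (G_i - \hat G_i)^2 / N}} (mg/dL)
#'   \item COD (coefficient of determination)
#'     \eqn{= 1 - \sum (G_i - \hat G_i)^2 / \sum (G_i - \bar G)^2}
#'   \item MAD \eqn{= \sum |G_i - \hat G_i| / N} (mg/dL)
#'   \item FIT \eqn{= (1 - RMSE / \sqrt{\sum (G_i - \bar G)^2 / N}) \times 100}
#'     (percent improvement over predicting the mean)
#'   \item MADP \eqn{= (\sum |G_i - \hat G_i| / G_i) / N \times 100} (percent)
#' }
#' COD and FIT are undefined (returned as `NA` with a warning) when the
#' references are constant; MADP requires strictly positive references.
#'
#' @param ps a [prediction_set()] with `N >= 2`.
#' @return an object of class `metric_report`: list with `rmse`, `mad`,
#'   `cod`, `fit`, `madp`.
#' @export
#' @examples
#' ps <- prediction_set(c(100, 150, 200), c(110, 140, 210))
#' unlist(evaluate_metrics(ps))
evaluate_metrics <- function(ps) {
  g <- ps$refs; gh <- ps$preds
  if (ps$N < 2L) stop("need at least 2 prediction pairs")
  if (any(g <= 0)) stop("MADP requires strictly positive reference values")
  sse <- sum((g - gh)^2)
  rmse <- sqrt(sse / ps$N)
  mad <- mean(abs(g - gh))
  sst <- sum((g - mean(g))^2)
  if (sst == 0) {
    warning("constant reference values: COD and FIT undefined")
    cod <- NA_real_; fit <- NA_real_
  } else {
    cod <- 1 - sse / sst
    fit <- (1 - rmse / sqrt(sst / ps$N)) * 100
  }
  madp <- mean(abs(g - gh) / g) * 100
  structure(list(rmse = rmse, mad = mad, cod = cod, fit = fit, madp = madp),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("RMSE %.4f mg/dL | MAD %.4f mg/dL | COD %.4f | FIT %.4f%% | MADP %.4f%%\n",
              x$rmse, x$mad, x$cod, x$fit, x$madp))
  invisible(x)
}

#' Clarke Error Grid zone of a (reference, prediction) pair
#'
#' Classifies reference/predicted glucose pairs into the five canonical
#' Clarke Error Grid zones. Zone A holds predictions within 20% of the
#' reference (or both values in the hypoglycemic range below 70 mg/dL);
#' zone E holds opposite-treatment errors (hypo read as hyper or vice
#' versa); zones C and D hold overcorrection and failure-to-detect errors;
#' everything else is the benign zone B. Points exactly on a boundary are
#' resolved by the fixed evaluation order A, E, C, D, B.
#'
#' @param ref,pred numeric vectors of glucose values in `(0, 400]` mg/dL,
#'   recycled to a common length.
#' @return character vector of zones `"A"`-`"E"`.
#' @export
#' @examples
#' clarke_zone(c(200, 50, 250, 150), c(200, 250, 120, 265))
clarke_zone <- function(ref, pred) {
  n <- max(length(ref), length(pred))
  ref <- rep_len(as.numeric(ref), n)
  pred <- rep_len(as.numeric(pred), n)
  if (any(ref <= 0 | ref > 400 | pred <= 0 | pred > 400)) {
    stop("glucose values must lie in (0, 400] mg/dL")
  }
  zone <- character(n)
  inA <- abs(pred - ref) <= 0.2 * ref | (ref <= 70 & pred <= 70)
  inE <- (ref >= 180 & pred <= 70) | (ref <= 70 & pred >= 180)
  inC <- (ref >= 70 & ref <= 290 & pred >= ref + 110) |
    (ref >= 130 & ref <= 180 & pred <= (7 / 5) * ref - 182)
  inD <- (ref >= 240 & pred >= 70 & pred <= 180) |
    (ref <= 175 / 3 & pred >= 70 & pred <= 180) |
    (ref >= 175 / 3 & ref <= 70 & pred >= (6 / 5) * ref)
  zone[] <- "B"
  zone[inD] <- "D"
  zone[inC] <- "C"
  zone[inE] <- "E"
  zone[inA] <- "A"
  zone
}

#' Clarke Error Grid analysis of a prediction set
#'
#' Tallies zones over all pairs and reports percentages, plus the merged
#' clinically safe (A+B) and unsafe (C+D+E) fractions.
#'
#' @param ps a [prediction_set()].
#' @param clamp if `TRUE`, project predictions onto the sensor reporting
#'   range `[40, 400]` mg/dL before classification (model output is
#'   unbounded; the grid is defined on sensor-range values).
#' @return an object of class `ceg_result`: `counts`, `percent` (named
#'   A-E), `safe_percent` (A+B) and `unsafe_percent` (C+D+E).
#' @export
ceg_analysis <- function(ps, clamp = FALSE) {
  if (ps$N < 1L) stop("empty prediction set")
  pred <- ps$preds
  if (clamp) pred <- pmin(pmax(pred, 40), 400)
  z <- clarke_zone(ps$refs, pred)
  counts <- vapply(c("A", "B", "C", "D", "E"), function(k) sum(z == k), 0L)
  pct <- 100 * counts / ps$N
  structure(list(counts = counts, percent = pct,
                 safe_percent = sum(pct[c("A", "B")]),
                 unsafe_percent = sum(pct[c("C", "D", "E")]),
                 N = ps$N, context = ps$context),
            class = "ceg_result")
}

#' @export
print.ceg_result <- function(x, ...) {
  cat(sprintf("CEG: A %.2f%% B %.2f%% C %.2f%% D %.2f%% E %.2f%% | safe (A+B) %.2f%%\n",
              x$percent["A"], x$percent["B"], x$percent["C"],
              x$percent["D"], x$percent["E"], x$safe_percent))
  invisible(x)
}
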