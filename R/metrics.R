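#' Root-mean-square error between measured and predicted values
#'
#' @param t Measured values.
#' @param y Predicted values (same length).
#' @return `sqrt(mean((t - y)^2))`.
#' @export
rmse <- function(t, y) {
  check_paired(t, y)
  sqrt(mean((t - y)^2))
}

#' Mean absolute error
#'
#' @inheritParams rmse
#' @return `mean(abs(t - y))`.
#' @export
mae <- function(t, y) {
  check_paired(t, y)
  mean(abs(t - y))
}

#' Pearson correlation between measured and predicted values
#'
#' @inheritParams rmse
#' @return Sample correlation in \[-1, 1\]. Errors on constant input, where
#'   the correlation is undefined.
#' @export
pearson_r <- function(t, y) {
  check_paired(t, y)
  if (length(t) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(t) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(t, y)
}

#' Residual standard deviation of the measured-on-predicted regression
#'
#' Least-squares fit `t ~ a*y + b`; the reported deviation is
#' `sqrt(sum(residuals^2) / (n - 1))`.
#'
#' @inheritParams rmse
#' @return List with `sd`, slope `a` and intercept `b`.
#' @export
regression_sd <- function(t, y) {
  check_paired(t, y)
  n <- length(t)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(y) == 0) stop("regression undefined for constant predictions", call. = FALSE)
  fit <- stats::lm.fit(cbind(y = y, intercept = 1), t)
  list(sd = sqrt(sum(fit$residuals^2) / (n - 1)),
       a = unname(fit$coefficients["y"]),
       b = unname(fit$coefficients["intercept"]))
}

#' Classification accuracy of thresholded scores against binary labels
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold; `score >= threshold` predicts 1.
#'   Default 0.5.
#' @return Fraction of correct predictions.
#' @export
accuracy <- function(scores, labels, threshold = 0.5) {
  check_paired(scores, labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)", call. = FALSE)
  mean((scores >= threshold) == (labels == 1))
}

check_paired <- function(a, b) {
  if (length(a) != length(b)) stop("input vectors differ in length", call. = FALSE)
  if (length(a) == 0L) stop("empty input", call. = FALSE)
  invisible(NULL)
}

#' Full evaluation report for predicted affinities or scores
#'
#' Bundles the package's evaluation quantities: RMSE, MAE, Pearson's R,
#' the regression residual deviation with its slope/intercept, and (when
#' binary labels are supplied) thresholded classification accuracy.
#'
#' @param data Data frame with measured and predicted columns.
#' @param truth,estimate Column names (strings) of measured and predicted
#'   values.
#' @param label Optional column name of binary labels for accuracy.
#' @param threshold Accuracy threshold, default 0.5.
#' @return A one-row `metrics_report` tibble: `n`, `rmse`, `mae`,
#'   `pearson_r`, `regression_sd`, `slope`, `intercept`, `accuracy` (NA
#'   without labels).
#' @export
metrics_report <- function(data, truth = "t", estimate = "y",
                           label = NULL, threshold = 0.5) {
  t <- data[[truth]]; y <- data[[estimate]]
  check_paired(t, y)
  reg <- tryCatch(regression_sd(t, y),
                  error = function(e) list(sd = NA_real_, a = NA_real_, b = NA_real_))
  r <- tryCatch(pearson_r(t, y), error = function(e) NA_real_)
  acc <- NA_real_
  if (!is.null(label)) acc <- accuracy(y, data[[label]], threshold)
  out <- tibble::tibble(n = length(t), rmse = rmse(t, y), mae = mae(t, y),
                        pearson_r = r, regression_sd = reg$sd,
                        slope = reg$a, intercept = reg$b, accuracy = acc)
  class(out) <- c("metrics_report", class(out))
  out
}

#' @export
glance.metrics_report <- function(x, ...) x
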