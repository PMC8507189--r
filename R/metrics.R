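#' Forecast error metrics
#'
#' Computes the standard point-forecast error suite:
#' MSE \eqn{= \frac{1}{N}\sum (y_t - \hat y_t)^2}, RMSE \eqn{= \sqrt{MSE}},
#' MAE \eqn{= \frac{1}{N}\sum |y_t - \hat y_t|} and MAPE
#' \eqn{= \frac{100}{N}\sum |(y_t - \hat y_t)/y_t|} (in percent), plus the
#' signed mean error as `bias`. If any true value is zero, MAPE is undefined
#' and reported as `NA` with a warning; the other metrics are still
#' computed.
#'
#' @param data Optional data frame in which `truth` and `estimate` are
#'   evaluated (e.g. a [lstm_forecast()] result with its `y_true`/`y_pred`
#'   columns); if omitted, `truth` and `estimate` are taken as vectors.
#' @param truth,estimate Columns or vectors of observed and predicted
#'   values.
#' @return One-row tibble: `n`, `mse`, `rmse`, `mae`, `mape`, `bias`.
#' @examples
#' forecast_metrics(truth = c(2, 4), estimate = c(1, 5))
#' @export
forecast_metrics <- function(data = NULL, truth = y_true,
                             estimate = y_pred) {
  y <- rlang::eval_tidy(rlang::enquo(truth), data)
  yhat <- rlang::eval_tidy(rlang::enquo(estimate), data)
  if (length(y) != length(yhat)) {
    stop("`truth` and `estimate` must have equal length", call. = FALSE)
  }
  keep <- !is.na(y) & !is.na(yhat)
  y <- y[keep]; yhat <- yhat[keep]
  if (length(y) < 1) stop("no complete observations", call. = FALSE)
  err <- y - yhat
  mse <- mean(err^2)
  mape <- if (any(y == 0)) {
    warning("MAPE undefined: `truth` contains zeros; reported as NA",
            call. = FALSE)
    NA_real_
  } else {
    100 * mean(abs(err / y))
  }
  tibble::tibble(n = length(y), mse = mse, rmse = sqrt(mse),
                 mae = mean(abs(err)), mape = mape, bias = mean(err))
}

#' Forecast residuals and normal QQ points
#'
#' `forecast_residuals()` returns the residual sequence `y - yhat`;
#' `qq_points()` pairs the ordered standardised residuals with standard
#' normal quantiles at plotting positions `(i - 0.5)/n`, the arrays behind a
#' residual normality (QQ) diagnostic plot.
#'
#' @inheritParams forecast_metrics
#' @return `forecast_residuals()`: a tibble with column `.resid` (plus `doy`
#'   when present in `data`); `qq_points()`: a tibble with `theoretical` and
#'   `sample` quantile columns.
#' @export
forecast_residuals <- function(data = NULL, truth = y_true,
                               estimate = y_pred) {
  y <- rlang::eval_tidy(rlang::enquo(truth), data)
  yhat <- rlang::eval_tidy(rlang::enquo(estimate), data)
  if (length(y) != length(yhat)) {
    stop("`truth` and `estimate` must have equal length", call. = FALSE)
  }
  out <- tibble::tibble(.resid = y - yhat)
  if (!is.null(data) && "doy" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(doy = data$doy), out)
  }
  out
}

#' @rdname forecast_residuals
#' @param resid Numeric vector of residuals (at least 3).
#' @export
qq_points <- function(resid) {
  resid <- resid[!is.na(resid)]
  n <- length(resid)
  if (n < 3) stop("need at least 3 residuals for a QQ diagnostic",
                  call. = FALSE)
  s <- stats::sd(resid)
  std <- if (s > 0) (resid - mean(resid)) / s else resid - mean(resid)
  tibble::tibble(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    sample = sort(std))
}
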