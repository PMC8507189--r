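#' Double-logistic seasonal model parameters
#'
#' Container for the parameters of the double-logistic greenness trajectory
#' \deqn{g(t) = w_{min} + (w_{max}-w_{min})\left[\frac{1}{1+e^{-m_S(t-S)}} +
#'   \frac{1}{1+e^{m_A(t-A)}} - 1\right]}
#' where `t` is day of year (DOY). `w_min` is the annual minimum (winter
#' baseline), `w_max` the annual maximum (summer plateau), `S` and `A` the
#' spring and autumn inflection days, and `mS`, `mA` the rise and fall rates
#' in 1/day.
#'
#' @param w_min Annual minimum of the index.
#' @param w_max Annual maximum; must exceed `w_min`.
#' @param S Spring inflection DOY; must be less than `A`.
#' @param A Autumn inflection DOY.
#' @param mS,mA Positive slopes (1/day) at the spring and autumn inflections.
#'
#' @return An object of class `dl_params`.
#' @examples
#' p <- dl_params(w_min = 10, w_max = 70, S = 87, A = 312, mS = 0.11, mA = 0.09)
#' double_logistic(c(1, 200, 365), p)
#' @export
dl_params <- function(w_min = 10, w_max = 70, S = 87, A = 312,
                      mS = 0.11, mA = 0.09) {
  stopifnot(is.numeric(w_min), is.numeric(w_max), is.numeric(S),
            is.numeric(A), is.numeric(mS), is.numeric(mA))
  if (!(w_max > w_min)) stop("`w_max` must exceed `w_min`", call. = FALSE)
  if (!(S < A)) stop("`S` must be earlier than `A`", call. = FALSE)
  if (!(mS > 0 && mA > 0)) stop("`mS` and `mA` must be positive", call. = FALSE)
  structure(list(w_min = w_min, w_max = w_max, S = S, A = A, mS = mS, mA = mA),
            class = "dl_params")
}

#' @export
print.dl_params <- function(x, ...) {
  cat("Double-logistic parameters\n")
  cat(sprintf("  w_min = %.4g, w_max = %.4g\n", x$w_min, x$w_max))
  cat(sprintf("  S = %.2f (mS = %.4g /day), A = %.2f (mA = %.4g /day)\n",
              x$S, x$mS, x$A, x$mA))
  invisible(x)
}

as_dl_params <- function(x) {
  if (inherits(x, "dl_params")) return(x)
  do.call(dl_params, as.list(x)[c("w_min", "w_max", "S", "A", "mS", "mA")])
}

#' Evaluate the double-logistic trajectory
#'
#' @param t Numeric vector of days of year (fractional values allowed).
#' @param params A [dl_params()] object.
#' @return Numeric vector `g(t)`, same length as `t`.
#' @export
double_logistic <- function(t, params) {
  p <- as_dl_params(params)
  u <- stats::plogis(p$mS * (t - p$S))   # rising sigmoid
  v <- stats::plogis(-p$mA * (t - p$A))  # falling sigmoid
  p$w_min + (p$w_max - p$w_min) * (u + v - 1)
}

# First three analytic derivatives of g(t). The logistic identities
# u' = mS u(1-u), u'' = mS^2 u(1-u)(1-2u), u''' = mS^3 u(1-u)(1-6u+6u^2)
# (and the mirrored forms for the falling sigmoid) keep these closed-form.
dl_derivatives <- function(t, params) {
  p <- as_dl_params(params)
  amp <- p$w_max - p$w_min
  u <- stats::plogis(p$mS * (t - p$S))
  v <- stats::plogis(-p$mA * (t - p$A))
  uu <- u * (1 - u)
  vv <- v * (1 - v)
  list(
    g1 = amp * (p$mS * uu - p$mA * vv),
    g2 = amp * (p$mS^2 * uu * (1 - 2 * u) + p$mA^2 * vv * (1 - 2 * v)),
    g3 = amp * (p$mS^3 * uu * (1 - 6 * u + 6 * u^2) -
                  p$mA^3 * vv * (1 - 6 * v + 6 * v^2))
  )
}

#' Curvature of the fitted seasonal curve
#'
#' Curvature \eqn{K(t) = |g''(t)| / (1 + g'(t)^2)^{3/2}} of the
#' double-logistic trajectory, from analytic derivatives. `signed = TRUE`
#' drops the absolute value, which is the form whose derivative defines the
#' curvature change rate.
#'
#' @param params A [dl_params()] object.
#' @param t Numeric vector of DOY.
#' @param signed If `TRUE` return the signed curvature \eqn{g''/(1+g'^2)^{3/2}}.
#' @return Numeric vector of curvatures.
#' @seealso [curvature_rate()], [extract_phenophases()]
#' @export
curvature <- function(params, t, signed = FALSE) {
  d <- dl_derivatives(t, params)
  k <- d$g2 / (1 + d$g1^2)^(3 / 2)
  if (signed) k else abs(k)
}

#' Curvature change rate of the fitted seasonal curve
#'
#' Analytic derivative \eqn{dK/dt} of the signed curvature. Its local extrema
#' bracket the spring and autumn inflections and mark the phenological
#' transition days (start of season, maturity onset, senescence onset, end of
#' season).
#'
#' @inheritParams curvature
#' @return Numeric vector, the signed rate of change of curvature.
#' @export
curvature_rate <- function(params, t) {
  d <- dl_derivatives(t, params)
  q <- 1 + d$g1^2
  (d$g3 * q - 3 * d$g1 * d$g2^2) / q^(5 / 2)
}
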