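#' Fit the double-logistic seasonal model to an index series
#'
#' Least-squares fit of the double-logistic trajectory (see [dl_params()])
#' to a daily colour-index series by Levenberg-Marquardt. Starting values are
#' derived from the data (5th/95th percentiles for the winter baseline and
#' summer plateau, half-amplitude crossings for the inflection days,
#' 0.1/day for both slopes) and the optimiser is restarted from a few
#' jittered starts under a fixed seed; the best converged fit by residual
#' sum of squares is kept.
#'
#' @param data Tibble with columns `doy` and `value` (e.g. one ROI x index
#'   slice of [compute_indices()] output). `NA` values are dropped; gaps in
#'   the DOY grid are accepted as-is.
#' @param init Optional [dl_params()] used as the starting point instead of
#'   the data-derived one.
#' @param n_restarts Number of jittered restarts around the starting point.
#' @param seed Seed for the restart jitter.
#' @return An object of class `pheno_fit`: list with `params`
#'   ([dl_params()]), `diagnostics` (tibble: `rmse`, `r_squared`, `n`),
#'   `data` (input with `.fitted` and `.resid`), and the underlying `nls`
#'   object. Supports [predict()][predict.pheno_fit],
#'   [tidy()][generics::tidy], [glance()][generics::glance],
#'   [augment()][generics::augment] and [autoplot()][ggplot2::autoplot].
#' @examples
#' ser <- simulate_index_series(dl_params(), noise_sd = 1.2, seed = 7)
#' fit <- fit_double_logistic(ser)
#' glance(fit)
#' @export
fit_double_logistic <- function(data, init = NULL, n_restarts = 5, seed = 1) {
  stopifnot(all(c("doy", "value") %in% names(data)))
  d <- data |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::arrange(.data$doy)
  if (nrow(d) < 6) {
    stop("need at least 6 non-missing points to fit", call. = FALSE)
  }

  start0 <- if (is.null(init)) dl_init_from_data(d) else unlist(
    as_dl_params(init)[c("w_min", "w_max", "S", "A", "mS", "mA")])

  starts <- list(start0)
  if (n_restarts > 1) {
    jit <- withr::with_seed(seed, {
      lapply(seq_len(n_restarts - 1), function(i) {
        s <- start0
        s["S"] <- s["S"] + stats::runif(1, -10, 10)
        s["A"] <- s["A"] + stats::runif(1, -10, 10)
        s["mS"] <- s["mS"] * exp(stats::runif(1, -0.7, 0.7))
        s["mA"] <- s["mA"] * exp(stats::runif(1, -0.7, 0.7))
        s
      })
    })
    starts <- c(starts, jit)
  }

  lower <- c(w_min = -Inf, w_max = -Inf,
             S = min(d$doy) - 60, A = min(d$doy) - 60,
             mS = 1e-4, mA = 1e-4)
  upper <- c(w_min = Inf, w_max = Inf,
             S = max(d$doy) + 60, A = max(d$doy) + 60, mS = 5, mA = 5)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ w_min + (w_max - w_min) *
          (plogis(mS * (doy - S)) + plogis(-mA * (doy - A)) - 1),
        data = d, start = as.list(s),
        lower = lower[names(s)], upper = upper[names(s)],
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best))) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("double-logistic fit failed to converge from any start",
         call. = FALSE)
  }

  cf <- stats::coef(best)
  if (!(cf["w_max"] > cf["w_min"]) || !(cf["S"] < cf["A"])) {
    stop("fit converged to a non-seasonal solution ",
         "(no rise-then-fall shape in the data?)", call. = FALSE)
  }
  params <- dl_params(w_min = unname(cf["w_min"]), w_max = unname(cf["w_max"]),
                      S = unname(cf["S"]), A = unname(cf["A"]),
                      mS = unname(cf["mS"]), mA = unname(cf["mA"]))
  fitted_vals <- double_logistic(d$doy, params)
  resid <- d$value - fitted_vals
  sse <- sum(resid^2)
  sst <- sum((d$value - mean(d$value))^2)
  diagnostics <- tibble::tibble(
    rmse = sqrt(sse / nrow(d)),
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
    n = nrow(d))

  structure(list(params = params, diagnostics = diagnostics,
                 data = d |> dplyr::mutate(.fitted = fitted_vals,
                                           .resid = resid),
                 fit = best),
            class = "pheno_fit")
}

# Starting values: percentile baseline/plateau, half-amplitude crossings for
# the inflections. Errors out when the series has no rise-and-fall signal.
dl_init_from_data <- function(d) {
  q <- stats::quantile(d$value, c(0.05, 0.95), names = FALSE)
  amp <- q[2] - q[1]
  if (amp <= 1e-8 * max(1, abs(q[2]))) {
    stop("series is flat: no seasonal signal to fit", call. = FALSE)
  }
  half <- (q[1] + q[2]) / 2
  above <- d$value > half
  if (!any(above) || all(above)) {
    stop("series never crosses half amplitude: no seasonal signal to fit",
         call. = FALSE)
  }
  s0 <- d$doy[which(above)[1]]
  a0 <- d$doy[rev(which(above))[1]]
  if (!(s0 < a0)) {
    stop("series has no rise-then-fall shape", call. = FALSE)
  }
  c(w_min = q[1], w_max = q[2], S = s0, A = a0, mS = 0.1, mA = 0.1)
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat("Double-logistic seasonal fit\n")
  print(x$params)
  cat(sprintf("  RMSE = %.4g, R^2 = %.4f, n = %d\n",
              x$diagnostics$rmse, x$diagnostics$r_squared,
              x$diagnostics$n))
  invisible(x)
}

#' Predict from a double-logistic fit
#'
#' @param object A `pheno_fit`.
#' @param newdata Optional tibble with a `doy` column (defaults to the
#'   training days).
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.pheno_fit <- function(object, newdata = NULL, ...) {
  doy <- if (is.null(newdata)) object$data$doy else newdata$doy
  double_logistic(doy, object$params)
}

#' @importFrom generics tidy
#' @method tidy pheno_fit
#' @export
tidy.pheno_fit <- function(x, ...) {
  su <- tryCatch(summary(x$fit)$coefficients, error = function(e) NULL)
  out <- tibble::tibble(
    term = c("w_min", "w_max", "S", "A", "mS", "mA"),
    estimate = unlist(x$params[c("w_min", "w_max", "S", "A", "mS", "mA")],
                      use.names = FALSE))
  if (!is.null(su)) {
    out$std.error <- su[out$term, "Std. Error"]
  }
  out
}

#' @importFrom generics glance
#' @method glance pheno_fit
#' @export
glance.pheno_fit <- function(x, ...) {
  x$diagnostics
}

#' @importFrom generics augment
#' @method augment pheno_fit
#' @export
augment.pheno_fit <- function(x, ...) {
  x$data
}

#' @importFrom ggplot2 autoplot
#' @method autoplot pheno_fit
#' @export
autoplot.pheno_fit <- function(object, dates = NULL, ...) {
  grid <- tibble::tibble(
    doy = seq(min(object$data$doy), max(object$data$doy), by = 0.25))
  grid$value <- double_logistic(grid$doy, object$params)
  p <- ggplot2::ggplot(object$data, ggplot2::aes(.data$doy, .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "forestgreen",
                       linewidth = 0.9) +
    ggplot2::labs(x = "Day of year", y = "Index value",
                  title = "Double-logistic seasonal fit")
  if (!is.null(dates)) {
    vl <- tidyr::pivot_longer(dates[, c("sos", "moe", "cos", "eos")],
                              dplyr::everything(),
                              names_to = "phase", values_to = "doy")
    p <- p + ggplot2::geom_vline(data = vl,
                                 ggplot2::aes(xintercept = .data$doy),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Smoothing-spline pass over an index series
#'
#' Cubic smoothing spline with a roughness parameter `p` in `(0, 1]` on the
#' csaps convention: the spline minimises
#' `p * sum((y - f)^2) + (1 - p) * integral(f'')^2`, so `p = 1` interpolates
#' the data and `p -> 0` approaches the least-squares straight line. Used as
#' an optional pre-step before the double-logistic fit when the raw daily
#' series is ragged.
#'
#' @param series Tibble with `doy` and `value` columns (other columns are
#'   carried through).
#' @param p Roughness parameter in `(0, 1]`.
#' @return `series` with `value` replaced by the smoothed values.
#' @export
smooth_series <- function(series, p) {
  stopifnot(all(c("doy", "value") %in% names(series)))
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stop("`p` must be a single value in (0, 1]", call. = FALSE)
  }
  ok <- !is.na(series$value)
  if (sum(ok) < 4) stop("need at least 4 points to smooth", call. = FALSE)
  out <- series
  if (p == 1) return(out)   # interpolation limit: the data are their own fit
  # smooth.spline penalises on x rescaled to [0, 1]; divide by the cubed day
  # range so p keeps its csaps meaning in day units
  span <- diff(range(series$doy[ok]))
  lambda <- (1 - p) / p / span^3
  sp <- stats::smooth.spline(series$doy[ok], series$value[ok],
                             lambda = lambda, all.knots = TRUE,
                             keep.data = FALSE)
  out$value[ok] <- stats::predict(sp, series$doy[ok])$y
  out
}

#' Phenological transition dates from the curvature change rate
#'
#' Evaluates the curvature change rate of a fitted (or true) double-logistic
#' trajectory on a fine DOY grid and takes its local extrema as the
#' transition days: in the spring half (before the midpoint of the two
#' inflections) the first extremum is the start of season (SOS) and the last
#' is the maturity onset (MOE, "time point of exuberance"); in the autumn
#' half the first extremum is the senescence onset (COS) and the last the
#' end of season (EOS). The growth-stage length LOS is `MOE - SOS`.
#'
#' @param object A [dl_params()] or a `pheno_fit`.
#' @param step Grid spacing in days (default 0.1).
#' @param doys Optional length-2 numeric giving the grid range; defaults to
#'   `[S - 12/mS, A + 12/mA]`, which covers all extrema.
#' @return One-row tibble: `sos`, `moe`, `cos`, `eos` (integer DOY) and
#'   `los` (days).
#' @examples
#' extract_phenophases(dl_params(S = 87, A = 312, mS = 0.11, mA = 0.09))
#' @export
extract_phenophases <- function(object, step = 0.1, doys = NULL) {
  params <- if (inherits(object, "pheno_fit")) object$params else
    as_dl_params(object)
  if (is.null(doys)) {
    doys <- c(params$S - 12 / params$mS, params$A + 12 / params$mA)
  }
  grid <- seq(doys[1], doys[2], by = step)
  r <- curvature_rate(params, grid)

  ext <- local_extrema(r)
  # discard numerically-flat plateau wiggles
  mid <- (params$S + params$A) / 2
  spring <- ext[grid[ext] < mid]
  autumn <- ext[grid[ext] >= mid]
  spring <- spring[abs(r[spring]) > 1e-6 * max(abs(r[grid < mid]))]
  autumn <- autumn[abs(r[autumn]) > 1e-6 * max(abs(r[grid >= mid]))]
  if (length(spring) < 2 || length(autumn) < 2) {
    stop("fewer than four curvature-change-rate extrema found; ",
         "cannot place transition dates", call. = FALSE)
  }
  sos <- round(grid[spring[1]])
  moe <- round(grid[rev(spring)[1]])
  cos_ <- round(grid[autumn[1]])
  eos <- round(grid[rev(autumn)[1]])
  tibble::tibble(sos = as.integer(sos), moe = as.integer(moe),
                 cos = as.integer(cos_), eos = as.integer(eos),
                 los = as.integer(moe - sos))
}

# Indices of strict local extrema of a sampled curve; flat runs inherit the
# preceding slope sign so plateaus do not spawn spurious extrema.
local_extrema <- function(x) {
  s <- sign(diff(x))
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  filled <- s
  last <- 0
  for (i in seq_along(filled)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  which(diff(filled) != 0) + 1L
}
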