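test_that("the double logistic saturates at the baseline and plateau", {
  p <- gei_params()
  expect_equal(double_logistic(-1e6, p), p$w_min, tolerance = 1e-12)
  expect_equal(double_logistic(1e6, p), p$w_min, tolerance = 1e-12)
  # at the spring inflection, far from autumn, g is at half amplitude
  expect_lt(abs(double_logistic(p$S, p) -
                  (p$w_min + (p$w_max - p$w_min) / 2)), 1e-6)
  # mid-season plateau (relative to the 60-unit amplitude)
  expect_lt(abs(double_logistic(200, p) - p$w_max) / (p$w_max - p$w_min),
            1e-4)
})

test_that("analytic curvature matches a finite-difference oracle", {
  p <- gei_params()
  grid <- seq(p$S - 40, p$A + 40, length.out = 500)
  h <- 2e-3
  g <- function(t) double_logistic(t, p)
  g1 <- (g(grid + h) - g(grid - h)) / (2 * h)
  g2 <- (g(grid + h) - 2 * g(grid) + g(grid - h)) / h^2
  k_fd <- g2 / (1 + g1^2)^(3 / 2)
  k <- curvature(p, grid, signed = TRUE)
  expect_lt(max(abs(k - k_fd)) / max(abs(k)), 1e-6)
  expect_true(all(curvature(p, grid) >= 0))
  expect_equal(curvature(p, grid), abs(k))
  # plateau: both sigmoids saturated, curvature negligible vs its peak
  expect_lt(curvature(p, 200) / max(k_fd), 1e-3)
})

test_that("curvature change rate matches differencing the curvature", {
  p <- gcc_params()
  grid <- seq(p$S - 40, p$A + 40, length.out = 300)
  h <- 2e-3
  r_fd <- (curvature(p, grid + h, signed = TRUE) -
             curvature(p, grid - h, signed = TRUE)) / (2 * h)
  r <- curvature_rate(p, grid)
  expect_lt(max(abs(r - r_fd)) / max(abs(r)), 1e-6)
  expect_lt(abs(curvature_rate(p, 200)) / max(abs(r)), 1e-3)  # plateau
})

test_that("for a single logistic the signed curvature is antisymmetric and
           its rate mirror-symmetric about the inflection", {
  p <- dl_params(0, 1, S = 100, A = 500, mS = 0.1, mA = 0.1)
  d <- seq(0.5, 40, by = 0.5)
  k_plus <- curvature(p, 100 + d, signed = TRUE)
  k_minus <- curvature(p, 100 - d, signed = TRUE)
  expect_equal(k_plus, -k_minus, tolerance = 1e-9)
  r_plus <- curvature_rate(p, 100 + d)
  r_minus <- curvature_rate(p, 100 - d)
  expect_equal(r_plus, r_minus, tolerance = 1e-9)
})

test_that("noiseless parameter recovery is exact to optimizer precision", {
  p <- gei_params()
  ser <- simulate_index_series(p, noise_sd = 0)
  fit <- fit_double_logistic(ser)
  est <- fit$params
  for (nm in c("w_min", "w_max", "S", "A", "mS", "mA")) {
    expect_lt(abs(est[[nm]] - p[[nm]]) / abs(p[[nm]]), 1e-4)
  }
  expect_lt(glance(fit)$rmse, 1e-6)
  expect_gt(glance(fit)$r_squared, 1 - 1e-10)
})

test_that("broom-style accessors expose the fit", {
  ser <- simulate_index_series(gei_params(), noise_sd = 1.2, seed = 3)
  fit <- fit_double_logistic(ser)
  td <- tidy(fit)
  expect_equal(td$term, c("w_min", "w_max", "S", "A", "mS", "mA"))
  expect_true(all(c("rmse", "r_squared", "n") %in% names(glance(fit))))
  au <- augment(fit)
  expect_true(all(c(".fitted", ".resid") %in% names(au)))
  expect_equal(au$.resid, au$value - au$.fitted)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(predict(fit, tibble::tibble(doy = 200)),
               double_logistic(200, fit$params))
})

test_that("degenerate series are rejected with informative errors", {
  flat <- tibble::tibble(doy = 1:50, value = 5)
  expect_error(fit_double_logistic(flat), "flat")
  short <- tibble::tibble(doy = 1:5, value = rnorm(5))
  expect_error(fit_double_logistic(short), "at least 6")
  tiny <- tibble::tibble(doy = 1:50, value = 5 + 1e-12 * (1:50))
  expect_error(fit_double_logistic(tiny), "flat")
})

test_that("transition dates bracket the inflections and are grid-stable", {
  for (p in list(gei_params(), gcc_params())) {
    ph <- extract_phenophases(p)
    expect_lt(ph$sos, p$S); expect_gt(ph$moe, p$S)
    expect_lt(ph$cos, p$A); expect_gt(ph$eos, p$A)
    expect_true(ph$sos < ph$moe && ph$moe <= ph$cos && ph$cos < ph$eos)
    expect_equal(ph$los, ph$moe - ph$sos)
    coarse <- extract_phenophases(p, step = 1.0)
    for (nm in c("sos", "moe", "cos", "eos")) {
      expect_lte(abs(ph[[nm]] - coarse[[nm]]), 1)
    }
  }
})

test_that("extraction converges to the analytic dates as noise vanishes", {
  p <- gei_params()
  truth <- extract_phenophases(p)
  for (sd in c(0.6, 0.06)) {
    ser <- simulate_index_series(p, noise_sd = sd, seed = 5)
    ph <- extract_phenophases(fit_double_logistic(ser))
    expect_lte(max(abs(unlist(ph - truth))), if (sd > 0.1) 3 else 1)
  }
})

test_that("smoothing spline has the csaps limits", {
  withr::with_seed(2, {
    ser <- tibble::tibble(doy = 1:40,
                          value = sin(1:40 / 6) + rnorm(40, 0, 0.2))
  })
  interp <- smooth_series(ser, p = 1)
  expect_lt(max(abs(interp$value - ser$value)), 1e-6)

  line <- smooth_series(ser, p = 1e-12)
  lmfit <- stats::lm(value ~ doy, data = ser)
  expect_lt(max(abs(line$value - stats::fitted(lmfit))), 1e-3)

  expect_error(smooth_series(ser, p = 0), "\\(0, 1\\]")
  expect_error(smooth_series(ser, p = 1.5), "\\(0, 1\\]")
  expect_error(smooth_series(ser[1:3, ], p = 0.5), "at least 4")
})

test_that("smoothing a noisy series brings it closer to the truth", {
  p <- gei_params()
  ser <- simulate_index_series(p, noise_sd = 2, seed = 9)
  sm <- smooth_series(ser, p = 0.05)
  rmse_raw <- sqrt(mean((ser$value - ser$truth)^2))
  rmse_sm <- sqrt(mean((sm$value - ser$truth)^2))
  expect_lt(rmse_sm, rmse_raw)
})
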