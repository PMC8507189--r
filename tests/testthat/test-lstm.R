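test_that("min-max normalisation scales, round-trips and extrapolates", {
  n <- normalize_minmax(c(0.1, 0.2, 0.3))
  expect_equal(n$values, c(0, 0.5, 1))
  expect_equal(denormalize(n$values, n$record), c(0.1, 0.2, 0.3),
               tolerance = 1e-12)
  expect_equal(denormalize(1.5, n$record), 0.4)   # linear, no clipping
  expect_error(normalize_minmax(rep(2, 5)), "constant")
})

test_that("sliding windows count and order correctly", {
  w <- make_windows(seq_len(100), window = 30)
  expect_equal(nrow(w$x), 70)
  w2 <- make_windows(1:5, window = 2)
  expect_equal(w2$x, rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(w2$y, c(3, 4, 5))
  expect_error(make_windows(1:5, window = 5), "exceed")
})

test_that("windows never span a gap in the day axis", {
  doys <- c(1:10, 20:29)
  w <- make_windows(seq_along(doys), window = 5, doys = doys)
  expect_equal(nrow(w$x), 10)   # 5 windows per 10-day run
  expect_true(all(w$target_doy %in% c(6:10, 25:29)))
  # every window row is consecutive values from one run
  expect_true(all(apply(w$x, 1, function(r) all(diff(r) == 1))))
})

test_that("the zero-weight cell halves the state exactly", {
  w <- zero_lstm_weights(hidden = 3, input = 1)
  out <- lstm_cell_forward(0.7, h_prev = rep(0, 3), c_prev = c(1, -2, 0.5), w)
  expect_equal(out$f, rep(0.5, 3))
  expect_equal(out$i, rep(0.5, 3))
  expect_equal(out$o, rep(0.5, 3))
  expect_equal(out$cbar, rep(0, 3))
  expect_equal(out$c, 0.5 * c(1, -2, 0.5))
  expect_equal(out$h, 0.5 * tanh(0.5 * c(1, -2, 0.5)))
})

test_that("with zero cell state the update is independent of the forgetting gate", {
  w1 <- random_lstm_weights(hidden = 4, input = 1, seed = 1)
  w2 <- w1
  w2$W_f <- w2$W_f * -3; w2$b_f <- w2$b_f + 1   # change only the f gate
  h0 <- rnorm(4); x <- 0.3
  a <- lstm_cell_forward(x, h0, rep(0, 4), w1)
  b <- lstm_cell_forward(x, h0, rep(0, 4), w2)
  expect_equal(a$c, b$c, tolerance = 1e-12)
  expect_equal(a$c, a$i * a$cbar, tolerance = 1e-12)
})

test_that("the cell matches an independent scalar-loop evaluation", {
  w <- random_lstm_weights(hidden = 5, input = 1, seed = 42)
  withr::with_seed(43, {
    h0 <- rnorm(5); c0 <- rnorm(5); x <- rnorm(1)
  })
  ours <- lstm_cell_forward(x, h0, c0, w)
  ref <- reference_lstm_cell(x, h0, c0, w)
  expect_equal(ours$h, ref$h, tolerance = 1e-10)
  expect_equal(ours$c, ref$c, tolerance = 1e-10)
})

test_that("gate activations stay in their ranges", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      w <- random_lstm_weights(hidden = 4, input = 1, seed = rep)
      out <- lstm_cell_forward(rnorm(1, sd = 3), rnorm(4, sd = 2),
                               rnorm(4, sd = 2), w)
      expect_true(all(out$f > 0 & out$f < 1))
      expect_true(all(out$i > 0 & out$i < 1))
      expect_true(all(out$o > 0 & out$o < 1))
      expect_true(all(out$cbar > -1 & out$cbar < 1))
      expect_true(all(tanh(out$c) > -1 & tanh(out$c) < 1))
    }
  })
})

test_that("mismatched weight shapes are rejected", {
  w <- zero_lstm_weights(hidden = 3, input = 1)
  expect_error(lstm_cell_forward(c(0.1, 0.2), rep(0, 3), rep(0, 3), w),
               "inconsistent")
})

test_that("training is deterministic under a fixed seed", {
  ser <- simulate_index_series(gei_params(), noise_sd = 0)
  cfg <- lstm_config(epochs = 3, hidden = 4, seed = 11)
  m1 <- lstm_train(ser, cfg)
  m2 <- lstm_train(ser, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  m3 <- lstm_train(ser, lstm_config(epochs = 3, hidden = 4, seed = 12))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("training loss decreases on a clean trend series (R batch path)", {
  ser <- tibble::tibble(doy = 1:120, value = seq(0, 10, length.out = 120))
  m <- lstm_train(ser, lstm_config(window = 10, hidden = 4, epochs = 60,
                                   batch_size = 8, seed = 2))
  expect_lt(mean(utils::tail(m$history$loss, 5)),
            mean(utils::head(m$history$loss, 5)))
  expect_s3_class(autoplot(m), "ggplot")
  g <- glance(m)
  expect_equal(g$depth, 2)
  expect_gt(g$n_train, 0)
})

test_that("forecast modes have the right shape and agree at the first step", {
  ser <- simulate_index_series(gei_params(), noise_sd = 0)
  m <- lstm_train(ser, lstm_config(window = 10, hidden = 4, epochs = 10,
                                   seed = 3))
  rec <- lstm_forecast(m, "recursive", horizon = 60)
  expect_equal(nrow(rec), 60)
  expect_true(all(is.na(rec$y_true)))
  expect_equal(rec$doy, max(ser$doy) + 1:60)

  one <- lstm_forecast(m, "onestep", set = "test")
  expect_equal(nrow(one), length(m$split$test))
  expect_false(any(is.na(one$y_true)))

  # recursive step 1 equals a manual forward pass with the exported cell
  scaled <- (m$series$value - m$record$min) / m$record$range
  buf <- utils::tail(scaled, m$config$window)
  h1 <- rep(0, 4); c1 <- rep(0, 4); h2 <- rep(0, 4); c2 <- rep(0, 4)
  for (t in seq_along(buf)) {
    s1 <- lstm_cell_forward(buf[t], h1, c1, m$weights$layers[[1]])
    h1 <- s1$h; c1 <- s1$c
    s2 <- lstm_cell_forward(h1, h2, c2, m$weights$layers[[2]])
    h2 <- s2$h; c2 <- s2$c
  }
  manual <- denormalize(sum(h2 * m$weights$w_out) +
                          m$weights$w_skip * buf[length(buf)] +
                          m$weights$b_out, m$record)
  expect_equal(rec$y_pred[1], manual, tolerance = 1e-10)

  expect_error(lstm_forecast(m, "recursive", horizon = 0), "positive")
})

test_that("too-short series are rejected at the split stage", {
  ser <- tibble::tibble(doy = 1:34, value = sin(1:34))
  expect_error(lstm_train(ser, lstm_config(window = 30, epochs = 1)),
               "split partition")
})
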