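#' Min-max normalisation with an invertible scale record
#'
#' Scales a series to `[0, 1]` and keeps the scale record so predictions can
#' be mapped back; values outside the training range extrapolate linearly
#' (no clipping).
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return List with `values` (scaled) and `record` (list `min`, `range`).
#' @export
normalize_minmax <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[1] == r[2]) {
    stop("cannot min-max normalise a constant series", call. = FALSE)
  }
  list(values = (x - r[1]) / (r[2] - r[1]),
       record = list(min = r[1], range = r[2] - r[1]))
}

#' @rdname normalize_minmax
#' @param record A scale record from [normalize_minmax()].
#' @export
denormalize <- function(x, record) {
  x * record$range + record$min
}

#' Supervised sliding windows from a daily series
#'
#' Builds (input window, next value) training pairs: each pair uses `window`
#' consecutive days as input and the following day as the target. Windows
#' are built only within contiguous DOY runs — a window never spans a gap in
#' the daily record. Chronological order is preserved.
#'
#' @param values Numeric series.
#' @param window Window length in days (default 30).
#' @param doys Integer day axis, same length as `values`; defaults to a
#'   gapless `1..n` axis.
#' @return List with `x` (n_pairs x window matrix), `y` (targets) and
#'   `target_doy`.
#' @examples
#' w <- make_windows(1:5, window = 2)
#' w$x; w$y
#' @export
make_windows <- function(values, window = 30, doys = seq_along(values)) {
  stopifnot(length(values) == length(doys), window >= 1)
  if (length(values) <= window) {
    stop("series length (", length(values),
         ") must exceed the window (", window, ")", call. = FALSE)
  }
  run_id <- cumsum(c(1, diff(doys) != 1))
  xs <- list(); ys <- list(); ds <- list()
  for (rid in unique(run_id)) {
    idx <- which(run_id == rid)
    L <- length(idx)
    if (L <= window) next
    n_pairs <- L - window
    x <- matrix(0, nrow = n_pairs, ncol = window)
    for (j in seq_len(n_pairs)) {
      x[j, ] <- values[idx[j:(j + window - 1)]]
    }
    xs[[length(xs) + 1]] <- x
    ys[[length(ys) + 1]] <- values[idx[(window + 1):L]]
    ds[[length(ds) + 1]] <- doys[idx[(window + 1):L]]
  }
  if (length(xs) == 0) {
    stop("no contiguous run exceeds the window; cannot build windows",
         call. = FALSE)
  }
  list(x = do.call(rbind, xs), y = unlist(ys),
       target_doy = unlist(ds))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One forward step of the gated LSTM cell
#'
#' The three-gate cell recursion on the concatenated vector
#' `[h_{t-1}, x_t]`:
#' \deqn{f_t = \sigma(W_f [h_{t-1}, x_t] + b_f)}
#' \deqn{i_t = \sigma(W_i [h_{t-1}, x_t] + b_i)}
#' \deqn{\bar C_t = \tanh(W_c [h_{t-1}, x_t] + b_c)}
#' \deqn{C_t = f_t \odot C_{t-1} + i_t \odot \bar C_t}
#' \deqn{o_t = \sigma(W_o [h_{t-1}, x_t] + b_o)}
#' \deqn{h_t = o_t \odot \tanh(C_t)}
#' The forgetting gate `f` decides how much of the stored cell state
#' survives, the in-gate `i` how much of the candidate state enters, and the
#' out-gate `o` how much of the state is exposed as the hidden output.
#'
#' @param x_t Input at time t: a numeric vector of length `input_size`, or a
#'   batch matrix (rows = samples).
#' @param h_prev,c_prev Previous hidden state and cell state: length-`hidden`
#'   vectors or batch matrices.
#' @param weights List with matrices `W_f`, `W_i`, `W_c`, `W_o`
#'   (`hidden x (hidden + input_size)`, acting on `[h, x]`) and bias vectors
#'   `b_f`, `b_i`, `b_c`, `b_o`.
#' @return List with `h`, `c` (same shape as `h_prev`) and the gate
#'   activations `f`, `i`, `cbar`, `o`.
#' @examples
#' w <- list(W_f = matrix(0, 2, 3), W_i = matrix(0, 2, 3),
#'           W_c = matrix(0, 2, 3), W_o = matrix(0, 2, 3),
#'           b_f = c(0, 0), b_i = c(0, 0), b_c = c(0, 0), b_o = c(0, 0))
#' lstm_cell_forward(0.5, c(0, 0), c(1, 1), w)$c  # 0.5 * C_prev
#' @export
lstm_cell_forward <- function(x_t, h_prev, c_prev, weights) {
  vec_in <- is.null(dim(h_prev))
  if (vec_in) {
    h_prev <- matrix(h_prev, nrow = 1)
    c_prev <- matrix(c_prev, nrow = 1)
    x_t <- matrix(x_t, nrow = 1)
  } else if (is.null(dim(x_t))) {
    x_t <- matrix(x_t, nrow = nrow(h_prev))
  }
  z <- cbind(h_prev, x_t)
  if (ncol(z) != ncol(weights$W_f)) {
    stop("weight shapes are inconsistent with [h, x] of width ", ncol(z),
         call. = FALSE)
  }
  f <- sigmoid(z %*% t(weights$W_f) + rep(weights$b_f, each = nrow(z)))
  i <- sigmoid(z %*% t(weights$W_i) + rep(weights$b_i, each = nrow(z)))
  cbar <- tanh(z %*% t(weights$W_c) + rep(weights$b_c, each = nrow(z)))
  cc <- f * c_prev + i * cbar
  o <- sigmoid(z %*% t(weights$W_o) + rep(weights$b_o, each = nrow(z)))
  h <- o * tanh(cc)
  if (vec_in) {
    list(h = drop(h), c = drop(cc), f = drop(f), i = drop(i),
         cbar = drop(cbar), o = drop(o))
  } else {
    list(h = h, c = cc, f = f, i = i, cbar = cbar, o = o)
  }
}

#' LSTM training configuration
#'
#' Defaults follow the forecasting setup for a daily canopy colour index:
#' 30-day input windows, a 2-layer stacked cell, uniform weight
#' initialisation on `[-0.01, 0.01]`, learning rate `1e-5` decaying
#' exponentially per epoch, and a chronological 70/20/10
#' train/test/validation split. The scalar prediction is read out from the
#' last hidden state and the last input through a single linear layer — a
#' residual head initialised at the persistence solution (skip weight 1),
#' so training refines the natural next-day baseline rather than having to
#' rediscover it; see the methods vignette for the reasoning.
#'
#' The default optimiser is Adam: with the small stated learning rate,
#' Adam's normalised steps are what make training move at all within a
#' realistic epoch budget (see the methods vignette); plain stochastic
#' gradient descent is available via `optimizer = "sgd"`. The default
#' per-sample updates (`batch_size = 1`, sequential stepwise training) run
#' in compiled code; any larger batch size uses the R mini-batch loop with
#' identical mathematics.
#'
#' @param window Input window length in days.
#' @param hidden Hidden state width per layer.
#' @param depth Number of stacked layers.
#' @param init_range Half-width of the symmetric uniform weight init.
#' @param learning_rate Base learning rate.
#' @param lr_decay Per-epoch exponential decay factor of the learning rate.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param split Chronological fractions for train/test/validation; must sum
#'   to 1.
#' @param seed Integer seed controlling init and batch order.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(window = 30, hidden = 16, depth = 2,
                        init_range = 0.01, learning_rate = 1e-5,
                        lr_decay = 0.999, epochs = 500, batch_size = 1,
                        optimizer = c("adam", "sgd"),
                        split = c(train = 0.7, test = 0.2, validation = 0.1),
                        seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(window >= 1, hidden >= 1, depth >= 1, init_range > 0,
            learning_rate > 0, lr_decay > 0, lr_decay <= 1,
            epochs >= 1, batch_size >= 1, length(split) == 3)
  if (abs(sum(split) - 1) > 1e-8) {
    stop("`split` fractions must sum to 1", call. = FALSE)
  }
  structure(list(window = window, hidden = hidden, depth = depth,
                 init_range = init_range, learning_rate = learning_rate,
                 lr_decay = lr_decay, epochs = epochs,
                 batch_size = batch_size, optimizer = optimizer,
                 split = split, seed = seed),
            class = "lstm_config")
}

# ---- internal fused representation -----------------------------------------
# Per layer one matrix W (4H x (H+in)) and bias (4H), gate row order
# f, i, c, o; plus a residual linear read-out (w_out, w_skip, b_out) over
# [h_T, x_T].

lstm_init_fused <- function(input_size, hidden, depth, init_range) {
  layers <- lapply(seq_len(depth), function(l) {
    ins <- if (l == 1) input_size else hidden
    list(W = matrix(stats::runif(4 * hidden * (hidden + ins),
                                 -init_range, init_range),
                    nrow = 4 * hidden),
         b = stats::runif(4 * hidden, -init_range, init_range))
  })
  # identity initialisation of the residual read-out: the model starts at
  # the persistence baseline (prediction = last input) and training learns
  # corrections through the gated cell
  list(layers = layers,
       w_out = stats::runif(hidden, -init_range, init_range),
       w_skip = rep(1, input_size),
       b_out = stats::runif(1, -init_range, init_range),
       hidden = hidden, input_size = input_size)
}

gate_rows <- function(hidden) {
  list(f = 1:hidden, i = hidden + 1:hidden,
       c = 2 * hidden + 1:hidden, o = 3 * hidden + 1:hidden)
}

# Forward pass over a batch of windows. X: n x T matrix (univariate input).
# Returns prediction and, if keep = TRUE, the caches needed for BPTT.
lstm_forward_fused <- function(net, X, keep = FALSE) {
  n <- nrow(X); T_ <- ncol(X); H <- net$hidden
  gr <- gate_rows(H)
  caches <- if (keep) vector("list", length(net$layers))
  inp <- NULL
  for (l in seq_along(net$layers)) {
    W <- net$layers[[l]]$W; b <- net$layers[[l]]$b
    h <- matrix(0, n, H); cc <- matrix(0, n, H)
    hs <- if (keep) vector("list", T_)
    lc <- if (keep) vector("list", T_)
    houts <- vector("list", T_)
    for (t in seq_len(T_)) {
      x_t <- if (l == 1) X[, t, drop = FALSE] else inp[[t]]
      z <- cbind(h, x_t)
      a <- z %*% t(W) + rep(b, each = n)
      f <- sigmoid(a[, gr$f, drop = FALSE])
      i <- sigmoid(a[, gr$i, drop = FALSE])
      cb <- tanh(a[, gr$c, drop = FALSE])
      o <- sigmoid(a[, gr$o, drop = FALSE])
      c_prev <- cc
      cc <- f * c_prev + i * cb
      tc <- tanh(cc)
      h <- o * tc
      if (keep) {
        lc[[t]] <- list(z = z, f = f, i = i, cb = cb, o = o,
                        c_prev = c_prev, c = cc, tc = tc)
      }
      houts[[t]] <- h
    }
    if (keep) caches[[l]] <- lc
    inp <- houts
  }
  h_last <- inp[[T_]]
  x_last <- X[, T_]
  yhat <- drop(h_last %*% net$w_out) + x_last * net$w_skip + net$b_out
  list(yhat = yhat, h_last = h_last, h_seq = inp, caches = caches)
}

# Backpropagation through time for the stacked cell + linear read-out,
# mean-squared-error loss. Returns gradients in the fused layout.
lstm_backward_fused <- function(net, X, y, fwd) {
  n <- nrow(X); T_ <- ncol(X); H <- net$hidden
  gr <- gate_rows(H)
  dy <- 2 * (fwd$yhat - y) / n                      # dL/dyhat
  g_wout <- drop(crossprod(fwd$h_last, dy))
  g_skip <- sum(dy * X[, T_])
  g_bout <- sum(dy)

  # dh flowing into the top layer at each timestep (read-out only at T)
  dh_ext <- vector("list", T_)
  for (t in seq_len(T_)) dh_ext[[t]] <- matrix(0, n, H)
  dh_ext[[T_]] <- outer(dy, net$w_out)

  grads <- vector("list", length(net$layers))
  for (l in rev(seq_along(net$layers))) {
    cache <- fwd$caches[[l]]
    W <- net$layers[[l]]$W
    in_width <- ncol(W) - H
    dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(4 * H)
    dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
    dx_out <- vector("list", T_)
    for (t in rev(seq_len(T_))) {
      cc <- cache[[t]]
      dh <- dh_ext[[t]] + dh_next
      do_ <- dh * cc$tc
      dcc <- dh * cc$o * (1 - cc$tc^2) + dc_next
      df <- dcc * cc$c_prev
      di <- dcc * cc$cb
      dcb <- dcc * cc$i
      dc_next <- dcc * cc$f
      dz_gate <- cbind(df * cc$f * (1 - cc$f),
                       di * cc$i * (1 - cc$i),
                       dcb * (1 - cc$cb^2),
                       do_ * cc$o * (1 - cc$o))
      dW <- dW + crossprod(dz_gate, cc$z)
      db <- db + colSums(dz_gate)
      dz_in <- dz_gate %*% W
      dh_next <- dz_in[, 1:H, drop = FALSE]
      dx_out[[t]] <- dz_in[, H + seq_len(in_width), drop = FALSE]
    }
    grads[[l]] <- list(W = dW, b = db)
    if (l > 1) dh_ext <- dx_out
  }
  list(layers = grads, w_out = g_wout, w_skip = g_skip, b_out = g_bout)
}

adam_state_like <- function(net) {
  zero_like <- function(x) if (is.matrix(x)) x * 0 else numeric(length(x))
  list(layers = lapply(net$layers, function(l) {
    list(W = list(m = zero_like(l$W), v = zero_like(l$W)),
         b = list(m = zero_like(l$b), v = zero_like(l$b)))
  }),
  w_out = list(m = zero_like(net$w_out), v = zero_like(net$w_out)),
  w_skip = list(m = zero_like(net$w_skip), v = zero_like(net$w_skip)),
  b_out = list(m = 0, v = 0))
}

adam_step <- function(w, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(w = w - lr * mhat / (sqrt(vhat) + eps), st = st)
}

# Spec-facing weight view: four gate matrices + biases per layer.
lstm_weights_view <- function(net) {
  gr <- gate_rows(net$hidden)
  layers <- lapply(net$layers, function(l) {
    list(W_f = l$W[gr$f, , drop = FALSE], W_i = l$W[gr$i, , drop = FALSE],
         W_c = l$W[gr$c, , drop = FALSE], W_o = l$W[gr$o, , drop = FALSE],
         b_f = l$b[gr$f], b_i = l$b[gr$i], b_c = l$b[gr$c], b_o = l$b[gr$o])
  })
  list(layers = layers, w_out = net$w_out, w_skip = net$w_skip,
       b_out = net$b_out, hidden = net$hidden,
       input_size = net$input_size)
}

lstm_fused_from_view <- function(weights) {
  layers <- lapply(weights$layers, function(l) {
    list(W = rbind(l$W_f, l$W_i, l$W_c, l$W_o),
         b = c(l$b_f, l$b_i, l$b_c, l$b_o))
  })
  list(layers = layers, w_out = weights$w_out, w_skip = weights$w_skip,
       b_out = weights$b_out, hidden = weights$hidden,
       input_size = weights$input_size)
}

#' Train the LSTM forecaster on a daily index series
#'
#' Normalises the series to `[0, 1]`, builds sliding supervised windows
#' ([make_windows()]), splits them chronologically (no shuffling across the
#' split boundaries), and trains the stacked gate-equation cell plus linear
#' read-out by backpropagation through time on the squared one-step-ahead
#' error. Training is deterministic under a fixed `config$seed`.
#'
#' @param series Tibble with `doy` and `value` columns, one ROI x index
#'   daily series.
#' @param config An [lstm_config()].
#' @return An object of class `canopy_lstm`: list with `weights` (gate
#'   matrices per layer + read-out), `record` (normalisation),
#'   `config`, `history` (tibble: `epoch`, `loss`, `lr`), `series`, and the
#'   chronological `split` indices. Supports [glance()][generics::glance],
#'   [tidy()][generics::tidy] and [autoplot()][ggplot2::autoplot].
#' @seealso [lstm_forecast()]
#' @export
lstm_train <- function(series, config = lstm_config()) {
  stopifnot(inherits(config, "lstm_config"),
            all(c("doy", "value") %in% names(series)))
  d <- series |> dplyr::filter(!is.na(.data$value)) |>
    dplyr::arrange(.data$doy)
  norm <- normalize_minmax(d$value)
  win <- make_windows(norm$values, config$window, doys = d$doy)
  n <- length(win$y)
  n_train <- floor(config$split[[1]] * n)
  n_test <- floor(config$split[[2]] * n)
  n_val <- n - n_train - n_test
  if (n_train < 1 || n_test < 1 || n_val < 1) {
    stop("series too short: every split partition needs at least one window",
         call. = FALSE)
  }
  split <- list(train = seq_len(n_train),
                test = n_train + seq_len(n_test),
                validation = n_train + n_test + seq_len(n_val))

  Xtr <- win$x[split$train, , drop = FALSE]
  ytr <- win$y[split$train]

  hist_loss <- numeric(config$epochs)
  hist_lr <- numeric(config$epochs)

  if (config$batch_size == 1) {
    # per-sample training runs in compiled code; identical maths, identical
    # RNG draws (init then one sample order per epoch) as the R path
    res <- withr::with_seed(config$seed, {
      net0 <- lstm_init_fused(1L, config$hidden, config$depth,
                              config$init_range)
      orders <- t(vapply(seq_len(config$epochs),
                         function(e) sample.int(n_train),
                         integer(n_train)))
      .lstm_train_cpp(Xtr, ytr, net0$layers, net0$w_out, net0$w_skip,
                      net0$b_out, orders, config$learning_rate,
                      config$lr_decay, config$optimizer)
    })
    net <- list(layers = res$layers, w_out = as.numeric(res$w_out),
                w_skip = as.numeric(res$w_skip), b_out = res$b_out,
                hidden = config$hidden, input_size = 1L)
    hist_loss <- as.numeric(res$loss)
    hist_lr <- config$learning_rate * config$lr_decay^(seq_len(config$epochs) - 1)
    return(structure(list(
      weights = lstm_weights_view(net),
      record = norm$record,
      config = config,
      history = tibble::tibble(epoch = seq_len(config$epochs),
                               loss = hist_loss, lr = hist_lr),
      series = d,
      windows = list(target_doy = win$target_doy),
      split = split),
      class = "canopy_lstm"))
  }

  net <- withr::with_seed(config$seed, {
    net <- lstm_init_fused(1L, config$hidden, config$depth,
                           config$init_range)
    st <- adam_state_like(net)
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate * config$lr_decay^(epoch - 1)
      order <- sample.int(n_train)
      batch_starts <- seq(1, n_train, by = config$batch_size)
      losses <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        idx <- order[batch_starts[bi]:
                       min(batch_starts[bi] + config$batch_size - 1, n_train)]
        Xb <- Xtr[idx, , drop = FALSE]
        yb <- ytr[idx]
        fwd <- lstm_forward_fused(net, Xb, keep = TRUE)
        loss <- mean((fwd$yhat - yb)^2)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        }
        losses[bi] <- loss
        g <- lstm_backward_fused(net, Xb, yb, fwd)
        step <- step + 1L
        if (config$optimizer == "adam") {
          for (l in seq_along(net$layers)) {
            up <- adam_step(net$layers[[l]]$W, g$layers[[l]]$W,
                            st$layers[[l]]$W, lr, step)
            net$layers[[l]]$W <- up$w; st$layers[[l]]$W <- up$st
            up <- adam_step(net$layers[[l]]$b, g$layers[[l]]$b,
                            st$layers[[l]]$b, lr, step)
            net$layers[[l]]$b <- up$w; st$layers[[l]]$b <- up$st
          }
          up <- adam_step(net$w_out, g$w_out, st$w_out, lr, step)
          net$w_out <- up$w; st$w_out <- up$st
          up <- adam_step(net$w_skip, g$w_skip, st$w_skip, lr, step)
          net$w_skip <- up$w; st$w_skip <- up$st
          up <- adam_step(net$b_out, g$b_out, st$b_out, lr, step)
          net$b_out <- up$w; st$b_out <- up$st
        } else {
          for (l in seq_along(net$layers)) {
            net$layers[[l]]$W <- net$layers[[l]]$W - lr * g$layers[[l]]$W
            net$layers[[l]]$b <- net$layers[[l]]$b - lr * g$layers[[l]]$b
          }
          net$w_out <- net$w_out - lr * g$w_out
          net$w_skip <- net$w_skip - lr * g$w_skip
          net$b_out <- net$b_out - lr * g$b_out
        }
      }
      hist_loss[epoch] <- mean(losses)
      hist_lr[epoch] <- lr
    }
    net
  })

  structure(list(
    weights = lstm_weights_view(net),
    record = norm$record,
    config = config,
    history = tibble::tibble(epoch = seq_len(config$epochs),
                             loss = hist_loss, lr = hist_lr),
    series = d,
    windows = list(target_doy = win$target_doy),
    split = split),
    class = "canopy_lstm")
}

#' @export
print.canopy_lstm <- function(x, ...) {
  cat(sprintf(
    "LSTM forecaster: depth %d, hidden %d, window %d days\n",
    x$config$depth, x$config$hidden, x$config$window))
  cat(sprintf("  trained %d epochs (%s), final loss %.3g\n",
              x$config$epochs, x$config$optimizer,
              utils::tail(x$history$loss, 1)))
  cat(sprintf("  windows: %d train / %d test / %d validation\n",
              length(x$split$train), length(x$split$test),
              length(x$split$validation)))
  invisible(x)
}

#' Forecast from a trained LSTM
#'
#' `mode = "onestep"` predicts each held-out day from its 30 observed
#' predecessor days (teacher-forced evaluation on the chosen split
#' partition). `mode = "recursive"` starts from the last observed window and
#' feeds each prediction back as input for `horizon` steps — the
#' out-of-sample continuation of the series. Predictions are returned on the
#' original index scale.
#'
#' @param model A `canopy_lstm` from [lstm_train()].
#' @param mode `"onestep"` or `"recursive"`.
#' @param horizon Number of recursive steps ahead (default 60).
#' @param set Split partition evaluated in one-step mode: `"test"`,
#'   `"validation"`, `"train"` or `"all"`.
#' @return A tibble of class `canopy_forecast`: `doy`, `y_true` (`NA` beyond
#'   the observed range), `y_pred`, `mode`.
#' @export
lstm_forecast <- function(model, mode = c("onestep", "recursive"),
                          horizon = 60,
                          set = c("test", "validation", "train", "all")) {
  mode <- match.arg(mode)
  set <- match.arg(set)
  stopifnot(inherits(model, "canopy_lstm"))
  net <- lstm_fused_from_view(model$weights)
  scaled <- (model$series$value - model$record$min) / model$record$range
  win <- make_windows(scaled, model$config$window, doys = model$series$doy)

  if (mode == "onestep") {
    idx <- if (set == "all") seq_along(win$y) else model$split[[set]]
    fwd <- lstm_forward_fused(net, win$x[idx, , drop = FALSE])
    out <- tibble::tibble(
      doy = win$target_doy[idx],
      y_true = denormalize(win$y[idx], model$record),
      y_pred = denormalize(fwd$yhat, model$record),
      mode = "onestep")
  } else {
    if (!is.numeric(horizon) || horizon < 1) {
      stop("`horizon` must be a positive integer", call. = FALSE)
    }
    buf <- scaled[(length(scaled) - model$config$window + 1):length(scaled)]
    preds <- numeric(horizon)
    for (s in seq_len(horizon)) {
      fwd <- lstm_forward_fused(net, matrix(buf, nrow = 1))
      preds[s] <- fwd$yhat
      buf <- c(buf[-1], fwd$yhat)
    }
    out <- tibble::tibble(
      doy = max(model$series$doy) + seq_len(horizon),
      y_true = NA_real_,
      y_pred = denormalize(preds, model$record),
      mode = "recursive")
  }
  class(out) <- c("canopy_forecast", class(out))
  out
}

#' @importFrom generics glance
#' @method glance canopy_lstm
#' @export
glance.canopy_lstm <- function(x, ...) {
  tibble::tibble(
    depth = x$config$depth, hidden = x$config$hidden,
    window = x$config$window, epochs = x$config$epochs,
    optimizer = x$config$optimizer,
    final_loss = utils::tail(x$history$loss, 1),
    n_train = length(x$split$train), n_test = length(x$split$test),
    n_validation = length(x$split$validation))
}

#' @importFrom generics tidy
#' @method tidy canopy_lstm
#' @export
tidy.canopy_lstm <- function(x, ...) {
  purrr::imap_dfr(x$weights$layers, function(l, li) {
    purrr::imap_dfr(l[c("W_f", "W_i", "W_c", "W_o")], function(W, nm) {
      tibble::tibble(layer = li, tensor = nm,
                     n_params = length(W),
                     frobenius = sqrt(sum(W^2)))
    })
  })
}

#' @importFrom ggplot2 autoplot
#' @method autoplot canopy_lstm
#' @export
autoplot.canopy_lstm <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "Training loss (normalised MSE)",
                  title = "LSTM training history")
}

#' @importFrom ggplot2 autoplot
#' @method autoplot canopy_forecast
#' @export
autoplot.canopy_forecast <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("y_true", "y_pred"),
                              names_to = "series", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$doy, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(y_true = "grey30", y_pred = "firebrick"),
      labels = c(y_true = "observed", y_pred = "predicted")) +
    ggplot2::labs(x = "Day of year", y = "Index value", colour = NULL,
                  title = "LSTM forecast")
}
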