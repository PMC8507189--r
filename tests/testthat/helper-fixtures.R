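# Shared fixtures: ground-truth parameter sets on the two index scales and a
# small scene so image tests stay fast.

gei_params <- function() dl_params(w_min = 10, w_max = 70, S = 87, A = 312,
                                   mS = 0.11, mA = 0.09)

gcc_params <- function() dl_params(w_min = 0.31, w_max = 0.43, S = 87,
                                   A = 312, mS = 0.11, mA = 0.09)

small_scene <- function(images_per_day = 2, illumination_jitter = 0) {
  scene_spec(width = 64, height = 48,
             canopy = roi_rect("canopy", 4, 60, 16, 36),
             trunk = roi_rect("trunk", 24, 40, 36, 48),
             sky = roi_rect("sky", 0, 64, 0, 16),
             images_per_day = images_per_day,
             illumination_jitter = illumination_jitter)
}

# Build an rgb_image in memory from per-channel matrices (0-255 scale).
make_image <- function(r, g, b, timestamp = as.POSIXct("2018-06-01 12:00:00",
                                                       tz = "UTC")) {
  ch <- array(0, dim = c(nrow(r), ncol(r), 3))
  ch[, , 1] <- r; ch[, , 2] <- g; ch[, , 3] <- b
  structure(list(channels = ch, width = ncol(r), height = nrow(r),
                 timestamp = timestamp),
            class = "rgb_image")
}

uniform_image <- function(r, g, b, width = 8, height = 6, ...) {
  make_image(matrix(r, height, width), matrix(g, height, width),
             matrix(b, height, width), ...)
}

# Independent straight-loop evaluation of the gate equations, used as the
# oracle for lstm_cell_forward. Deliberately scalar: no matrix algebra.
reference_lstm_cell <- function(x_t, h_prev, c_prev, w) {
  H <- length(h_prev)
  z <- c(h_prev, x_t)
  gate <- function(W, b, act) {
    out <- numeric(H)
    for (j in seq_len(H)) {
      acc <- b[j]
      for (k in seq_along(z)) acc <- acc + W[j, k] * z[k]
      out[j] <- act(acc)
    }
    out
  }
  sig <- function(a) 1 / (1 + exp(-a))
  f <- gate(w$W_f, w$b_f, sig)
  i <- gate(w$W_i, w$b_i, sig)
  cbar <- gate(w$W_c, w$b_c, tanh)
  cc <- f * c_prev + i * cbar
  o <- gate(w$W_o, w$b_o, sig)
  list(h = o * tanh(cc), c = cc)
}

random_lstm_weights <- function(hidden, input, seed = 99) {
  withr::with_seed(seed, {
    mk <- function() matrix(rnorm(hidden * (hidden + input), sd = 0.5),
                            nrow = hidden)
    list(W_f = mk(), W_i = mk(), W_c = mk(), W_o = mk(),
         b_f = rnorm(hidden), b_i = rnorm(hidden), b_c = rnorm(hidden),
         b_o = rnorm(hidden))
  })
}

zero_lstm_weights <- function(hidden, input) {
  z <- matrix(0, hidden, hidden + input)
  list(W_f = z, W_i = z, W_c = z, W_o = z,
       b_f = numeric(hidden), b_i = numeric(hidden),
       b_c = numeric(hidden), b_o = numeric(hidden))
}
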