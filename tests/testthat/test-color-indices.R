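test_that("achromatic pixels give the neutral index values", {
  expect_equal(color_index(100, 100, 100, "gcc"), 1 / 3)
  expect_equal(color_index(100, 100, 100, "rcc"), 1 / 3)
  expect_equal(color_index(100, 100, 100, "grvi"), 0)
  expect_equal(color_index(100, 100, 100, "gei"), 0)
  expect_equal(color_index(100, 100, 100, "ggr"), 1)
  expect_warning(h <- color_index(100, 100, 100, "hue"), "achromatic")
  expect_true(is.na(h))
})

test_that("hand-computed index values match the formulas", {
  expect_equal(color_index(50, 100, 50, "gei"), 100)
  expect_equal(color_index(50, 100, 50, "gcc"), 0.5)
  expect_equal(color_index(50, 100, 50, "grvi"), 1 / 3)
  expect_equal(color_index(50, 100, 50, "ggr"), 2)
  expect_equal(color_index(50, 100, 50, "rcc"), 0.25)
  expect_equal(color_index(0, 255, 0, "hue"), 120)  # pure green
})

test_that("degenerate denominators yield NA sentinels with a warning", {
  expect_warning(v <- color_index(0, 10, 10, "ggr"), "GGR")
  expect_true(is.na(v))
  expect_warning(v <- color_index(0, 0, 10, "grvi"), "GRVI")
  expect_true(is.na(v))
  expect_warning(v <- color_index(0, 0, 0, "gcc"), "GCC")
  expect_true(is.na(v))
})

test_that("out-of-range channels and unknown indices are rejected", {
  expect_error(color_index(-1, 0, 0, "gcc"), "\\[0, 255\\]")
  expect_error(color_index(0, 300, 0, "gcc"), "\\[0, 255\\]")
  expect_error(color_index(1, 2, 3, "ndvi"), "unknown index")
})

test_that("chromatic identities hold over random triples", {
  withr::with_seed(42, {
    r <- runif(10000, 0, 255); g <- runif(10000, 0, 255)
    b <- runif(10000, 0, 255)
  })
  gcc <- color_index(r, g, b, "gcc")
  rcc <- color_index(r, g, b, "rcc")
  bcc <- b / (r + g + b)
  expect_equal(gcc + rcc + bcc, rep(1, length(r)), tolerance = 1e-12)

  # GRVI antisymmetry under swapping R and G
  expect_equal(color_index(r, g, b, "grvi"), -color_index(g, r, b, "grvi"),
               tolerance = 1e-12)

  # GEI linearity in the channels (scaled so sums stay within 8-bit range)
  r2 <- (255 - r) / 2; g2 <- (255 - g) / 2; b2 <- (255 - b) / 2
  expect_equal(color_index(r + r2, g + g2, b + b2, "gei"),
               color_index(r, g, b, "gei") + color_index(r2, g2, b2, "gei"),
               tolerance = 1e-9)

  # brightness scale invariance of the chromatic coordinates and hue
  k <- 0.4
  expect_equal(color_index(k * r, k * g, k * b, "gcc"), gcc,
               tolerance = 1e-12)
  expect_equal(color_index(k * r, k * g, k * b, "rcc"), rcc,
               tolerance = 1e-12)
  expect_equal(color_index(k * r, k * g, k * b, "grvi"),
               color_index(r, g, b, "grvi"), tolerance = 1e-12)
  expect_equal(color_index(k * r, k * g, k * b, "hue"),
               color_index(r, g, b, "hue"), tolerance = 1e-9)
})

test_that("standard hue agrees with the HSV decomposition", {
  withr::with_seed(7, {
    r <- round(runif(2000, 0, 255)); g <- round(runif(2000, 0, 255))
    b <- round(runif(2000, 0, 255))
  })
  distinct <- !(r == g & g == b)
  r <- r[distinct]; g <- g[distinct]; b <- b[distinct]
  ours <- color_index(r, g, b, "hue")
  ref <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)[1, ] * 360
  expect_equal(ours %% 360, ref %% 360, tolerance = 1e-9)
})

test_that("the literal tabulated hue branches differ only where printed", {
  # R max, G >= B: branch 4 in both conventions
  expect_equal(color_index(200, 100, 50, "hue"),
               color_index(200, 100, 50, "hue", hue_as_printed = TRUE))
  # R max, G < B: standard wraps by 360, printed adds 340
  expect_equal(color_index(200, 50, 100, "hue"), 340)
  expect_equal(color_index(200, 50, 100, "hue", hue_as_printed = TRUE), 320)
  # B max: printed keeps the (B - R) numerator
  expect_equal(color_index(50, 100, 200, "hue"),
               (50 - 100) / 150 * 60 + 240)
  expect_equal(color_index(50, 100, 200, "hue", hue_as_printed = TRUE),
               (200 - 50) / 150 * 60 + 240)
})

test_that("indices increase with G at fixed R and B", {
  g <- seq(10, 250, by = 10)
  for (ix in c("gcc", "gei", "grvi", "ggr")) {
    v <- color_index(100, g, 50, ix)
    expect_true(all(diff(v) > 0), info = ix)
  }
})

test_that("compute_indices returns aligned long series and keeps gaps", {
  daily <- tibble::tibble(
    roi = "c", date = as.Date("2018-01-01") + c(0, 1, 3),
    doy = c(1L, 2L, 4L), mean_r = 50, mean_g = 100, mean_b = 50,
    n_images = 11L)
  out <- compute_indices(daily, c("gcc", "gei"))
  expect_equal(nrow(out), 6)
  expect_equal(unique(out$doy), c(1L, 2L, 4L))
  expect_equal(out$value[out$index == "gcc"], rep(0.5, 3))
  expect_equal(out$value[out$index == "gei"], rep(100, 3))
  wide <- indices_wide(out)
  expect_equal(names(wide), c("roi", "date", "doy", "gcc", "gei"))
  expect_error(compute_indices(daily, "exg"), "unknown index")

  full <- compute_indices(daily)
  grids <- full |> dplyr::group_by(index) |>
    dplyr::summarise(g = paste(doy, collapse = ","))
  expect_equal(dplyr::n_distinct(grids$g), 1)  # identical DOY grids
})
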