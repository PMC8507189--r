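test_that("noiseless simulated series equals the closed-form trajectory", {
  p <- gei_params()
  ser <- simulate_index_series(p, doys = 1:365, noise_sd = 0)
  expect_identical(ser$value, ser$truth)
  expect_equal(ser$value, double_logistic(1:365, p))
})

test_that("trajectory saturates at the baseline and is unimodal", {
  p <- dl_params(w_min = 0.05, w_max = 0.15, S = 67, A = 337,
                 mS = 0.15, mA = 0.10)
  ser <- simulate_index_series(p, doys = 1:365, noise_sd = 0)
  expect_lt(abs(ser$value[1] - 0.05), 1e-5)      # t << S: near baseline
  expect_lt(abs(ser$value[365] - 0.05), 1e-2)    # after EOS: baseline again
  expect_lt(abs(double_logistic(-200, p) - 0.05), 1e-12)  # full saturation
  peak <- which.max(ser$value)
  expect_true(all(diff(ser$value[1:peak]) >= -1e-12))
  expect_true(all(diff(ser$value[peak:365]) <= 1e-12))
  expect_lt(abs(max(ser$value) - 0.15), 1e-6)
})

test_that("series generation is seeded and reproducible", {
  p <- gei_params()
  a <- simulate_index_series(p, noise_sd = 2, seed = 1)
  b <- simulate_index_series(p, noise_sd = 2, seed = 1)
  c <- simulate_index_series(p, noise_sd = 2, seed = 2)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$value, c$value)))
})

test_that("invalid trajectory requests are rejected", {
  expect_error(simulate_index_series(gei_params(), doys = integer(0)),
               "nonempty")
  expect_error(simulate_index_series(gei_params(), doys = 700:740),
               "\\[1, 730\\]")
  expect_error(simulate_index_series(gei_params(), noise_sd = -1),
               "nonnegative")
  expect_error(dl_params(w_min = 1, w_max = 0), "w_max")
  expect_error(dl_params(S = 300, A = 100), "S")
})

test_that("archive writes images_per_day files per DOY with parseable names", {
  dir <- withr::local_tempdir()
  arch <- simulate_image_archive(dir, scene = small_scene(images_per_day = 11),
                                 params = gcc_params(), doys = 1:3, seed = 1)
  expect_equal(nrow(arch$manifest), 33)
  expect_length(list.files(dir, pattern = "\\.png$"), 33)
  ts <- vapply(arch$manifest$file, function(f) {
    format(read_canopy_image(file.path(dir, f))$timestamp, "%Y%m%d_%H%M%S")
  }, character(1))
  expect_identical(unname(ts), gsub("\\.png$", "", arch$manifest$file))
})

test_that("jitter-free canopy GCC matches the requested value to quantization", {
  dir <- withr::local_tempdir()
  p <- dl_params(w_min = 0.40, w_max = 0.41, S = 87, A = 312,
                 mS = 0.11, mA = 0.09)   # requested GCC ~0.40 in winter
  arch <- simulate_image_archive(dir, scene = small_scene(), params = p,
                                 doys = 1:2, seed = 1)
  daily <- aggregate_daily(extract_roi_means(dir, arch$rois))
  gcc <- compute_indices(daily, "gcc") |> dplyr::filter(roi == "canopy")
  expect_equal(gcc$value, arch$truth$gcc, tolerance = 0.01)
  expect_lt(max(abs(gcc$value - 0.40)), 0.01)
})

test_that("static trunk region has zero day-to-day variance without jitter", {
  dir <- withr::local_tempdir()
  arch <- simulate_image_archive(dir, scene = small_scene(),
                                 params = gcc_params(), doys = 1:4, seed = 1)
  daily <- aggregate_daily(extract_roi_means(dir, arch$rois))
  trunk_gcc <- compute_indices(daily, "gcc") |>
    dplyr::filter(roi == "trunk")
  expect_equal(stats::var(trunk_gcc$value), 0)
})

test_that("archive generation is deterministic under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sc <- small_scene(illumination_jitter = 0.05)
  simulate_image_archive(d1, scene = sc, doys = 1:2, seed = 7)
  simulate_image_archive(d2, scene = sc, doys = 1:2, seed = 7)
  f1 <- list.files(d1, pattern = "png$", full.names = TRUE)
  f2 <- list.files(d2, pattern = "png$", full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(lapply(f1, function(f) unname(tools::md5sum(f))),
                   lapply(f2, function(f) unname(tools::md5sum(f))))
})

test_that("scene regions must be disjoint and inside the image", {
  expect_error(
    scene_spec(width = 64, height = 48,
               canopy = roi_rect("canopy", 0, 64, 10, 40),
               trunk = roi_rect("trunk", 0, 10, 30, 48),
               sky = roi_rect("sky", 0, 64, 0, 10)),
    "disjoint")
  expect_error(
    scene_spec(width = 64, height = 48,
               canopy = roi_rect("canopy", 4, 80, 16, 36),
               trunk = roi_rect("trunk", 24, 40, 36, 48),
               sky = roi_rect("sky", 0, 64, 0, 16)),
    "outside")
})
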