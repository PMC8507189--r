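#' Simulate a seasonal colour-index series
#'
#' Evaluates a double-logistic greenness trajectory on a day-of-year grid and
#' adds i.i.d. Gaussian noise, emulating the daily index series obtained from
#' a canopy camera archive. The noiseless trajectory is retained in the
#' `truth` column so downstream fits can be scored against ground truth.
#'
#' The DOY grid may run past 365 (up to 730): values above 365 are read as
#' days of the following calendar year, which is how a 14-month archive
#' (November of year one through December of year two) is laid on a single
#' monotone axis.
#'
#' @param params A [dl_params()] object, the ground-truth trajectory.
#' @param doys Integer DOY grid, strictly increasing, within `[1, 730]`.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in index
#'   units. `0` gives the closed-form trajectory exactly.
#' @param seed Integer seed; the same `params`/`doys`/`noise_sd`/`seed` always
#'   reproduce the same series.
#' @param roi,index Labels stamped on the output.
#'
#' @return A tibble with columns `roi`, `index`, `doy`, `truth`, `value`.
#' @examples
#' ser <- simulate_index_series(dl_params(), noise_sd = 1.2, seed = 42)
#' head(ser)
#' @export
simulate_index_series <- function(params = dl_params(), doys = 1:365,
                                  noise_sd = 0, seed = 1,
                                  roi = "ROI1", index = "gei") {
  params <- as_dl_params(params)
  if (length(doys) < 1) stop("`doys` must be nonempty", call. = FALSE)
  if (any(doys < 1 | doys > 730)) {
    stop("`doys` must lie within [1, 730]", call. = FALSE)
  }
  if (is.unsorted(doys, strictly = TRUE)) {
    stop("`doys` must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be a nonnegative number", call. = FALSE)
  }
  truth <- double_logistic(doys, params)
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(length(doys), 0, noise_sd))
  } else {
    rep(0, length(doys))
  }
  tibble::tibble(roi = roi, index = index, doy = as.integer(doys),
                 truth = truth, value = truth + noise)
}

#' Map a green chromatic coordinate to an RGB pixel colour
#'
#' Monotone, invertible greenness-to-colour map used by the synthetic archive
#' generator: red and blue are held at a fixed brown-grey base `base_rb` and
#' the green channel is set to `G = 2 * base_rb * gcc / (1 - gcc)`, so the
#' pixel's GCC equals the requested value exactly (before 8-bit rounding).
#'
#' @param gcc Green chromatic coordinate(s) in `(0, 1)`; values are clamped to
#'   `[0.02, 0.95]` so the map stays within 8-bit range.
#' @param base_rb Red/blue base brightness (0-255 scale).
#' @return A matrix with columns `r`, `g`, `b` on the 0-255 scale.
#' @export
gcc_to_rgb <- function(gcc, base_rb = 80) {
  gcc <- pmin(pmax(gcc, 0.02), 0.95)
  g <- 2 * base_rb * gcc / (1 - gcc)
  cbind(r = rep(base_rb, length(gcc)), g = pmin(g, 255),
        b = rep(base_rb, length(gcc)))
}

#' Rectangular scene region
#'
#' Axis-aligned rectangle in 0-based pixel coordinates with half-open
#' extents `[x0, x1) x [y0, y1)` (`x` = column, `y` = row).
#'
#' @param name Region label.
#' @param x0,x1,y0,y1 Integer pixel bounds.
#' @return A one-row tibble usable as an ROI specification.
#' @export
roi_rect <- function(name, x0, x1, y0, y1) {
  stopifnot(x1 > x0, y1 > y0, x0 >= 0, y0 >= 0)
  tibble::tibble(name = name, type = "rect",
                 coords = list(c(x0 = x0, x1 = x1, y0 = y0, y1 = y1)))
}

#' Polygonal scene region
#'
#' @param name Region label.
#' @param x,y Equal-length numeric vectors of polygon vertices in 0-based
#'   pixel coordinates (`x` = column, `y` = row).
#' @return A one-row tibble usable as an ROI specification.
#' @export
roi_polygon <- function(name, x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  tibble::tibble(name = name, type = "polygon",
                 coords = list(cbind(x = x, y = y)))
}

#' Synthetic camera scene description
#'
#' Layout of the synthetic canopy frame: image size, one or more canopy
#' patches (each tied to its own greenness trajectory), a trunk patch and a
#' sky band with static colours, the number of frames captured per day, and a
#' multiplicative illumination jitter applied per frame.
#'
#' Regions must be pairwise disjoint and lie inside the image. The default
#' scene is a small 160 x 120 frame: full-width sky band on top, a canopy
#' block in the middle and a trunk column at the bottom, mirroring the
#' composition of a tower-mounted canopy camera.
#'
#' @param width,height Image size in pixels.
#' @param canopy A tibble of canopy regions from [roi_rect()] (one row per
#'   region of interest); rows may be bound together for multiple ROIs.
#' @param trunk,sky Single-region tibbles from [roi_rect()].
#' @param trunk_color,sky_color RGB triples (0-255) for the static regions.
#' @param images_per_day Frames per day (default 11, hourly 07:05-17:05).
#' @param illumination_jitter Log-scale standard deviation of the per-frame
#'   multiplicative brightness factor; `0` disables jitter.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 160, height = 120,
                       canopy = roi_rect("canopy", 10, 150, 40, 90),
                       trunk = roi_rect("trunk", 70, 90, 90, 120),
                       sky = roi_rect("sky", 0, 160, 0, 40),
                       trunk_color = c(92, 68, 50),
                       sky_color = c(135, 170, 210),
                       images_per_day = 11,
                       illumination_jitter = 0.05) {
  stopifnot(width >= 1, height >= 1, images_per_day >= 1,
            illumination_jitter >= 0,
            length(trunk_color) == 3, length(sky_color) == 3)
  regions <- dplyr::bind_rows(canopy, trunk, sky)
  masks <- lapply(seq_len(nrow(regions)), function(i) {
    roi_mask(regions[i, ], width, height)
  })
  for (m in masks) {
    if (!any(m)) stop("scene regions must be nonempty", call. = FALSE)
  }
  overlap <- Reduce(`+`, masks)
  if (any(overlap > 1)) {
    stop("scene regions must be pairwise disjoint", call. = FALSE)
  }
  structure(list(width = width, height = height, canopy = canopy,
                 trunk = trunk, sky = sky,
                 trunk_color = trunk_color, sky_color = sky_color,
                 images_per_day = images_per_day,
                 illumination_jitter = illumination_jitter),
            class = "scene_spec")
}

# Hour-of-day schedule: images_per_day frames spread hourly starting 07:05.
frame_times <- function(n) {
  hours <- 7 + seq_len(n) - 1
  sprintf("%02d%02d%02d", hours %% 24, 5, 0)
}

#' Generate a synthetic canopy image archive
#'
#' Writes `images_per_day` timestamped PNG frames per day whose canopy-region
#' mean GCC tracks a double-logistic trajectory (one trajectory per canopy
#' region), with static trunk and sky colours and optional multiplicative
#' per-frame illumination jitter. Filenames encode the capture time as
#' `YYYYMMDD_HHMMSS.png`. A manifest of files and the ground-truth daily GCC
#' per canopy region are returned and also written alongside the images
#' (`manifest.json`, `truth.csv`).
#'
#' Because the jitter multiplies all three channels equally, the chromatic
#' indices (GCC, RCC, GRVI, HUE) of a frame are unaffected by it; only the
#' absolute-brightness indices (GEI) and the raw channel means vary within a
#' day.
#'
#' @param out_dir Directory to write into (created if missing).
#' @param scene A [scene_spec()].
#' @param params A [dl_params()] on the GCC scale (values in `(0, 1)`), or a
#'   list of one per canopy region.
#' @param doys Integer DOY grid (see [simulate_index_series()]).
#' @param noise_sd Day-to-day Gaussian noise on the GCC trajectory.
#' @param seed Integer seed driving both trajectory noise and jitter.
#' @param year Calendar year anchoring DOY 1.
#' @return An object of class `canopy_archive`: list with `manifest` (tibble:
#'   `file`, `timestamp`, `date`, `doy`, `frame`), `truth` (tibble: `roi`,
#'   `doy`, `gcc`), `rois` (canopy/trunk/sky ROI tibble) and `dir`.
#' @examples
#' \donttest{
#' dir <- tempfile("archive")
#' arch <- simulate_image_archive(dir, doys = 1:3, seed = 1)
#' nrow(arch$manifest)  # 3 days x 11 frames
#' }
#' @export
simulate_image_archive <- function(out_dir,
                                   scene = scene_spec(),
                                   params = dl_params(w_min = 0.31,
                                                      w_max = 0.43,
                                                      S = 87, A = 312,
                                                      mS = 0.11, mA = 0.09),
                                   doys = 1:365, noise_sd = 0, seed = 1,
                                   year = 2018) {
  if (!inherits(scene, "scene_spec")) stop("`scene` must be a scene_spec")
  if (inherits(params, "dl_params")) params <- list(params)
  n_canopy <- nrow(scene$canopy)
  if (length(params) == 1 && n_canopy > 1) {
    params <- rep(params, n_canopy)
  }
  if (length(params) != n_canopy) {
    stop("need one trajectory per canopy region", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create `out_dir`: ", out_dir)

  canopy_names <- scene$canopy$name
  truth <- purrr::imap_dfr(params, function(p, i) {
    ser <- simulate_index_series(p, doys = doys, noise_sd = noise_sd,
                                 seed = seed + i, roi = canopy_names[[i]],
                                 index = "gcc")
    tibble::tibble(roi = ser$roi, doy = ser$doy, gcc = ser$value)
  })

  masks <- list(
    canopy = lapply(seq_len(n_canopy), function(i) {
      roi_mask(scene$canopy[i, ], scene$width, scene$height)
    }),
    trunk = roi_mask(scene$trunk, scene$width, scene$height),
    sky = roi_mask(scene$sky, scene$width, scene$height)
  )

  base <- array(0, dim = c(scene$height, scene$width, 3))
  for (ch in 1:3) {
    plane <- base[, , ch]
    plane[masks$trunk] <- scene$trunk_color[ch] / 255
    plane[masks$sky] <- scene$sky_color[ch] / 255
    base[, , ch] <- plane
  }

  n_frames <- scene$images_per_day
  times <- frame_times(n_frames)
  jitter <- if (scene$illumination_jitter > 0) {
    withr::with_seed(seed, matrix(
      exp(stats::rnorm(length(doys) * n_frames, 0,
                       scene$illumination_jitter)),
      nrow = length(doys)))
  } else {
    matrix(1, nrow = length(doys), ncol = n_frames)
  }

  origin <- as.Date(sprintf("%d-01-01", year)) - 1
  rows <- vector("list", length(doys) * n_frames)
  k <- 0L
  for (d in seq_along(doys)) {
    day_img <- base
    for (i in seq_len(n_canopy)) {
      rgb <- gcc_to_rgb(truth$gcc[truth$roi == canopy_names[[i]] &
                                    truth$doy == doys[[d]]])
      for (ch in 1:3) {
        plane <- day_img[, , ch]
        plane[masks$canopy[[i]]] <- rgb[1, ch] / 255
        day_img[, , ch] <- plane
      }
    }
    date <- origin + doys[[d]]
    for (fr in seq_len(n_frames)) {
      img <- pmin(pmax(day_img * jitter[d, fr], 0), 1)
      file <- sprintf("%s_%s.png", format(date, "%Y%m%d"), times[[fr]])
      png::writePNG(img, file.path(out_dir, file))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        file = file,
        timestamp = as.POSIXct(paste0(format(date, "%Y%m%d"), times[[fr]]),
                               format = "%Y%m%d%H%M%S", tz = "UTC"),
        date = date, doy = as.integer(doys[[d]]), frame = fr)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  rois <- dplyr::bind_rows(scene$canopy, scene$trunk, scene$sky)

  jsonlite::write_json(
    list(n_images = nrow(manifest), images_per_day = n_frames,
         files = manifest$file),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  readr::write_csv(truth, file.path(out_dir, "truth.csv"))

  structure(list(manifest = manifest, truth = truth, rois = rois,
                 dir = out_dir, year = year),
            class = "canopy_archive")
}
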