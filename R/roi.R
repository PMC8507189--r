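#' Read a timestamped canopy image
#'
#' Loads a PNG frame as an 8-bit RGB image and parses the capture time from
#' the filename (`YYYYMMDD_HHMMSS` anywhere in the basename). Grayscale
#' images are rejected: three colour channels are required for the colour
#' indices. An alpha channel, if present, is dropped.
#'
#' Archives are expected in PNG (lossless, as written by
#' [simulate_image_archive()]); there is no JPEG decoder among the package's
#' dependencies, so JPEG archives must be converted to PNG beforehand.
#'
#' @param path Path to a PNG file.
#' @return An object of class `rgb_image`: list with `channels` (height x
#'   width x 3 array on the 0-255 scale), `width`, `height`, `timestamp`
#'   (POSIXct, UTC).
#' @export
read_canopy_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) {
                    stop("cannot decode image '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(dim(arr)) < 3 || dim(arr)[3] < 3) {
    stop("image '", path, "' is not a three-channel RGB image", call. = FALSE)
  }
  ts <- parse_frame_timestamp(basename(path))
  structure(list(channels = arr[, , 1:3, drop = FALSE] * 255,
                 width = dim(arr)[2], height = dim(arr)[1],
                 timestamp = ts),
            class = "rgb_image")
}

parse_frame_timestamp <- function(name) {
  m <- regmatches(name, regexpr("\\d{8}[_-]\\d{6}", name))
  if (length(m) != 1) {
    stop("cannot parse a YYYYMMDD_HHMMSS timestamp from filename '",
         name, "'", call. = FALSE)
  }
  ts <- as.POSIXct(gsub("[_-]", "", m), format = "%Y%m%d%H%M%S", tz = "UTC")
  if (is.na(ts)) {
    stop("invalid timestamp in filename '", name, "'", call. = FALSE)
  }
  ts
}

#' Pixel mask for a region of interest
#'
#' Rasterises an ROI (rectangle or polygon, 0-based pixel coordinates,
#' rectangles half-open) into a logical height x width matrix. Pixel centres
#' at `(col - 0.5, row - 0.5)` decide polygon membership.
#'
#' @param roi A one-row ROI tibble from [roi_rect()] or [roi_polygon()].
#' @param width,height Image size in pixels.
#' @return Logical matrix, `TRUE` inside the region.
#' @export
roi_mask <- function(roi, width, height) {
  stopifnot(nrow(roi) == 1)
  co <- roi$coords[[1]]
  mask <- matrix(FALSE, nrow = height, ncol = width)
  if (roi$type == "rect") {
    if (co["x0"] < 0 || co["y0"] < 0 || co["x1"] > width || co["y1"] > height) {
      stop("ROI '", roi$name, "' extends outside the image", call. = FALSE)
    }
    mask[(co["y0"] + 1):co["y1"], (co["x0"] + 1):co["x1"]] <- TRUE
  } else if (roi$type == "polygon") {
    if (min(co[, "x"]) < 0 || min(co[, "y"]) < 0 ||
        max(co[, "x"]) > width || max(co[, "y"]) > height) {
      stop("ROI '", roi$name, "' extends outside the image", call. = FALSE)
    }
    cx <- rep(seq_len(width) - 0.5, each = height)
    cy <- rep(seq_len(height) - 0.5, times = width)
    inside <- pracma::inpolygon(cx, cy, co[, "x"], co[, "y"],
                                boundary = TRUE)
    mask <- matrix(inside, nrow = height, ncol = width)
  } else {
    stop("unknown ROI type '", roi$type, "'", call. = FALSE)
  }
  mask
}

#' Mean channel brightness over a region of interest
#'
#' Arithmetic mean of the R, G and B channels over the pixels of one ROI of
#' one frame — the per-frame record from which daily values are aggregated.
#'
#' @param image An `rgb_image` from [read_canopy_image()].
#' @param roi A one-row ROI tibble ([roi_rect()]/[roi_polygon()]).
#' @return One-row tibble: `roi`, `timestamp`, `mean_r`, `mean_g`, `mean_b`.
#' @export
image_mean_rgb <- function(image, roi) {
  stopifnot(inherits(image, "rgb_image"))
  mask <- roi_mask(roi, image$width, image$height)
  if (!any(mask)) {
    stop("ROI '", roi$name, "' covers no pixels", call. = FALSE)
  }
  tibble::tibble(
    roi = roi$name,
    timestamp = image$timestamp,
    mean_r = mean(image$channels[, , 1][mask]),
    mean_g = mean(image$channels[, , 2][mask]),
    mean_b = mean(image$channels[, , 3][mask])
  )
}

#' Per-frame ROI means for a whole archive
#'
#' Reads every PNG in a directory (or an explicit file list) and computes
#' [image_mean_rgb()] for each requested ROI.
#'
#' @param path Directory containing the archive, or a character vector of
#'   files.
#' @param rois ROI tibble (one row per region), e.g. rows of [roi_rect()] or
#'   the `rois` element of a [simulate_image_archive()] result.
#' @return Tibble with one row per frame x ROI: `roi`, `timestamp`,
#'   `mean_r`, `mean_g`, `mean_b`.
#' @export
extract_roi_means <- function(path, rois) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, pattern = "\\.png$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0) stop("no PNG images found", call. = FALSE)
  purrr::map_dfr(files, function(f) {
    img <- read_canopy_image(f)
    purrr::map_dfr(seq_len(nrow(rois)),
                   function(i) image_mean_rgb(img, rois[i, ]))
  })
}

#' Aggregate per-frame means to one RGB triple per ROI per day
#'
#' Averages all frames falling on the same calendar date (the "mean value"
#' aggregation that suppresses within-day illumination differences). Days
#' with no frames are simply absent from the output — gaps are preserved,
#' never zero-filled.
#'
#' The `doy` column is a continuous day-of-year axis anchored at 1 January of
#' the earliest year present (or of `anchor_year`), so an archive spanning a
#' year boundary (e.g. November of year one to December of year two) maps to
#' a single strictly increasing axis with values up to 730.
#'
#' @param samples Per-frame tibble from [extract_roi_means()] (columns `roi`,
#'   `timestamp`, `mean_r`, `mean_g`, `mean_b`).
#' @param anchor_year Year whose 1 January is DOY 1; defaults to the earliest
#'   year in `samples`.
#' @return Tibble: `roi`, `date`, `doy`, `mean_r`, `mean_g`, `mean_b`,
#'   `n_images`, sorted by ROI then day.
#' @export
aggregate_daily <- function(samples, anchor_year = NULL) {
  stopifnot(nrow(samples) > 0)
  dates <- as.Date(samples$timestamp, tz = "UTC")
  if (is.null(anchor_year)) {
    anchor_year <- as.integer(format(min(dates), "%Y"))
  }
  origin <- as.Date(sprintf("%d-01-01", anchor_year)) - 1
  samples |>
    dplyr::mutate(date = dates) |>
    dplyr::group_by(.data$roi, .data$date) |>
    dplyr::summarise(mean_r = mean(.data$mean_r),
                     mean_g = mean(.data$mean_g),
                     mean_b = mean(.data$mean_b),
                     n_images = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(doy = as.integer(.data$date - origin), .after = "date") |>
    dplyr::arrange(.data$roi, .data$doy)
}
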