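#' Read an ROI specification file
#'
#' Reads ROI definitions from JSON or YAML: a list of records with `name`,
#' `type` (`"rect"` or `"polygon"`) and `coords` (for rectangles a mapping
#' with `x0`, `x1`, `y0`, `y1`; for polygons a list of `[x, y]` vertex
#' pairs).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return ROI tibble as produced by [roi_rect()]/[roi_polygon()].
#' @export
read_roi_spec <- function(path) {
  if (!file.exists(path)) stop("ROI spec not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML ROI specs requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  purrr::map_dfr(raw, function(r) {
    if (identical(r$type, "rect")) {
      co <- r$coords
      roi_rect(r$name, co$x0, co$x1, co$y0, co$y1)
    } else if (identical(r$type, "polygon")) {
      xy <- do.call(rbind, lapply(r$coords, unlist))
      roi_polygon(r$name, xy[, 1], xy[, 2])
    } else {
      stop("unknown ROI type '", r$type, "' in ", path, call. = FALSE)
    }
  })
}

#' Scene with several canopy regions of interest
#'
#' Splits the canopy block of the default [scene_spec()] into `n_rois`
#' vertical strips named `ROI1..ROIn`, each of which can carry its own
#' phenology trajectory — the layout used to emulate micro-environment
#' differences between positions in the same stand.
#'
#' @param n_rois Number of canopy strips.
#' @param ... Passed on to [scene_spec()].
#' @return A `scene_spec` with `n_rois` canopy regions.
#' @export
multi_roi_scene <- function(n_rois = 3, ...) {
  edges <- round(seq(10, 150, length.out = n_rois + 1))
  canopy <- purrr::map_dfr(seq_len(n_rois), function(i) {
    roi_rect(paste0("ROI", i), edges[i], edges[i + 1], 40, 90)
  })
  scene_spec(canopy = canopy, ...)
}

#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs. Exactly one input source must
#' be given: a directory of timestamped images (`archive_dir`), a
#' pre-extracted long index series CSV (`series_csv`, columns `roi`, `doy`,
#' `index`, `value` — extraction and index stages are then skipped), or a
#' synthetic-archive request (`synthetic`, a list of arguments understood by
#' [run_pipeline()]: `n_rois`, `doys`, `noise_sd`, `s_shifts`, plus optional
#' `params`).
#'
#' @param archive_dir,series_csv,synthetic The input source (give one).
#' @param rois ROI tibble or path to a JSON/YAML spec (required with
#'   `archive_dir`; the synthetic source provides its own).
#' @param indices Colour indices to compute.
#' @param smooth_p Optional smoothing-spline roughness parameter applied
#'   before fitting (see [smooth_series()]).
#' @param forecast `FALSE`, or a list with `index` (default `"gei"`), `roi`
#'   (default first ROI), `horizon` (default 60) and `config` (an
#'   [lstm_config()]).
#' @param hue_as_printed See [color_index()].
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @param seed Top-level seed fanned out to every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(archive_dir = NULL, series_csv = NULL,
                            synthetic = NULL, rois = NULL,
                            indices = PHENO_INDICES, smooth_p = NULL,
                            forecast = FALSE, hue_as_printed = FALSE,
                            out_dir = NULL, seed = 1) {
  n_src <- sum(!is.null(archive_dir), !is.null(series_csv),
               !is.null(synthetic))
  if (n_src != 1) {
    stop("give exactly one input source: `archive_dir`, `series_csv` or ",
         "`synthetic`", call. = FALSE)
  }
  if (isTRUE(forecast)) forecast <- list()
  structure(list(archive_dir = archive_dir, series_csv = series_csv,
                 synthetic = synthetic, rois = rois, indices = indices,
                 smooth_p = smooth_p, forecast = forecast,
                 hue_as_printed = hue_as_printed,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the canopy-phenology pipeline
#'
#' Orchestrates archive extraction (or synthetic generation), daily
#' aggregation, colour-index computation, the per-ROI double-logistic fits
#' and phenophase extraction, the multi-ROI comparison table, and — when
#' requested — the LSTM forecast with its error metrics. All stage outputs
#' are returned and, if `out_dir` is set, written as CSV/JSON.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pheno_run`: list with `daily`, `indices`
#'   (long series), `fits` (named list of `pheno_fit`), `dates` (ROI x index
#'   phenophase tibble), `comparison` (pairwise ROI differences),
#'   `forecast`/`forecast_metrics` (when enabled), `errors` (tibble of
#'   per-combination failures) and `truth` (synthetic runs only).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  archive <- NULL

  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    n_rois <- sy$n_rois %||% 3
    doys <- sy$doys %||% 1:365
    s_shifts <- sy$s_shifts %||% seq(0, by = -5, length.out = n_rois)
    base <- sy$params %||% dl_params(w_min = 0.31, w_max = 0.43, S = 87,
                                     A = 312, mS = 0.11, mA = 0.09)
    params <- lapply(seq_len(n_rois), function(i) {
      dl_params(base$w_min, base$w_max, base$S + s_shifts[i], base$A,
                base$mS, base$mA)
    })
    dir <- sy$dir %||% file.path(tempdir(),
                                 paste0("pheno_archive_", config$seed))
    scene <- multi_roi_scene(n_rois,
                             images_per_day = sy$images_per_day %||% 11,
                             illumination_jitter = sy$illumination_jitter %||%
                               0.05)
    archive <- simulate_image_archive(dir, scene = scene, params = params,
                                      doys = doys,
                                      noise_sd = sy$noise_sd %||% 0,
                                      seed = config$seed)
    truth <- archive$truth
    config$archive_dir <- archive$dir
    config$rois <- archive$rois[archive$rois$name %in% scene$canopy$name, ]
  }

  daily <- NULL
  if (!is.null(config$series_csv)) {
    series <- readr::read_csv(config$series_csv, show_col_types = FALSE)
    stopifnot(all(c("roi", "doy", "index", "value") %in% names(series)))
    series <- series |> dplyr::filter(.data$index %in% config$indices)
  } else {
    rois <- config$rois
    if (is.character(rois)) rois <- read_roi_spec(rois)
    if (is.null(rois)) {
      stop("`rois` is required with an image-archive input", call. = FALSE)
    }
    samples <- extract_roi_means(config$archive_dir, rois)
    daily <- aggregate_daily(samples)
    series <- compute_indices(daily, config$indices,
                              hue_as_printed = config$hue_as_printed)
  }

  groups <- series |> dplyr::distinct(.data$roi, .data$index)
  fits <- list(); dates <- list(); errors <- list()
  for (k in seq_len(nrow(groups))) {
    ro <- groups$roi[k]; ix <- groups$index[k]
    key <- paste(ro, ix, sep = ".")
    sl <- series |> dplyr::filter(.data$roi == ro, .data$index == ix)
    if (!is.null(config$smooth_p)) {
      sl <- smooth_series(sl, config$smooth_p)
    }
    res <- tryCatch({
      fit <- fit_double_logistic(sl, seed = config$seed)
      ph <- extract_phenophases(fit)
      list(fit = fit, dates = dplyr::bind_cols(
        tibble::tibble(roi = ro, index = ix), ph))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- tibble::tibble(stage = "fit", roi = ro, index = ix,
                                      message = conditionMessage(res))
    } else {
      fits[[key]] <- res$fit
      dates[[key]] <- res$dates
    }
  }
  dates <- dplyr::bind_rows(dates)
  comparison <- if (nrow(dates) > 0) compare_rois(dates) else tibble::tibble()

  fc <- NULL; fc_metrics <- NULL
  if (is.list(config$forecast)) {
    f <- config$forecast
    ix <- tolower(f$index %||% "gei")
    ro <- f$roi %||% sort(unique(series$roi))[1]
    lc <- f$config %||% lstm_config(seed = config$seed)
    sl <- series |> dplyr::filter(.data$roi == ro, .data$index == ix)
    model <- lstm_train(sl, lc)
    onestep <- lstm_forecast(model, "onestep", set = "test")
    recursive <- lstm_forecast(model, "recursive",
                               horizon = f$horizon %||% 60)
    fc <- list(model = model, onestep = onestep, recursive = recursive)
    fc_metrics <- forecast_metrics(onestep)
  }

  run <- structure(list(daily = daily, indices = series, fits = fits,
                        dates = dates, comparison = comparison,
                        forecast = fc, forecast_metrics = fc_metrics,
                        errors = dplyr::bind_rows(errors), truth = truth,
                        config = config),
                   class = "pheno_run")
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pheno_run <- function(x, ...) {
  cat("Canopy-phenology pipeline run\n")
  cat(sprintf("  %d ROI x index series, %d fitted\n",
              nrow(dplyr::distinct(x$indices, .data$roi, .data$index)),
              length(x$fits)))
  if (nrow(x$dates) > 0) {
    cat("  phenophase dates:\n")
    print(x$dates, n = 6)
  }
  if (!is.null(x$forecast_metrics)) {
    cat("  one-step forecast metrics:\n")
    print(x$forecast_metrics)
  }
  if (nrow(x$errors) > 0) {
    cat(sprintf("  %d combination(s) failed to fit\n", nrow(x$errors)))
  }
  invisible(x)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(indices_wide(run$indices),
                   file.path(out_dir, "indices.csv"))
  if (nrow(run$dates) > 0) {
    readr::write_csv(run$dates, file.path(out_dir, "phenophase_dates.csv"))
  }
  if (nrow(run$comparison) > 0) {
    readr::write_csv(run$comparison,
                     file.path(out_dir, "roi_comparison.csv"))
  }
  fits_json <- purrr::imap(run$fits, function(f, key) {
    list(params = unclass(f$params),
         diagnostics = as.list(f$diagnostics))
  })
  jsonlite::write_json(fits_json, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(run$forecast)) {
    readr::write_csv(dplyr::bind_rows(run$forecast$onestep,
                                      run$forecast$recursive),
                     file.path(out_dir, "forecast.csv"))
    jsonlite::write_json(as.list(run$forecast_metrics),
                         file.path(out_dir, "forecast_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Pairwise ROI comparison of phenophase dates
#'
#' For every colour index shared by at least two ROIs, tabulates the
#' pairwise differences (in days) of the transition dates — the "same index,
#' different position" comparison that exposes micro-environment differences
#' within a stand. Differences are `roi_b - roi_a`.
#'
#' @param dates Phenophase tibble with columns `roi`, `index`, `sos`,
#'   `moe`, `los`, `eos` (e.g. the `dates` element of a [run_pipeline()]
#'   result).
#' @return Tibble: `index`, `roi_a`, `roi_b`, `d_sos`, `d_moe`, `d_los`,
#'   `d_eos`. Empty (with a warning) when no index is shared by two ROIs.
#' @export
compare_rois <- function(dates) {
  stopifnot(all(c("roi", "index", "sos", "moe", "los", "eos") %in%
                  names(dates)))
  out <- dates |>
    dplyr::group_by(.data$index) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) return(tibble::tibble())
      pairs <- utils::combn(seq_len(nrow(d)), 2)
      purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
        a <- d[pairs[1, j], ]; b <- d[pairs[2, j], ]
        tibble::tibble(roi_a = a$roi, roi_b = b$roi,
                       d_sos = b$sos - a$sos, d_moe = b$moe - a$moe,
                       d_los = b$los - a$los, d_eos = b$eos - a$eos)
      })
    }) |>
    dplyr::ungroup()
  if (nrow(out) == 0) {
    warning("no colour index is shared by two or more ROIs; ",
            "nothing to compare", call. = FALSE)
  }
  out
}
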