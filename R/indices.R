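PHENO_INDICES <- c("grvi", "hue", "ggr", "rcc", "gcc", "gei")

#' Colour indices from mean RGB brightness
#'
#' Computes one of the six canopy colour indices from channel brightness
#' values on the 0-255 scale:
#' \describe{
#'   \item{GGR}{`G / R` (ratio greenness)}
#'   \item{GCC}{`G / (R + G + B)` (green chromatic coordinate)}
#'   \item{GEI}{`2G - (R + B)` (green excess index)}
#'   \item{RCC}{`R / (R + G + B)` (red chromatic coordinate)}
#'   \item{GRVI}{`(G - R) / (G + R)` (green-red vegetation index)}
#'   \item{HUE}{the HSV hue angle in degrees, piecewise on which channel
#'     attains the maximum}
#' }
#'
#' Degenerate denominators (`R = 0` for GGR, `G + R = 0` for GRVI,
#' `R + G + B = 0` for GCC/RCC, achromatic pixels for HUE) yield `NA` for
#' that observation, with a warning, rather than an error.
#'
#' `hue_as_printed = TRUE` switches HUE to a literal variant sometimes seen
#' in tabulated index lists, whose third branch uses an offset of 340 instead
#' of the standard 360 wrap and whose `B`-maximum branch keeps the `B - R`
#' numerator; the default is the standard, continuous HSV hue in
#' `[0, 360)`.
#'
#' @param r,g,b Numeric vectors of channel brightness in `[0, 255]`
#'   (recycled to a common length).
#' @param index One of `"grvi"`, `"hue"`, `"ggr"`, `"rcc"`, `"gcc"`,
#'   `"gei"` (case-insensitive).
#' @param hue_as_printed Use the literal tabulated HUE branches (see above).
#' @return Numeric vector of index values.
#' @examples
#' color_index(50, 100, 50, "gei")  # 100
#' color_index(50, 100, 50, "gcc")  # 0.5
#' @export
color_index <- function(r, g, b, index, hue_as_printed = FALSE) {
  index <- tolower(index)
  if (!index %in% PHENO_INDICES) {
    stop("unknown index '", index, "'; expected one of ",
         paste(PHENO_INDICES, collapse = ", "), call. = FALSE)
  }
  n <- max(length(r), length(g), length(b))
  r <- rep_len(as.numeric(r), n)
  g <- rep_len(as.numeric(g), n)
  b <- rep_len(as.numeric(b), n)
  bad <- !is.na(r) & !is.na(g) & !is.na(b) &
    (r < 0 | r > 255 | g < 0 | g > 255 | b < 0 | b > 255)
  if (any(bad)) {
    stop("channel brightness must lie in [0, 255]", call. = FALSE)
  }
  out <- switch(index,
    ggr = safe_ratio(g, r, "GGR"),
    gcc = safe_ratio(g, r + g + b, "GCC"),
    rcc = safe_ratio(r, r + g + b, "RCC"),
    gei = 2 * g - (r + b),
    grvi = safe_ratio(g - r, g + r, "GRVI"),
    hue = hue_angle(r, g, b, as_printed = hue_as_printed)
  )
  out
}

safe_ratio <- function(num, den, label) {
  zero <- !is.na(den) & den == 0
  if (any(zero)) {
    warning(sum(zero), " observation(s) with a zero denominator for ",
            label, " set to NA", call. = FALSE)
    den[zero] <- NA_real_
  }
  num / den
}

hue_angle <- function(r, g, b, as_printed = FALSE) {
  i_max <- pmax(r, g, b)
  i_min <- pmin(r, g, b)
  d <- i_max - i_min
  achromatic <- !is.na(d) & d == 0
  if (any(achromatic)) {
    warning(sum(achromatic),
            " achromatic observation(s) have undefined HUE, set to NA",
            call. = FALSE)
  }
  d[achromatic] <- NA_real_
  if (as_printed) {
    h <- ifelse(g == i_max, (b - r) / d * 60 + 120,
         ifelse(b == i_max, (b - r) / d * 60 + 240,
         ifelse(g < b, (g - b) / d * 60 + 340,
                (g - b) / d * 60)))
  } else {
    h <- ifelse(g == i_max, (b - r) / d * 60 + 120,
         ifelse(b == i_max, (r - g) / d * 60 + 240,
                ((g - b) / d * 60) %% 360))
  }
  h
}

#' Colour-index series from daily mean RGB
#'
#' Computes the requested indices from daily ROI-mean RGB triples
#' (mean-then-index: the channel means are aggregated first, then the index
#' formula is applied) and returns a long, DOY-indexed series. Gaps in the
#' daily record are preserved.
#'
#' @param daily Daily tibble from [aggregate_daily()] (columns `roi`, `doy`,
#'   `mean_r`, `mean_g`, `mean_b`; `date` carried through if present).
#' @param indices Character vector of index names (default all six).
#' @param hue_as_printed See [color_index()].
#' @return Long tibble: `roi`, (`date`,) `doy`, `index`, `value`, sorted by
#'   ROI, index, day.
#' @export
compute_indices <- function(daily, indices = PHENO_INDICES,
                            hue_as_printed = FALSE) {
  stopifnot(nrow(daily) > 0)
  indices <- tolower(indices)
  unknown <- setdiff(indices, PHENO_INDICES)
  if (length(unknown) > 0) {
    stop("unknown index name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- intersect(c("roi", "date", "doy"), names(daily))
  purrr::map_dfr(indices, function(ix) {
    daily |>
      dplyr::transmute(!!!rlang::syms(keep), index = ix,
                       value = color_index(.data$mean_r, .data$mean_g,
                                           .data$mean_b, ix,
                                           hue_as_printed = hue_as_printed))
  }) |>
    dplyr::arrange(.data$roi, .data$index, .data$doy)
}

#' Widen a long index series
#'
#' One row per ROI-day with one column per index, the layout used for CSV
#' export.
#'
#' @param series Long tibble from [compute_indices()].
#' @return Wide tibble: `roi`, (`date`,) `doy`, then one column per index.
#' @export
indices_wide <- function(series) {
  tidyr::pivot_wider(series, names_from = "index", values_from = "value")
}
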