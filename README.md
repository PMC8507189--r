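# phenocanopy

Forest phenology from repeat canopy photography. A fixed camera images the
same stand several times a day for a year or more; `phenocanopy` turns that
archive into phenological quantities and forecasts:

1. **Colour indices** — per-ROI channel means are averaged per day, and six
   greenness indices are computed from the daily mean RGB: GCC
   $= G/(R{+}G{+}B)$, RCC, GEI $= 2G-(R{+}B)$, GGR, GRVI and the HSV HUE.
2. **Seasonal model** — the annual trajectory is fitted by the double
   logistic
   $g(t) = w_{min} + (w_{max}-w_{min})\left[\frac{1}{1+e^{-m_S(t-S)}} +
   \frac{1}{1+e^{m_A(t-A)}} - 1\right]$
   with inflection days $S$ (spring) and $A$ (autumn).
3. **Transition dates** — the extrema of the curvature change rate
   $dK/dt$, $K = g''/(1+g'^2)^{3/2}$, mark the start of season (SOS),
   maturity onset (MOE), senescence onset (COS) and end of season (EOS);
   LOS = MOE − SOS.
4. **Forecast** — a gate-equation LSTM (2 stacked layers, 30-day sliding
   windows, residual linear read-out) is trained on the daily index series
   and produces one-step and 60-day recursive forecasts, scored by
   MSE/RMSE/MAE/MAPE with residual and QQ diagnostics.

Because public canopy archives of this kind are rarely deposited, the
package includes a seeded synthetic-archive generator with exact ground
truth (the canopy pixels' GCC *equals* the requested trajectory value), so
the whole pipeline is validated end-to-end by parameter recovery.

It is a tidyverse-style package: data frames in, tibbles out, `tidy()` /
`glance()` / `augment()` on fitted objects, `autoplot()` for each result
type.

## Worked example

Simulate a one-year archive (three frames per day, mild exposure jitter and
day-to-day noise), extract the canopy GCC series, fit the seasonal model
and read off the transition dates:

```r
library(phenocanopy)
library(dplyr)

dir  <- file.path(tempdir(), "archive")
arch <- simulate_image_archive(dir,
  scene = scene_spec(images_per_day = 3, illumination_jitter = 0.03),
  doys = 1:365, noise_sd = 0.004, seed = 42)

daily <- aggregate_daily(extract_roi_means(dir, arch$rois))
gcc   <- compute_indices(daily, "gcc") |> filter(roi == "canopy")

fit <- fit_double_logistic(gcc)
glance(fit)
#> # A tibble: 1 × 3
#>      rmse r_squared     n
#>     <dbl>     <dbl> <int>
#> 1 0.00410     0.994   365

extract_phenophases(fit)
#> # A tibble: 1 × 5
#>     sos   moe   cos   eos   los
#>   <int> <int> <int> <int> <int>
#> 1    66   107   286   338    41
```

The fit explains 99.4% of the variance with an RMSE of 0.004 GCC units —
the injected noise level — and the extracted dates say: green-up starts on
day 66, the canopy is fully mature by day 107 (a 41-day green-up stage),
senescence begins around day 286 and the season ends on day 338. The
generating trajectory had its inflections at days 87 and 312, which the
dates bracket exactly as the curvature geometry predicts
(SOS < S < MOE, COS < A < EOS).

`autoplot(fit, dates = extract_phenophases(fit))` overlays the fitted
curve and the dates on the daily points. For forecasting:

```r
model <- lstm_train(gcc, lstm_config())      # 30-day windows, 70/20/10 split
forecast_metrics(lstm_forecast(model, "onestep", set = "test"))
lstm_forecast(model, "recursive", horizon = 60)  # next 60 days
```

`run_pipeline(pipeline_config(...))` chains every stage (images or a series
CSV in; index CSVs, fit JSONs, a ROI × index date matrix, ROI comparisons,
forecasts and metrics out), and `inst/scripts/phenocanopy.R` wraps it for
the shell. The methods vignette
(`vignettes/canopy-phenology-methods.Rmd`) documents the models,
parameter defaults and limitations.

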