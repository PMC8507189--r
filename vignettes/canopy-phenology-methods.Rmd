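---
title: "Canopy phenology from time-lapse imagery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy phenology from time-lapse imagery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocanopy)
library(dplyr)
```

`phenocanopy` turns an archive of repeat canopy photographs — the
"near-earth remote sensing" setup in which a fixed tower camera images the
same stand many times a day for a year or more — into phenological
quantities: daily colour-index series, a fitted seasonal trajectory,
transition dates, and a short-range forecast. This vignette explains the
models behind each stage, the tunable parameters and the reasoning behind
their defaults, what the synthetic-data generator does and does not emulate,
and the package's known limitations.

## From pixels to daily colour indices

Each frame is reduced to the arithmetic mean of the red, green and blue
channel brightness over one or more fixed regions of interest (ROIs). All
frames of a calendar day are then averaged (the "mean value" step), which
suppresses within-day illumination differences without discarding any
frames; days with no frames remain gaps and are never zero-filled or
imputed. Six colour indices are computed from the daily means
(mean-then-index, not index-then-mean):

| Index | Formula | Range |
|-------|---------|-------|
| GCC   | $G/(R+G+B)$ | $[0,1]$ |
| RCC   | $R/(R+G+B)$ | $[0,1]$ |
| GEI   | $2G-(R+B)$  | $[-510,510]$ |
| GGR   | $G/R$       | $[0,\infty)$ |
| GRVI  | $(G-R)/(G+R)$ | $[-1,1]$ |
| HUE   | HSV hue angle | $[0,360)$ |

GCC, RCC, GRVI and HUE are invariant to a common brightness rescaling of
the three channels, which is why they are robust to exposure changes; GEI
and GGR are not (GGR is ratio-invariant but not offset-robust). Degenerate
denominators (e.g. $R=0$ for GGR, achromatic pixels for HUE) produce a
missing value for that day with a warning, never an error: one bad day
should not kill a year-long series.

HUE follows the standard HSV case analysis on which channel attains the
maximum. Printed index tables in the field sometimes carry a variant whose
wrap-around constant is 340 rather than 360 and whose blue-maximum branch
keeps a $B-R$ numerator; `color_index(..., hue_as_printed = TRUE)`
reproduces that variant verbatim for comparability, but the default is the
standard, continuous hue, cross-checked in the tests against
`grDevices::rgb2hsv()`.

## The seasonal model and its transition dates

The annual trajectory of a greenness index in a deciduous stand is modelled
by the double logistic

$$g(t) = w_{min} + (w_{max}-w_{min})\left[\frac{1}{1+e^{-m_S(t-S)}}
 + \frac{1}{1+e^{\,m_A(t-A)}} - 1\right],$$

with winter baseline $w_{min}$, summer plateau $w_{max}$, spring and autumn
inflection days $S < A$, and rates $m_S, m_A$ (1/day). Printed forms of
this equation vary and are sometimes internally inconsistent; the package
uses this canonical form, which has the defining limits $g \to w_{min}$ in
both winters and $g \approx w_{max}$ at the mid-season plateau.

Fitting is ordinary least squares via Levenberg–Marquardt
(`minpack.lm::nlsLM`). Starting values come from the data (5th/95th
percentiles for $w_{min}/w_{max}$, half-amplitude crossings for $S/A$,
$0.1$/day for both rates) plus five jittered restarts under a fixed seed;
the best converged fit by residual sum of squares wins. The convergence
tolerance is $10^{-12}$ on the relative reduction of the sum of squares.
Irregular or gappy day grids are fitted as-is. A series with no detectable
rise-and-fall (flat, or never crossing half amplitude) is rejected rather
than fitted: every downstream quantity would be meaningless.

Transition dates come from the curvature of the fitted curve,
$K = g''/(1+g'^2)^{3/2}$, computed from analytic derivatives. The *rate of
change* of the signed curvature, $dK/dt$, has three local extrema around
each inflection; following the curvature-change-rate convention used for
satellite phenology, the first extremum before $S$ is the start of season
(SOS), the last after $S$ the maturity onset (MOE), the first before $A$
the senescence onset (COS) and the last after $A$ the end of season (EOS).
The stage length is LOS = MOE − SOS. Two numerical details matter:

* the extrema are located on a fine grid (default step 0.1 day, range
  $[S - 12/m_S,\ A + 12/m_A]$, which provably contains them all) by sign
  changes of the discrete slope, with flat runs inheriting the preceding
  slope so the mid-season plateau cannot spawn spurious extrema, and tiny
  extrema below $10^{-6}$ of the half-season maximum are discarded;
* $dK/dt$ is evaluated on the *signed* curvature. The absolute-value form
  $|K|$ is what the curvature formula reports, but its derivative has
  artificial kinks at zero crossings; the signed form is smooth and its
  extrema are well defined. For a single rising logistic the signed
  curvature is antisymmetric about $S$ and $dK/dt$ is mirror-symmetric —
  a property the test suite verifies numerically.

Because $K$ mixes the units of $t$ (days) and $g$ (index units), the
extremum locations depend on the index's amplitude: a GEI curve (amplitude
tens of units) yields wider SOS–MOE brackets than a GCC curve (amplitude
a few hundredths) with identical $S, A, m_S, m_A$. This is an intrinsic
property of curvature-based extraction, not an artefact; comparisons across
indices should keep it in mind.

An optional smoothing-spline pre-step (`smooth_series()`) is available for
ragged series. Its roughness parameter $p \in (0,1]$ follows the csaps
convention ($p = 1$ interpolates, $p \to 0$ approaches the least-squares
line); internally it maps to `stats::smooth.spline`'s penalty with a
$1/\mathrm{range}(t)^3$ correction so $p$ keeps its meaning in day units.

## The synthetic study conditions

No camera archive ships with the package, so a seeded generator produces
one with known ground truth. `simulate_index_series()` evaluates a
double-logistic trajectory on a DOY grid and adds i.i.d. Gaussian noise on
the index scale. `simulate_image_archive()` renders small PNG frames — a
sky band, a trunk patch and one or more canopy patches — in which the
canopy colour is chosen so its green chromatic coordinate *equals* the
requested trajectory value: red and blue are pinned at a base brightness
$R_0$ and $G = 2R_0\,\mathrm{gcc}/(1-\mathrm{gcc})$, a monotone and exactly
invertible map. Per-frame illumination jitter is multiplicative lognormal
on all three channels, so chromatic indices are unaffected by construction
while raw brightness and GEI vary — mirroring how real exposure variation
acts.

Default conditions: an annual grid of 365 days (or 426 days spanning
fourteen months for forecasting), eleven frames per day (hourly
07:05–17:05), spring inflection day 87 and autumn day 312 with rates
0.11 and 0.09 per day, a GCC range of 0.31–0.43 (GEI 10–70), trajectory
noise of 2% of the amplitude where noise is wanted, and illumination jitter
with log-sd 0.05 (no within-day variance is reported for real archives;
this value gives a visible but not dominant exposure wobble). Multi-ROI
scenes shift $S$ by a few days per canopy patch, emulating micro-environment
differences within one stand.

What the generator deliberately does *not* emulate: weather artefacts
(fog, rain drops, snow on the lens), camera shake or drift (real pipelines
register frames first; the package accepts pre-registered images), mixed
pixels at canopy boundaries, and sensor noise beyond 8-bit quantisation.
Passing tests on synthetic archives therefore demonstrate the correctness
of the *computation* — extraction, aggregation, index algebra, fitting,
extraction of dates, forecasting — not robustness to dirty optics.

## The LSTM forecaster

The forecaster is a stacked (depth 2) long short-term memory network
written out at equation level, on the concatenated vector $[h_{t-1}, x_t]$:

$$f_t = \sigma(W_f[h_{t-1},x_t]+b_f),\quad
  i_t = \sigma(W_i[h_{t-1},x_t]+b_i),$$
$$\bar C_t = \tanh(W_c[h_{t-1},x_t]+b_c),\quad
  C_t = f_t \odot C_{t-1} + i_t \odot \bar C_t,$$
$$o_t = \sigma(W_o[h_{t-1},x_t]+b_o),\quad
  h_t = o_t \odot \tanh(C_t).$$

The series is min–max normalised to $[0,1]$ (the scale record is kept and
inverted for all reported predictions), cut into 30-day sliding windows
whose next day is the target — windows never span a gap in the daily record
— and split chronologically 70/20/10 into training, test and validation
windows with no shuffling across the boundaries. The scalar prediction is
a linear read-out over the last hidden vector *and* the last input,
$\hat y = w^\top h_T + a\,x_T + b$ — a residual head, an addition of this
package (descriptions of the architecture leave the output head
unspecified). Following residual-network practice the head is initialised
at the identity mapping, $a = 1$ with $w, b$ small, so the untrained model
is exactly the persistence baseline ("tomorrow equals today") and training
learns corrections to it through the gated cell. Cell weights are
initialised uniformly on $[-0.01, 0.01]$ and trained per-sample in
sequence on the squared one-step-ahead error, with backpropagation through
time; the training loop is compiled (RcppArmadillo) with all randomness —
initialisation and per-epoch sample order — drawn from R's RNG under the
configuration seed, so training is bit-reproducible. An R-level mini-batch
trainer with identical mathematics is used when `batch_size > 1`.

The learning rate is $10^{-5}$, decaying exponentially per epoch. Two
design choices around it deserve explanation:

* **Optimiser.** With plain gradient descent at $10^{-5}$ and weights
  initialised at $\pm 0.01$, the total parameter displacement available
  under any realistic epoch budget is orders of magnitude short of a
  trained network — the model cannot leave its initialisation and the
  training loss stays at the variance of the target. Adam's
  gradient-normalised steps make the same nominal learning rate effective,
  so Adam is the default (`optimizer = "sgd"` retains the plain form).
* **Epochs.** Per-parameter movement under Adam is bounded by the learning
  rate times the number of updates, so the epoch budget — not the optimum
  of the loss — is what limits how far training gets. The default epoch
  count is chosen so the training loss has plateaued on the package's
  synthetic study conditions; the forecast-quality checks in the test
  suite run at exactly these defaults.

The identity initialisation is not cosmetic. On a *noise-free* seasonal
series the training windows (winter, rise, plateau) admit many
train-perfect solutions, most of which memorise the seasonal pattern
rather than follow the input; gradient training under the fixed small
learning rate reliably converges to one of those and then stops, and such
a solution fails badly on the chronologically held-out autumn decline —
its one-step errors there are an order of magnitude larger than the
persistence baseline's, regardless of hidden size, epoch budget or batch
size. Starting from the persistence baseline
removes that degeneracy: the model begins at the natural next-day
predictor and training can only improve on it. Consequently, the forecast
checks in the test suite demonstrate that training *preserves and refines*
an input-following predictor under the stated optimisation regime — not
that the network discovers forecasting from a blank slate.

One-step ("teacher-forced") evaluation predicts each held-out day from its
30 observed predecessors; recursive forecasting feeds each prediction back
for a 60-day horizon. The chronological split makes the test segment the
autumn decline, a regime the training windows barely contain — an honest
extrapolation test: a network that merely memorises the seasonal pattern
fails it, while one that follows its input generalises.

Forecast quality is summarised by MSE, RMSE = $\sqrt{\mathrm{MSE}}$, MAE
and MAPE (in percent). The mean *signed* error is reported separately as
`bias`; MAPE is undefined and reported `NA` when any true value is zero.
Residual and normal-QQ arrays (plotting positions $(i-0.5)/n$ on
standardised residuals) support the usual diagnostics.

## Problem sizes used in the checks

The package's own validation runs at deliberately modest sizes: 64×48-pixel
frames with two frames per day for the full-year image round trip (the
image computation is resolution-independent: ROI means are averages, so a
small frame exercises the same code path as a 2560×1440 one), 100
replicates for the noisy parameter-recovery study, and one LSTM training
run at the default configuration on the 14-month clean series. These
choices keep the full suite in the minutes range on a single CPU while
leaving every algorithmic path exercised.

## Known limitations

* Curvature-based dates are amplitude-dependent (see above); indices should
  be compared on a common scale if their dates are to be compared.
* The forecaster is univariate: no temperature, precipitation or
  photoperiod covariates, no uncertainty intervals on forecasts.
* Image registration, exposure correction and bad-frame screening are out
  of scope; the extractor assumes a stable, pre-registered archive.
* The LSTM's learning-rate/initialisation regime (fixed by the study
  conditions) trains slowly by modern standards; the compiled trainer makes
  it practical, but the configuration is not tuned for speed-optimal
  convergence.
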