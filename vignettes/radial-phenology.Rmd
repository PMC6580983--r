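---
title: "Radial encoding of phenocam greenness series: models, conventions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial encoding of phenocam greenness series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoring)
```

## What the package computes

Near-surface phenology monitors recurrent leaf events — flushing, expansion,
senescence — by pointing a fixed camera at vegetation and reducing each
day's image to chromatic vegetation indices over polygonal regions of
interest (ROIs). The green chromatic coordinate

$$Gcc = \frac{\bar G}{\bar R + \bar G + \bar B}$$

is the normalized green fraction of the ROI and tracks canopy greenness
through the seasonal cycle. Because these series are cyclical with no
natural origin (especially in tropical systems with no dormant season),
`phenoring` displays them on a circle: angle encodes position in the year,
concentric rings encode either the variables of one year or the years of
one variable, and cell color encodes the value.

This vignette documents the models, the fixed conventions, the tunable
parameters, and the design choices that were genuinely open.

## Chromatic coordinates: ratio of means

`chromatic_coordinates()` averages each channel over the masked pixels
*first* and then normalizes (ratio-of-means), rather than averaging
per-pixel ratios. The two conventions differ observably: for a two-pixel
region {(100, 200, 0), (200, 0, 0)} the channel means are (150, 100, 0), so
ratio-of-means gives $gcc = 100/250 = 0.4$ while mean-of-ratios would give
$1/3$. Ratio-of-means is the standard in phenocam processing chains and is
what the test-suite pins down. The result is invariant under uniform
brightness scaling — multiplying all channels by $k > 0$ cancels in the
ratio — which we assert for $k \le 1$: beyond saturation (a channel clipped
at 255) the premise of a pure gain change no longer holds.

A totally black region has an undefined ratio and yields missing, as does a
day with no usable frame after compositing.

## ROI rasterization

`rasterize_roi()` uses pixel-center even-odd (crossing-number) semantics:
a pixel belongs to the mask exactly when its center lies inside the
polygon. Coordinates are 0-based, origin top-left, x rightward, y downward,
and the center of pixel (column $i$, row $j$) is at $(i, j)$. These
conventions are load-bearing — ROI files are interchanged between tools —
so they are stated here and frozen by tests, including a comparison of mask
areas against an independent point-in-polygon implementation on random
convex polygons. Self-intersecting polygons are rejected outright: under
even-odd semantics they would silently punch holes in the mask and make the
"crown area" ambiguous. An ROI that covers no pixel center is an error, not
an empty series.

## Daily compositing

With several frames per day, `daily_composite()` reduces the within-day
samples by `mean` (default), `median`, or a percentile with linear
interpolation between order statistics (so the 90th percentile of
{0.1, ..., 0.5} is 0.46). High percentiles are widely used in the phenocam
literature to suppress illumination and weather noise; the choice is left
to the user because different processing chains legitimately differ here.
Missing samples are ignored; an all-missing day stays missing.

## Timescales and binning

`resample_table()` aggregates the daily table to the display granularity:

* **daily** — one bin per calendar day (365, or 366 in leap years);
* **weekly** — blocks of 7 consecutive doys anchored at doy 1, 53 bins per
  year, the last holding the 1–2 remainder days. These are doy-blocks, not
  ISO weeks: ISO weeks straddle year boundaries, which would break the
  one-ring-per-year model;
* **monthly** — calendar months, 12 bins; doy 366 belongs to December.

The bin statistic is the mean of non-missing daily values — the simplest
faithful default; nothing in the display model depends on it being robust.
Bins are enumerated for the *whole* year of every year present, so a sparse
series (e.g. monthly ground observations) still produces a complete ring
with missing cells where there is no datum. No gap-filling, smoothing or
interpolation is done anywhere.

The month containing a doy is derived by base Date arithmetic and checked,
for every year 1900–2100, against an independent cumulative-month-length
enumeration in the test-suite.

## The radial scene model

`build_scene()` is a pure function from (table, config) to a
resolution-independent scene: ring radii, annular cells with angular
extents, values, normalized values and fill colors, month labels, and a
per-variable legend. Rendering is a separate, stateless step
(`render_scene()`, PDF vector or PNG raster), and scenes serialize to
deterministic JSON for golden-file comparison.

Fixed conventions, chosen once where the display model was open:

* **Angular origin and direction.** 1 January at 12 o'clock, clockwise —
  the calendar-clock convention common in phenology diagrams.
* **Segment widths.** Monthly segments are equal-width 30°, read literally
  from the twelve-segment design, rather than day-count-proportional;
  daily segments are equal-width within a year, so leap-year cells are
  very slightly narrower.
* **Ring order.** Innermost ring = first selected variable (variables
  mode) or earliest year (years mode). Arbitrary but fixed and documented.
* **Value encoding.** Color-filled annular cells (a "heat ring"), the
  robust reading of a segments-and-circles design; magnitude is not
  additionally encoded radially.
* **Normalization.** Per variable, min–max over *all* loaded bins of all
  years, so a given value has the same color on every ring of its variable
  — the property that makes cross-year comparison meaningful. A constant
  variable maps to 0.5 (mid-scale) rather than an arbitrary endpoint;
  missing stays missing and is drawn in `missing_color` (light gray by
  default).
* **Colormap.** A perceptually uniform sequential palette
  (`grDevices::hcl.colors`, "Viridis" by default), configurable.
* **Ring geometry.** Rings share equal radial thickness between
  `inner_hole_fraction` (default 0.25, range [0, 0.9]) and the outer
  radius. The hole keeps innermost cells from degenerating to slivers, a
  known legibility limit of multi-ring radial displays that this package
  does not otherwise attempt to solve.

`ring_mode = "years"` (the all-years view) requires exactly one variable;
year navigation (`next_year()` / `previous_year()`, or `--year` and
`--all-years-grid` in the CLI) saturates at the ends of the available range
rather than wrapping.

## Camera-vs-ground comparison

`build_comparison_scene()` renders ground-observation variables as
additional rings, flagged in the ring label and legend and normalized
independently of the camera variables (a phenophase-activity proportion and
a chromatic index do not share a scale). Ground series keep their native,
coarser resolution: they are binned at `ground_timescale` (default
monthly), so a monthly ground ring shows 12 cells beside a 365-cell daily
camera ring. We made the native cadence an explicit argument rather than
inferring it from the data — inference from gap patterns is fragile exactly
when data are sparse. A table containing only ground variables renders as a
ground-only scene.

## The synthetic-data generator

The generator exists so that every stage is testable against known ground
truth without downloads; it is first-class, tested code.

* **Seasonal curve.** `double_logistic()` is the de facto phenocam
  greenness model: baseline $b$, amplitude $a$, green-up and senescence
  inflections $t_g$, $t_s$ (doy) with rates $k_g$, $k_s$ (per day),
  $$g(t) = b + a\left[\mathrm{logit}^{-1}(k_g(t - t_g)) -
  \mathrm{logit}^{-1}(k_s(t - t_s))\right].$$
  Defaults emulate a seasonal savanna crown: baseline 0.33 (chromatic
  coordinates hover near 1/3), amplitude 0.08, green-up around doy 120,
  senescence around doy 280, transitions of a few weeks, additive Gaussian
  daily noise with sd 0.005, clipped to [0, 1]. The four-species demo set
  varies baseline (0.32–0.35), amplitude (0.04–0.10) and timing to mimic
  distinct leaf-exchange strategies. These values were chosen once as
  realistic and are not tuned to any test.
* **Noise model.** Additive white Gaussian noise only — sufficient to
  exercise aggregation and display. Real Gcc series have autocorrelated
  weather artifacts, exposure drift and snow/fog excursions; passing tests
  on synthetic data therefore demonstrate correctness of the pipeline's
  arithmetic and plumbing, not robustness to such artifacts.
* **Ground observations.** `gen_ground_obs()` simulates a cohort of
  individuals with jittered parameters and records, at monthly or biweekly
  cadence, the proportion whose noise-free curve exceeds an activity
  threshold — the shape of a traditional phenology scoring campaign.
* **Frames.** `gen_frames()` paints each ROI with the brightest 8-bit RGB
  triple whose chromatic coordinates match the day's target Gcc (the
  non-green remainder splits red/blue as `rcc_fraction` = 0.55 by default,
  reflecting the red-shifted background of senesced canopies) on a neutral
  gray background. Rounding to 8 bits perturbs the realized coordinate by
  less than 2/255, which is the closed-loop error bound the extraction
  stage is held to: generate → extract recovers every target within 2/255
  across 4 ROIs × 120 days. Overlapping ROIs are refused because they make
  the per-ROI ground truth ambiguous.
* **Determinism.** Every random stream is an explicit seed parameter; no
  global RNG state leaks in or out (`with_seed` saves and restores
  `.Random.seed`). The materialized fixture set is byte-stable per seed.

## Numerical choices and degenerate inputs

* CSV values are written with the fewest significant digits (15–17) that
  reproduce the stored double exactly, so write→read is an identity at
  full precision; missing cells are empty fields.
* Duplicate (year, doy) rows in one file are a hard error — upstream
  compositing should have produced one value per day — as is a `month`
  column inconsistent with (year, doy): with no stated resolution rule, we
  refuse to guess which is right.
* Merging tables unions keys and variables; the same variable from two
  files must agree wherever keys overlap, else a conflict error names the
  key and variable. No averaging.
* Angular tiling is exact to floating tolerance: per ring the segment
  widths sum to $2\pi$ within $10^{-9}$ with no overlap, verified for
  every timescale over leap and non-leap years.
* Chromatic triples satisfy $rcc + gcc + bcc = 1$ within $10^{-9}$
  whenever defined.

## Problem sizes in the checks

The shipped verification uses desk-scale inputs chosen to exercise every
code path: the four-variable demo table over 2012–2015 (1461 daily
records), scenes at all three timescales, 1000 random masked images for
the chromatic identity, a 4-ROI × 120-day closed extraction loop on
120 × 90 px frames, 100 random tables for CSV round-trips, and the full
1900–2100 calendar sweep for month derivation. Larger inputs change
nothing structurally: all operations are linear in days × variables ×
pixels.

## Known limitations

* Inner rings of many-ring scenes are small; legibility of dense daily
  cells near the hub is limited by geometry.
* No camera calibration, exposure correction, fisheye de-warping or
  sun-angle filtering; frames are taken as given.
* No circular statistics or phenological metrics (mean date, concentration,
  onset/peak estimation) — the package visualizes; it does not yet
  summarize seasonality.
* No gap-filling or smoothing; what is missing stays visibly missing.
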