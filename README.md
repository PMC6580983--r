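# phenoring

Radial layouts for near-surface phenology time series.

## The problem

Phenocams — fixed digital cameras photographing vegetation daily — have
become a standard instrument for monitoring leaf phenology. Each camera
yields, per monitored tree crown, a daily greenness series: the **green
chromatic coordinate**

```
Gcc = Ḡ / (R̄ + Ḡ + B̄)
```

where R̄, Ḡ, B̄ are the mean red/green/blue digital numbers over a polygonal
region of interest (ROI) drawn around the crown. These series are long,
multivariate (several species or crowns per camera) and above all
*cyclical*: in tropical vegetation such as the Brazilian Cerrado there is no
dormant season and no natural start date, so plotting them on a straight
time axis obscures exactly the recurrence one wants to see.

`phenoring` encodes such series as **radial layouts**: one full turn of the
circle is one year (1 January at 12 o'clock, clockwise), concentric rings
carry either the different variables of one year or the successive years of
one variable, and each ring is tiled by angular segments — 12 monthly, 53
weekly, or 365/366 daily cells — colored by the (per-variable min-max
normalized) value. Ground-based visual observations can be drawn as
additional rings at their own, coarser cadence next to the daily camera
rings, for direct camera-vs-ground intercomparison.

The package covers the whole path from pixels to figure:

| stage | functions |
|---|---|
| CSV time-series I/O (`year,month,doy,` + variables) | `read_pheno_csv`, `write_pheno_csv`, `merge_tables`, `filter_table` |
| ROI → chromatic indices from RGB frames | `roi_polygon`, `rasterize_roi`, `chromatic_coordinates`, `daily_composite`, `extract_series` |
| timescale aggregation | `resample_table` (daily / weekly / monthly) |
| radial scenes and rendering | `layout_config`, `build_scene`, `build_comparison_scene`, `next_year`/`previous_year`, `render_scene`, `scene_to_json` |
| synthetic data with known ground truth | `seasonal_params`, `double_logistic`, `gen_gcc_table`, `gen_ground_obs`, `gen_frames`, `make_fixtures` |
| batch CLI | `phenoring_main`; script at `inst/cli/phenoring` (subcommands `view`, `extract`, `make-fixtures`) |

## Worked example

```r
library(phenoring)

# deterministic demo set: four savanna species, 2012-2015, daily Gcc
fx  <- make_fixtures("demo_fixtures", seed = 1)
tab <- read_pheno_csv(fx$gcc_csv)
tab
#> <pheno_table> 1461 record(s), 4 variable(s): gcc_aspido, gcc_cary, gcc_mic, gcc_pout
#>   years 2012-2015
#> # A tibble: 1,461 x 7
#>    year month   doy gcc_aspido gcc_cary gcc_mic gcc_pout
#>  1 2012     1     1      0.313    0.343   0.327    0.351
#>  2 2012     1     2      0.328    0.339   0.339    0.359
#>  ...

# monthly bins of one species for one year
resample_table(filter_table(tab, years = 2013, variables = "gcc_mic"), "monthly")
#> <pheno_bins> timescale=monthly, 12 bin-row(s), variables: gcc_mic
#>   year   bin doy_start doy_end n_days gcc_mic
#> 1 2013     1         1      31     31   0.330
#> 2 2013     2        32      59     28   0.329
#> 3 2013     3        60      90     31   0.338
#>  ...

# all-years view: one ring per year, 12 monthly segments each
scene <- build_scene(tab, layout_config(ring_mode = "years",
                                        timescale = "monthly",
                                        variables = "gcc_mic",
                                        species = "Miconia", roi = "mic"))
scene
#> <radial_scene> 4 ring(s), 48 cell(s): 2012, 2013, 2014, 2015
render_scene(scene, "Miconia_mic_2012-2015.pdf")
```

The 1461 records are the four calendar years 2012–2015 (366 + 3 × 365
days); the 48 cells are 4 year-rings × 12 monthly segments. The dry-season
trough near Gcc ≈ 0.33 and the wet-season rise of `gcc_mic` show up as the
dark-to-bright sweep of each ring.

The same figure from the shell:

```sh
inst/cli/phenoring make-fixtures --out demo_fixtures --seed 1
inst/cli/phenoring view --in demo_fixtures/gcc_demo.csv --vars gcc_mic \
    --ring-mode years --timescale monthly --out mic.pdf
inst/cli/phenoring extract --frames-dir demo_fixtures/frames \
    --roi-file demo_fixtures/rois.json --out extracted.csv
```

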