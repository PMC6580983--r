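#' Double-logistic seasonal greenness parameters
#'
#' The de facto model for annual greenness (Gcc) trajectories in phenocam
#' work: a baseline dry-season level, a green-up logistic rising at
#' `t_green` and a senescence logistic falling at `t_sen`,
#' \deqn{g(t) = b + a\left[\frac{1}{1+e^{-k_g (t-t_g)}} -
#'   \frac{1}{1+e^{-k_s (t-t_s)}}\right].}
#' Units: `baseline` and `amplitude` are Gcc fractions (so
#' `baseline + amplitude <= 1`); `t_green`/`t_sen` are doys; `k_green`/
#' `k_sen` are per-day logistic rates; `noise_sd` is the standard deviation
#' of additive Gaussian daily noise.
#'
#' The defaults emulate a seasonal savanna crown: trough Gcc around 0.33
#' (chromatic coordinates hover near 1/3), seasonal range 0.08, green-up in
#' the early wet season and senescence at the onset of the dry season,
#' transitions of a few weeks, and day-to-day noise of 0.005.
#'
#' @param baseline dry-season Gcc level
#' @param amplitude seasonal Gcc range
#' @param t_green,t_sen green-up / senescence inflection doys
#' @param k_green,k_sen logistic steepness (per day), positive
#' @param noise_sd additive noise standard deviation, non-negative
#' @param seed integer seed for this variable's noise stream
#' @return a `seasonal_params` list
#' @export
seasonal_params <- function(baseline = 0.33, amplitude = 0.08,
                            t_green = 120, t_sen = 280,
                            k_green = 0.15, k_sen = 0.12,
                            noise_sd = 0.005, seed = 1L) {
  ph_assert(baseline >= 0 && baseline + amplitude <= 1,
            "need baseline >= 0 and baseline + amplitude <= 1 (Gcc is a proportion)",
            "phenoring_parameter")
  ph_assert(k_green > 0 && k_sen > 0, "logistic rates must be positive",
            "phenoring_parameter")
  ph_assert(noise_sd >= 0, "noise_sd must be non-negative", "phenoring_parameter")
  structure(list(baseline = baseline, amplitude = amplitude,
                 t_green = t_green, t_sen = t_sen,
                 k_green = k_green, k_sen = k_sen,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "seasonal_params")
}

#' Noise-free double-logistic greenness curve
#'
#' @param doy day of year, 1-366 (vectorized)
#' @param p a [seasonal_params()]
#' @return Gcc value(s)
#' @export
double_logistic <- function(doy, p) {
  ph_assert(all(doy >= 1 & doy <= 366), "doy must lie in 1..366",
            "phenoring_parameter")
  p$baseline + p$amplitude *
    (stats::plogis(p$k_green * (doy - p$t_green)) -
       stats::plogis(p$k_sen * (doy - p$t_sen)))
}

#' Generate a synthetic daily Gcc table
#'
#' Daily values are the double-logistic curve plus seeded additive Gaussian
#' noise, clipped to [0, 1]; one record per calendar day of each year
#' (365/366). Fully deterministic given the per-variable seeds.
#'
#' @param years integer vector of years
#' @param params named list: variable name -> [seasonal_params()]
#' @return a [pheno_table()]
#' @export
gen_gcc_table <- function(years, params) {
  ph_assert(length(years) >= 1, "need at least one year", "phenoring_parameter")
  ph_assert(is.list(params) && length(params) >= 1 && !is.null(names(params)),
            "params must be a named list of seasonal_params", "phenoring_parameter")
  years <- sort(as.integer(years))
  grid <- bind_rows(lapply(years, function(y) {
    tibble(year = y, doy = seq_len(days_in_year(y)))
  }))
  for (v in names(params)) {
    p <- params[[v]]
    mu <- double_logistic(grid$doy, p)
    noise <- if (p$noise_sd > 0) {
      with_seed(p$seed, stats::rnorm(nrow(grid), 0, p$noise_sd))
    } else rep(0, nrow(grid))
    grid[[v]] <- pmin(pmax(mu + noise, 0), 1)
  }
  pheno_table(grid, variables = names(params))
}

#' Generate a synthetic ground-observation series
#'
#' Emulates traditional on-the-ground phenology scoring: a cohort of
#' individuals with jittered seasonal parameters is simulated, and at each
#' observation date the recorded value is the proportion of individuals
#' whose noise-free greenness curve exceeds `threshold` (a
#' phenophase-activity index in [0, 1]). Cadence is coarser than daily:
#' monthly (mid-month, 12 records/year) or biweekly (every 14 days from doy
#' 8, 26 records/year).
#'
#' @param years integer vector of years
#' @param cadence `"monthly"` or `"biweekly"`
#' @param params a [seasonal_params()] for the population mean curve
#' @param threshold activity threshold on the Gcc scale, in (0, 1)
#' @param n_individuals cohort size
#' @param var_name output variable name
#' @return a [pheno_table()] with the variable flagged as a ground series
#' @export
gen_ground_obs <- function(years, cadence = c("monthly", "biweekly"),
                           params = seasonal_params(), threshold = 0.36,
                           n_individuals = 10L, var_name = "ground_activity") {
  cadence <- match.arg(cadence)
  ph_assert(threshold > 0 && threshold < 1, "threshold must lie in (0, 1)",
            "phenoring_parameter")
  years <- sort(as.integer(years))

  cohort <- with_seed(params$seed + 1L, lapply(seq_len(n_individuals), function(i) {
    seasonal_params(
      baseline = params$baseline * stats::runif(1, 0.97, 1.03),
      amplitude = params$amplitude * stats::runif(1, 0.9, 1.1),
      t_green = params$t_green + stats::rnorm(1, 0, 8),
      t_sen = params$t_sen + stats::rnorm(1, 0, 8),
      k_green = params$k_green, k_sen = params$k_sen,
      noise_sd = 0, seed = params$seed + i
    )
  }))

  rows <- bind_rows(lapply(years, function(y) {
    doys <- switch(cadence,
      monthly = vapply(1:12, function(m) {
        mdays <- which(month_from_doy(rep(y, days_in_year(y)),
                                      seq_len(days_in_year(y))) == m)
        as.integer(round(stats::median(mdays)))
      }, integer(1)),
      biweekly = seq(8L, days_in_year(y), by = 14L)
    )
    act <- vapply(doys, function(d) {
      mean(vapply(cohort, function(ind) double_logistic(d, ind) >= threshold,
                  logical(1)))
    }, numeric(1))
    tibble(year = y, doy = doys, value = act)
  }))
  names(rows)[names(rows) == "value"] <- var_name
  pheno_table(rows, variables = var_name, ground_vars = var_name)
}

#' Generate synthetic phenocam frames with known Gcc ground truth
#'
#' Each ROI's pixels are painted a uniform RGB color whose chromatic
#' coordinates equal that day's target up to 8-bit rounding; the background
#' is a neutral mid-gray. The extraction stage therefore recovers the
#' targets to within 2/255, which closes the generator-extractor loop used
#' throughout the test-suite.
#'
#' @param days data frame (or tibble) with columns `year`, `doy`
#' @param rois list of [roi_polygon()]s; must not overlap (overlap would
#'   make the ground truth ambiguous)
#' @param targets function `(roi_name, year, doy) -> gcc target in (0, 1)`,
#'   or a named list `roi_name -> numeric vector along days`
#' @param frame_size `c(width, height)` in pixels
#' @param rcc_fraction how the non-green remainder splits between red and
#'   blue: rcc = (1 - gcc) * rcc_fraction
#' @return list of frames as consumed by [extract_series()], each with
#'   fields `year`, `doy`, `seq`, `image`, plus a `targets` attribute
#'   (tibble of the exact per-day, per-ROI targets)
#' @export
gen_frames <- function(days, rois, targets, frame_size = c(120, 90),
                       rcc_fraction = 0.55) {
  days <- as_tibble(days)
  ph_assert(all(c("year", "doy") %in% names(days)),
            "days needs 'year' and 'doy' columns", "phenoring_parameter")
  width <- frame_size[1]; height <- frame_size[2]
  masks <- lapply(rois, rasterize_roi, width = width, height = height)
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(overlap > 1)) {
    ph_stop("ROIs overlap: ground-truth Gcc would be ambiguous",
            "phenoring_geometry")
  }
  target_of <- if (is.function(targets)) {
    targets
  } else {
    function(name, year, doy) {
      i <- which(days$year == year & days$doy == doy)[1]
      targets[[name]][i]
    }
  }

  truth <- list()
  frames <- lapply(seq_len(nrow(days)), function(i) {
    img <- array(128, dim = c(height, width, 3)) # neutral background
    for (k in seq_along(rois)) {
      g <- target_of(rois[[k]]$name, days$year[i], days$doy[i])
      ph_assert(g > 0 && g < 1, "gcc targets must lie in (0, 1)",
                "phenoring_parameter")
      rgb <- gcc_to_rgb(g, rcc_fraction)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[masks[[k]]] <- rgb[ch]
        img[, , ch] <- plane
      }
      truth[[length(truth) + 1]] <<- tibble(
        year = days$year[i], doy = days$doy[i], roi = rois[[k]]$name, gcc = g)
    }
    list(year = days$year[i], doy = days$doy[i], seq = 1L, image = img)
  })
  attr(frames, "targets") <- bind_rows(truth)
  frames
}

# pick the brightest 8-bit RGB triple whose chromatic coordinates hit the
# requested gcc (and rcc_fraction split) up to rounding
gcc_to_rgb <- function(gcc, rcc_fraction = 0.55) {
  cc <- c(r = (1 - gcc) * rcc_fraction, g = gcc, b = (1 - gcc) * (1 - rcc_fraction))
  s <- floor(255 / max(cc))
  round(cc * s)
}

#' Write frames to a directory of PNG files
#'
#' Files are named `frame_<year>_<doy>_<seq>.png`, matching the default
#' timestamp pattern of [read_frames_dir()].
#'
#' @param frames list of frames from [gen_frames()]
#' @param dir output directory (created if needed)
#' @return character vector of file paths, invisibly
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(frames, function(f) {
    p <- file.path(dir, sprintf("frame_%04d_%03d_%d.png", f$year, f$doy, f$seq))
    write_rgb_png(f$image, p)
    p
  }, character(1))
  invisible(paths)
}

#' Materialize the full demo fixture set
#'
#' Writes, deterministically per seed, a complete worked dataset into
#' `out_dir`: a four-species daily Gcc CSV spanning 2012-2015 (1461 rows),
#' a monthly ground-observation CSV, an ROI JSON with four crown polygons,
#' and a month of synthetic frames for those ROIs.
#'
#' @param out_dir output directory
#' @param seed integer seed driving every random stream
#' @param years years to simulate
#' @param n_frame_days how many days of synthetic frames to write
#' @return named list of the paths written
#' @export
make_fixtures <- function(out_dir, seed = 1L, years = 2012:2015,
                          n_frame_days = 30L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  species <- demo_species_params(seed)
  tab <- gen_gcc_table(years, species)
  csv_path <- file.path(out_dir, "gcc_demo.csv")
  write_pheno_csv(tab, csv_path)

  ground <- gen_ground_obs(years, "monthly",
                           params = species[[1]], threshold = 0.36,
                           var_name = "ground_flush")
  ground_path <- file.path(out_dir, "ground_demo.csv")
  write_pheno_csv(ground, ground_path)

  rois <- demo_rois()
  roi_path <- file.path(out_dir, "rois.json")
  write_roi_json(rois, roi_path)

  frame_days <- tibble(year = years[1],
                       doy = seq(1L, by = 12L, length.out = n_frame_days))
  targets <- lapply(species, function(p) double_logistic(frame_days$doy, p))
  names(targets) <- sub("^gcc_", "", names(species))
  frames <- gen_frames(frame_days, rois, targets)
  frames_dir <- file.path(out_dir, "frames")
  write_frames(frames, frames_dir)

  list(gcc_csv = csv_path, ground_csv = ground_path,
       roi_json = roi_path, frames_dir = frames_dir)
}

# the four-crown demo parameter set: distinct leaf-exchange strategies
# (differing amplitude and timing) on a shared savanna seasonal template
demo_species_params <- function(seed = 1L) {
  list(
    gcc_aspido = seasonal_params(baseline = 0.32, amplitude = 0.10,
                                 t_green = 110, t_sen = 270, seed = seed + 11L),
    gcc_cary = seasonal_params(baseline = 0.34, amplitude = 0.06,
                               t_green = 130, t_sen = 300, seed = seed + 12L),
    gcc_mic = seasonal_params(baseline = 0.33, amplitude = 0.08,
                              t_green = 95, t_sen = 285, seed = seed + 13L),
    gcc_pout = seasonal_params(baseline = 0.35, amplitude = 0.04,
                               t_green = 140, t_sen = 260, seed = seed + 14L)
  )
}

# four non-overlapping crown polygons in a 120x90 frame
demo_rois <- function() {
  list(
    roi_polygon("aspido", rbind(c(5, 5), c(50, 5), c(50, 40), c(5, 40))),
    roi_polygon("cary", rbind(c(65, 5), c(110, 5), c(110, 40), c(65, 40))),
    roi_polygon("mic", rbind(c(5, 50), c(50, 50), c(50, 85), c(5, 85))),
    roi_polygon("pout", rbind(c(65, 50), c(110, 50), c(110, 85), c(65, 85)))
  )
}
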