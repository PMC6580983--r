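#' Radial layout configuration
#'
#' Controls how a binned phenology series is mapped onto concentric rings.
#' Fixed conventions (declared because the encoding must be reproducible):
#' the angular origin is 12 o'clock = 1 January, angles run clockwise, one
#' full turn is one year; rings share equal radial thickness between
#' `inner_hole_fraction` and 1; values are min-max normalized per variable
#' across all loaded bins of all years, so a given value has the same color
#' on every ring of its variable.
#'
#' @param ring_mode `"variables"` (one ring per variable for one displayed
#'   year) or `"years"` (one ring per year, single variable; the all-years
#'   view)
#' @param timescale `"daily"`, `"weekly"` or `"monthly"` — 366/365, 53 or 12
#'   angular segments per ring
#' @param displayed_year the year shown when `ring_mode = "variables"`
#' @param variables ordered variable names to display (`NULL` = all)
#' @param colormap name of a sequential palette understood by
#'   [grDevices::hcl.colors()]; the default is perceptually uniform
#' @param missing_color fill for bins with no data
#' @param inner_hole_fraction radius of the empty center, as a fraction of
#'   the outer radius, in [0, 0.9]
#' @param species,roi,title text labels; `species` and `roi` also name
#'   output files
#' @return a `layout_config` list
#' @export
layout_config <- function(ring_mode = c("variables", "years"),
                          timescale = c("monthly", "weekly", "daily"),
                          displayed_year = NULL,
                          variables = NULL,
                          colormap = "Viridis",
                          missing_color = "grey85",
                          inner_hole_fraction = 0.25,
                          species = NULL, roi = NULL, title = NULL) {
  ring_mode <- match.arg(ring_mode)
  timescale <- match.arg(timescale)
  ph_assert(is.numeric(inner_hole_fraction) &&
              inner_hole_fraction >= 0 && inner_hole_fraction <= 0.9,
            "inner_hole_fraction must lie in [0, 0.9]", "phenoring_config")
  structure(list(
    ring_mode = ring_mode, timescale = timescale,
    displayed_year = if (!is.null(displayed_year)) as.integer(displayed_year),
    variables = variables, colormap = colormap,
    missing_color = missing_color,
    inner_hole_fraction = inner_hole_fraction,
    angle_origin = "top", direction = "clockwise",
    species = species, roi = roi, title = title
  ), class = "layout_config")
}

#' Angular extent of a time bin
#'
#' Bins partition the full turn uniformly: bin i of n (0-based) spans
#' angles `[2*pi*i/n, 2*pi*(i+1)/n)`, measured clockwise from the top
#' (12 o'clock = 1 January). Monthly segments are equal-width 30 degrees
#' regardless of month length; daily segments are equal-width within a year,
#' so leap-year cells are slightly narrower.
#'
#' @param bin_index 0-based bin index
#' @param bins_in_year total bins in the ring's year
#' @return numeric vector `c(theta_start, theta_end)` in radians
#' @export
angle_for_bin <- function(bin_index, bins_in_year) {
  ph_assert(bins_in_year >= 1, "bins_in_year must be positive", "phenoring_index")
  if (any(bin_index < 0 | bin_index >= bins_in_year)) {
    ph_stop(sprintf("bin_index %d out of range [0, %d)",
                    bin_index[bin_index < 0 | bin_index >= bins_in_year][1],
                    bins_in_year), "phenoring_index")
  }
  c(theta_start = 2 * pi * bin_index / bins_in_year,
    theta_end = 2 * pi * (bin_index + 1) / bins_in_year)
}

#' Min-max normalize values to [0, 1]
#'
#' The normalization that backs the shared color scale: per variable over
#' all loaded bins (all years), v maps to (v - vmin) / (vmax - vmin). A
#' constant variable maps to 0.5 everywhere; missing stays missing.
#'
#' @param x numeric vector (one variable's bin values, all years)
#' @return numeric vector in [0, 1] with `NA`s preserved
#' @export
normalize_values <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  vmin <- min(x[ok]); vmax <- max(x[ok])
  if (vmax == vmin) {
    x[ok] <- 0.5
    return(x)
  }
  (x - vmin) / (vmax - vmin)
}

#' Build a radial scene from a phenology table
#'
#' Maps the table onto a resolution-independent scene of concentric rings
#' tiled by annular cells. With `ring_mode = "variables"` each selected
#' variable is one ring (innermost = first variable) for `displayed_year`;
#' with `ring_mode = "years"` each year is one ring (innermost = earliest)
#' for a single variable — the all-years view. Cell fills come from the
#' colormap applied to the per-variable min-max normalization over all
#' loaded years; missing bins get `missing_color`.
#'
#' @param table a [pheno_table()] (resampled internally to
#'   `config$timescale`) or an already-binned `pheno_bins` object
#' @param config a [layout_config()]
#' @return a `radial_scene`: list with `rings` (label, year, variable,
#'   radii, ground flag), `cells` (tibble of annular cells), `month_labels`,
#'   `legend`, `caption`
#' @export
build_scene <- function(table, config) {
  build_scene_impl(table, config, ground = ground_set_none(table))
}

#' Build a camera-vs-ground comparison scene
#'
#' Ground-observation variables are rendered as additional rings, visually
#' flagged (distinct ring-label style and their own legend entries) and
#' normalized independently of the camera variables. Ground series keep
#' their native, usually coarser, resolution: they are binned at
#' `ground_timescale`, so a monthly ground series shows 12 cells beside a
#' daily camera ring.
#'
#' @inheritParams build_scene
#' @param ground_vars character vector of table variables carrying
#'   ground-based observations; defaults to the table's own flags. Empty
#'   set reduces to [build_scene()].
#' @param ground_timescale timescale for the ground rings (default
#'   `"monthly"`)
#' @export
build_comparison_scene <- function(table, config, ground_vars = NULL,
                                   ground_timescale = "monthly") {
  gv <- ground_vars %||% ground_vars(table)
  unknown <- setdiff(gv, pheno_vars(table))
  if (length(unknown)) {
    ph_stop(paste0("unknown ground variable(s): ", paste(unknown, collapse = ", "),
                   "; available: ", paste(pheno_vars(table), collapse = ", ")),
            "phenoring_lookup")
  }
  ph_assert(config$ring_mode == "variables",
            "comparison scenes require ring_mode = 'variables'",
            "phenoring_config")
  build_scene_impl(table, config,
                   ground = list(vars = gv, timescale = ground_timescale))
}

ground_set_none <- function(table) list(vars = character(), timescale = "monthly")

build_scene_impl <- function(table, config, ground) {
  ph_assert(inherits(config, "layout_config"), "config must be a layout_config",
            "phenoring_config")
  if (inherits(table, "pheno_bins")) {
    bins <- table
    ph_assert(attr(bins, "timescale") == config$timescale,
              "pre-binned table timescale disagrees with config", "phenoring_config")
    daily_src <- NULL
  } else {
    validate_pheno_table(table)
    bins <- resample_table(table, config$timescale)
    daily_src <- table
  }
  vars <- config$variables %||% pheno_vars(bins)
  unknown <- setdiff(vars, pheno_vars(bins))
  if (length(unknown)) {
    ph_stop(paste0("unknown variable(s): ", paste(unknown, collapse = ", "),
                   "; available: ", paste(pheno_vars(bins), collapse = ", ")),
            "phenoring_lookup")
  }
  cam_vars <- setdiff(vars, ground$vars)
  grd_vars <- intersect(vars, ground$vars)
  years <- sort(unique(bins$year))
  ph_assert(length(years) >= 1, "table holds no records to display",
            "phenoring_config")

  if (config$ring_mode == "years") {
    ph_assert(length(vars) == 1,
              "ring_mode = 'years' requires exactly one variable",
              "phenoring_config")
    ring_spec <- tibble(label = as.character(years),
                        year = years, variable = vars[1],
                        ground = vars[1] %in% grd_vars,
                        timescale = config$timescale)
  } else {
    yr <- config$displayed_year %||% years[1]
    if (!yr %in% years) {
      ph_stop(sprintf("displayed_year %d not present (available: %s)",
                      yr, paste(years, collapse = ", ")), "phenoring_config")
    }
    is_grd <- vars %in% grd_vars
    ts_vec <- ifelse(is_grd, ground$timescale, config$timescale)
    ring_spec <- tibble(label = vars, year = yr, variable = vars,
                        ground = is_grd, timescale = ts_vec)
  }

  # ground rings may need their own (coarser) binning of the daily source
  bins_by_scale <- list()
  bins_by_scale[[config$timescale]] <- bins
  for (ts in unique(ring_spec$timescale)) {
    if (is.null(bins_by_scale[[ts]])) {
      ph_assert(!is.null(daily_src),
                "pre-binned input cannot be re-binned for ground rings",
                "phenoring_config")
      bins_by_scale[[ts]] <- resample_table(daily_src, ts)
    }
  }

  # normalization: per variable over ALL loaded bins at that ring's timescale
  norm_lookup <- lapply(seq_len(nrow(ring_spec)), function(i) {
    b <- bins_by_scale[[ring_spec$timescale[i]]]
    normalize_values(b[[ring_spec$variable[i]]])
  })

  n_rings <- nrow(ring_spec)
  r0 <- config$inner_hole_fraction
  thick <- (1 - r0) / n_rings
  palette_fun <- function(v) {
    ramp <- grDevices::hcl.colors(256, config$colormap)
    ramp[pmin(pmax(floor(v * 255) + 1, 1), 256)]
  }

  cells <- vector("list", n_rings)
  rings <- ring_spec
  rings$r_inner <- r0 + (seq_len(n_rings) - 1) * thick
  rings$r_outer <- r0 + seq_len(n_rings) * thick
  for (i in seq_len(n_rings)) {
    b <- bins_by_scale[[rings$timescale[i]]]
    sel <- b$year == rings$year[i]
    bi <- b[sel, ]
    vals <- bi[[rings$variable[i]]]
    nv <- norm_lookup[[i]][sel]
    n_bins <- nrow(bi)
    theta <- 2 * pi * (seq_len(n_bins) - 1) / n_bins
    theta_end <- 2 * pi * seq_len(n_bins) / n_bins
    fill <- ifelse(is.na(nv), config$missing_color, palette_fun(nv))
    cells[[i]] <- tibble(
      ring_index = i - 1L, bin = bi$bin,
      theta_start = theta, theta_end = theta_end,
      r_inner = rings$r_inner[i], r_outer = rings$r_outer[i],
      value = vals, norm = nv, fill = fill
    )
  }

  legend <- lapply(seq_len(n_rings), function(i) {
    b <- bins_by_scale[[rings$timescale[i]]]
    v <- b[[rings$variable[i]]]
    ok <- !is.na(v)
    list(variable = rings$variable[i],
         ground = rings$ground[i],
         vmin = if (any(ok)) min(v[ok]) else NA_real_,
         vmax = if (any(ok)) max(v[ok]) else NA_real_,
         colormap = config$colormap)
  })
  legend <- legend[!duplicated(vapply(legend, `[[`, "", "variable"))]

  structure(list(
    rings = rings,
    cells = bind_rows(cells),
    month_labels = month.abb,
    legend = legend,
    caption = config$title %||%
      paste(c(config$species, config$roi,
              if (config$ring_mode == "years")
                paste(range(years), collapse = "-")
              else as.character(ring_spec$year[1])),
            collapse = " "),
    config = config
  ), class = "radial_scene")
}

#' Navigate the displayed year
#'
#' Batch counterpart of the previous/next year navigation: moves
#' `displayed_year` to the adjacent year available in the table, saturating
#' (not wrapping) at the ends of the range.
#'
#' @param config a [layout_config()] with `ring_mode = "variables"`
#' @param table the [pheno_table()] the scene is built from
#' @return an updated `layout_config`
#' @export
next_year <- function(config, table) shift_year(config, table, +1L)

#' @rdname next_year
#' @export
previous_year <- function(config, table) shift_year(config, table, -1L)

shift_year <- function(config, table, step) {
  ph_assert(config$ring_mode == "variables",
            "year navigation applies to ring_mode = 'variables'",
            "phenoring_config")
  years <- sort(unique(table$year))
  cur <- config$displayed_year %||% years[1]
  pos <- match(cur, years)
  ph_assert(!is.na(pos), "displayed_year not present in table", "phenoring_config")
  config$displayed_year <- years[min(max(pos + step, 1L), length(years))]
  config
}

#' Serialize a radial scene to JSON
#'
#' Deterministic, field-ordered JSON (`rings`, `cells`, `legend`,
#' `month_labels`, `caption`) for golden-file comparison and for consumption
#' by other renderers.
#'
#' @param scene a `radial_scene`
#' @param path optional output path; when `NULL` the JSON string is returned
#' @return path (invisibly) or a JSON string
#' @export
scene_to_json <- function(scene, path = NULL) {
  ph_assert(inherits(scene, "radial_scene"), "not a radial_scene", "phenoring_schema")
  payload <- list(
    rings = as.data.frame(scene$rings),
    cells = as.data.frame(scene$cells),
    month_labels = scene$month_labels,
    legend = scene$legend,
    caption = scene$caption
  )
  json <- jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.radial_scene <- function(x, ...) {
  cat(sprintf("<radial_scene> %d ring(s), %d cell(s): %s\n",
              nrow(x$rings), nrow(x$cells),
              paste(x$rings$label, collapse = ", ")))
  invisible(x)
}
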