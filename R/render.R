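#' Render a radial scene to PDF or PNG
#'
#' Draws the scene with base graphics: each annular cell becomes a filled
#' polygon (arc sampled finely enough to look smooth at any size), month
#' labels sit outside the outer ring at the twelve 30-degree positions, ring
#' labels along the left horizontal, and a per-variable color-bar legend on
#' the right. PDF output is vector; PNG is rendered at the requested pixel
#' size.
#'
#' @param scene a `radial_scene` from [build_scene()]
#' @param path output file; when `NULL` a default
#'   `<species>_<roi>_<year-or-range>.<ext>` name (built from the config's
#'   labels) is used in the working directory
#' @param format `"pdf"` or `"png"`; inferred from `path`'s extension when
#'   possible
#' @param size PNG width/height in pixels, or PDF side in inches
#' @return the output path, invisibly
#' @export
render_scene <- function(scene, path = NULL, format = NULL, size = NULL) {
  ph_assert(inherits(scene, "radial_scene"), "not a radial_scene",
            "phenoring_schema")
  if (is.null(path)) path <- default_scene_filename(scene, format %||% "pdf")
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdf", "png")) ext else "pdf"
  }
  if (!format %in% c("pdf", "png")) {
    ph_stop(paste0("unknown output format: ", format), "phenoring_parameter")
  }
  if (!dir.exists(dirname(path))) {
    ph_stop(paste0("output directory does not exist: ", dirname(path)),
            "phenoring_io")
  }
  if (format == "pdf") {
    size <- size %||% 7
    grDevices::pdf(path, width = size, height = size, useDingbats = FALSE)
  } else {
    size <- size %||% 800
    args <- list(filename = path, width = size, height = size)
    if (capabilities("cairo")) args$type <- "cairo-png"
    do.call(grDevices::png, args)
  }
  on.exit(grDevices::dev.off())
  draw_scene(scene)
  invisible(path)
}

#' @rdname render_scene
#' @export
default_scene_filename <- function(scene, format = "pdf") {
  cfg <- scene$config
  years <- sort(unique(scene$rings$year))
  span <- if (length(years) > 1) paste(range(years), collapse = "-") else as.character(years)
  parts <- c(cfg$species %||% "phenoring", cfg$roi, span)
  paste0(paste(gsub("[^A-Za-z0-9_-]+", "-", parts), collapse = "_"), ".", format)
}

# screen coordinates: clockwise-from-top angle theta maps to the standard
# math angle phi = pi/2 - theta
polar_xy <- function(theta, r) {
  phi <- pi / 2 - theta
  cbind(x = r * cos(phi), y = r * sin(phi))
}

draw_scene <- function(scene) {
  op <- graphics::par(mar = c(1, 1, 3, 7), xpd = NA)
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), asp = 1)

  cells <- scene$cells
  for (i in seq_len(nrow(cells))) {
    arc_n <- max(2L, ceiling((cells$theta_end[i] - cells$theta_start[i]) / (pi / 90)))
    th <- seq(cells$theta_start[i], cells$theta_end[i], length.out = arc_n + 1)
    outer_pts <- polar_xy(th, cells$r_outer[i])
    inner_pts <- polar_xy(rev(th), cells$r_inner[i])
    graphics::polygon(c(outer_pts[, 1], inner_pts[, 1]),
                      c(outer_pts[, 2], inner_pts[, 2]),
                      col = cells$fill[i], border = NA)
  }

  # ring separators
  th_full <- seq(0, 2 * pi, length.out = 361)
  radii <- sort(unique(c(scene$rings$r_inner, scene$rings$r_outer)))
  for (r in radii) {
    p <- polar_xy(th_full, r)
    graphics::lines(p[, 1], p[, 2], col = "grey40", lwd = 0.5)
  }

  # month spokes and labels outside the outer ring
  r_out <- max(scene$rings$r_outer)
  r_in <- min(scene$rings$r_inner)
  for (m in 0:11) {
    th <- 2 * pi * m / 12
    p <- polar_xy(th, c(r_in, r_out))
    graphics::lines(p[, 1], p[, 2], col = "grey40", lwd = 0.5)
    lab <- polar_xy(th + pi / 12, r_out + 0.08)
    graphics::text(lab[1], lab[2], scene$month_labels[m + 1], cex = 0.9)
  }

  # ring labels along the left horizontal; ground rings flagged
  for (i in seq_len(nrow(scene$rings))) {
    rmid <- (scene$rings$r_inner[i] + scene$rings$r_outer[i]) / 2
    lab <- scene$rings$label[i]
    if (scene$rings$ground[i]) lab <- paste0(lab, " (ground)")
    graphics::text(-rmid, 0.02, lab, cex = 0.62, adj = c(0.5, 0),
                   font = if (scene$rings$ground[i]) 3 else 1,
                   col = "grey10")
  }

  graphics::title(main = scene$caption, cex.main = 1)

  draw_legend(scene)
  invisible(NULL)
}

draw_legend <- function(scene) {
  leg <- scene$legend
  if (!length(leg)) return(invisible(NULL))
  n <- length(leg)
  x0 <- 1.3
  slot_h <- min(0.5, 2 / n)
  for (k in seq_len(n)) {
    e <- leg[[k]]
    y_top <- 1 - (k - 1) * (slot_h + 0.15)
    ramp <- grDevices::hcl.colors(64, e$colormap)
    ys <- seq(y_top - slot_h, y_top, length.out = 65)
    graphics::rect(x0, ys[-65], x0 + 0.07, ys[-1], col = ramp, border = NA)
    graphics::rect(x0, y_top - slot_h, x0 + 0.07, y_top, border = "grey40", lwd = 0.5)
    lab <- if (isTRUE(e$ground)) paste0(e$variable, " (ground)") else e$variable
    graphics::text(x0, y_top + 0.05, lab, adj = c(0, 0), cex = 0.62,
                   font = if (isTRUE(e$ground)) 3 else 1)
    if (!is.na(e$vmin)) {
      graphics::text(x0 + 0.09, y_top - slot_h, format(e$vmin, digits = 3),
                     adj = c(0, 0), cex = 0.55)
      graphics::text(x0 + 0.09, y_top, format(e$vmax, digits = 3),
                     adj = c(0, 1), cex = 0.55)
    }
  }
  invisible(NULL)
}
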