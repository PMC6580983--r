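#' Regions of interest (ROI) in camera frames
#'
#' An `roi_polygon` is a named simple polygon in pixel coordinates
#' delineating the unit analysed in a phenocam frame — typically an
#' individual tree crown. Coordinate convention (documented because ROI files
#' are interchanged): 0-based pixel coordinates, origin at the top-left
#' corner of the frame, x rightward, y downward; the center of pixel
#' (column i, row j) is at (x, y) = (i, j).
#'
#' @param name label for the ROI (species or crown id); used to name the
#'   extracted variable `gcc_<name>`
#' @param vertices numeric matrix (or two-column data frame) of (x, y)
#'   vertex coordinates, at least 3 rows; the polygon is closed implicitly
#' @return an `roi_polygon`
#' @export
roi_polygon <- function(name, vertices) {
  vertices <- as.matrix(vertices)
  ph_assert(is.character(name) && length(name) == 1 && nzchar(name),
            "ROI name must be a non-empty string", "phenoring_geometry")
  ph_assert(ncol(vertices) == 2 && nrow(vertices) >= 3,
            "ROI needs >= 3 (x, y) vertices", "phenoring_geometry")
  storage.mode(vertices) <- "double"
  ph_assert(!anyNA(vertices), "ROI vertices must be finite", "phenoring_geometry")
  # drop a repeated closing vertex
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ]) && n > 3) vertices <- vertices[-n, , drop = FALSE]
  if (polygon_self_intersects(vertices)) {
    ph_stop(sprintf("ROI '%s' is self-intersecting", name), "phenoring_geometry")
  }
  structure(list(name = name, vertices = vertices), class = "roi_polygon")
}

# segment-intersection test over non-adjacent edge pairs (even-odd polygons
# must be simple for the mask to be meaningful ground truth)
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE]) # x1 y1 x2 y2
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      # skip adjacent edges (share a vertex), incl. the wrap-around pair
      if (j == i + 1 || (i == 1 && j == n)) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d2 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      d3 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d4 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize an ROI polygon to a boolean pixel mask
#'
#' A pixel belongs to the mask exactly when its center lies inside the
#' polygon under the even-odd (crossing-number) rule. An ROI that covers no
#' pixel center is a coverage error: it would yield an undefined index.
#'
#' @param roi an [roi_polygon()]
#' @param width,height frame dimensions in pixels
#' @return logical matrix with `height` rows and `width` columns
#'   (row-major image layout: row = y, column = x)
#' @export
rasterize_roi <- function(roi, width, height) {
  ph_assert(inherits(roi, "roi_polygon"), "roi must be an roi_polygon",
            "phenoring_geometry")
  ph_assert(width >= 1 && height >= 1, "frame dimensions must be positive",
            "phenoring_geometry")
  v <- roi$vertices
  xs <- rep(seq_len(width) - 1, each = height)   # pixel-center x, 0-based
  ys <- rep(seq_len(height) - 1, times = width)  # pixel-center y
  inside <- point_in_polygon_evenodd(xs, ys, v)
  mask <- matrix(inside, nrow = height, ncol = width)
  if (!any(mask)) {
    ph_stop(sprintf("ROI '%s' covers no pixel center in a %dx%d frame",
                    roi$name, width, height), "phenoring_coverage")
  }
  mask
}

# vectorized even-odd crossing test; points on a horizontal edge resolve by
# the half-open [y1, y2) crossing convention
point_in_polygon_evenodd <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read / write ROI definitions as JSON
#'
#' File format: `{"rois": [{"name": ..., "vertices": [[x, y], ...]}, ...]}`.
#'
#' @param path JSON file path
#' @return `read_roi_json()`: a list of [roi_polygon()]s.
#' @export
read_roi_json <- function(path) {
  ph_assert(file.exists(path), paste0("file not found: ", path), "phenoring_io")
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  ph_assert(is.list(spec$rois), "ROI JSON must have a top-level 'rois' array",
            "phenoring_schema")
  ph_assert(length(spec$rois) >= 1, "ROI JSON defines no ROIs", "phenoring_schema")
  lapply(spec$rois, function(r) {
    roi_polygon(r$name, do.call(rbind, lapply(r$vertices, unlist)))
  })
}

#' @rdname read_roi_json
#' @param rois list of [roi_polygon()]s
#' @export
write_roi_json <- function(rois, path) {
  payload <- list(rois = lapply(rois, function(r) {
    list(name = r$name,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ])))
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
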