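#' Chromatic coordinates of a masked image region
#'
#' Computes the normalized RGB chromatic coordinates of an ROI using the
#' ratio-of-means convention standard in phenocam processing: each channel is
#' first averaged over the masked pixels, then normalized by the sum of the
#' three channel means,
#' \deqn{gcc = \bar G / (\bar R + \bar G + \bar B),}
#' and analogously for rcc and bcc. This is observably different from
#' averaging per-pixel ratios and is the convention tested here. The result
#' is scale-free: multiplying all channels by a constant leaves it unchanged.
#'
#' @param image numeric array `height x width x 3` (R, G, B). Any common
#'   scale works (0-1 or 0-255); only channel ratios matter.
#' @param mask logical matrix `height x width`; at least one `TRUE` pixel
#' @return named numeric vector `c(rcc, gcc, bcc)` summing to 1, or all-`NA`
#'   when the masked region is totally black (undefined ratio)
#' @export
chromatic_coordinates <- function(image, mask) {
  d <- dim(image)
  ph_assert(length(d) == 3 && d[3] == 3, "image must be height x width x 3",
            "phenoring_dimension")
  ph_assert(is.matrix(mask) && all(dim(mask) == d[1:2]),
            sprintf("mask %dx%d does not match image %dx%d",
                    NROW(mask), NCOL(mask), d[1], d[2]),
            "phenoring_dimension")
  ph_assert(any(mask), "mask selects no pixels", "phenoring_coverage")
  means <- vapply(1:3, function(ch) mean(image[, , ch][mask]), numeric(1))
  s <- sum(means)
  if (s == 0) {
    return(c(rcc = NA_real_, gcc = NA_real_, bcc = NA_real_))
  }
  c(rcc = means[1] / s, gcc = means[2] / s, bcc = means[3] / s)
}

#' Composite multiple within-day samples to one daily value
#'
#' Phenocams often take several frames per day; illumination noise is
#' commonly suppressed by taking a high percentile of the within-day values
#' rather than the mean. The composite is applied independently per
#' (year, doy) and per index over that day's defined (non-missing) samples;
#' a day with no defined sample stays missing.
#'
#' @param samples data frame with columns `year`, `doy`, and one or more
#'   numeric index columns (e.g. `gcc`), one row per frame
#' @param method `"mean"`, `"median"`, or `"percentile"`
#' @param p percentile in (0, 100), used when `method = "percentile"`;
#'   linear interpolation between order statistics
#' @return tibble with one row per (year, doy), index columns composited
#' @export
daily_composite <- function(samples, method = c("mean", "median", "percentile"),
                            p = 90) {
  method <- match.arg(method)
  samples <- as_tibble(samples)
  ph_assert(all(c("year", "doy") %in% names(samples)),
            "samples need 'year' and 'doy' columns", "phenoring_schema")
  ph_assert(nrow(samples) >= 1, "no samples to composite", "phenoring_schema")
  if (method == "percentile") {
    ph_assert(is.numeric(p) && length(p) == 1 && p > 0 && p < 100,
              "percentile p must lie strictly between 0 and 100",
              "phenoring_parameter")
  }
  stat <- switch(method,
    mean = function(x) mean(x),
    median = function(x) stats::median(x),
    percentile = function(x) unname(stats::quantile(x, p / 100, type = 7))
  )
  idx_cols <- setdiff(names(samples), c("year", "doy", "seq"))
  samples %>%
    group_by(.data$year, .data$doy) %>%
    summarise(dplyr::across(all_of(idx_cols), function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else stat(x)
    }), .groups = "drop") %>%
    arrange(.data$year, .data$doy)
}

#' Extract daily chromatic-index series from a set of frames
#'
#' The frame-to-table stage of the phenocam workflow: every ROI is
#' rasterized once (all frames share dimensions, so masks are reused), each
#' frame contributes one chromatic triple per ROI, and within-day samples
#' are composited to one value per day. Output variables are named
#' `gcc_<roi name>` (and `rcc_<roi name>` when `indices` includes `"rcc"`).
#'
#' @param frames list of frames; each element is a list with fields `year`,
#'   `doy`, `seq` (ordinal within day) and `image` (`height x width x 3`
#'   array). See [read_frames_dir()] to build this from files.
#' @param rois list of [roi_polygon()]s
#' @param method,p daily compositing, as in [daily_composite()]
#' @param indices which chromatic coordinates to emit, subset of
#'   `c("gcc", "rcc", "bcc")`
#' @return a [pheno_table()] with one variable per ROI per index; an empty
#'   (zero-frame) input yields a zero-record table with declared variables
#' @export
extract_series <- function(frames, rois, method = "mean", p = 90,
                           indices = "gcc") {
  ph_assert(length(rois) >= 1, "at least one ROI is required", "phenoring_schema")
  indices <- match.arg(indices, c("gcc", "rcc", "bcc"), several.ok = TRUE)
  var_names <- unlist(lapply(rois, function(r) paste(indices, r$name, sep = "_")))

  if (length(frames) == 0) {
    empty <- tibble(year = integer(), doy = integer())
    for (v in var_names) empty[[v]] <- numeric()
    return(pheno_table(empty, variables = var_names))
  }

  dims <- dim(frames[[1]]$image)[1:2]
  for (f in frames) {
    ph_assert(all(dim(f$image)[1:2] == dims),
              "all frames must share the same dimensions", "phenoring_dimension")
  }
  masks <- lapply(rois, rasterize_roi, width = dims[2], height = dims[1])

  rows <- lapply(frames, function(f) {
    row <- tibble(year = as.integer(f$year), doy = as.integer(f$doy))
    for (k in seq_along(rois)) {
      cc <- chromatic_coordinates(f$image, masks[[k]])
      for (idx in indices) {
        row[[paste(idx, rois[[k]]$name, sep = "_")]] <- unname(cc[[idx]])
      }
    }
    row
  })
  daily <- daily_composite(bind_rows(rows), method = method, p = p)
  pheno_table(daily, variables = var_names)
}

#' Read a directory of phenocam frames
#'
#' Frame timestamps are parsed from filenames with a configurable Perl
#' regular expression containing named groups `year`, `doy` and (optionally)
#' `seq`. The default matches `<prefix>_<year>_<doy>_<seq>.png/jpg`.
#' PNG frames are read with the png package; 8-bit RGB is assumed and
#' channels are returned on the 0-255 scale.
#'
#' @param dir directory containing image files
#' @param pattern Perl regex with named capture groups
#' @return list of frames as consumed by [extract_series()]
#' @export
read_frames_dir <- function(dir,
                            pattern = "^.*_(?<year>\\d{4})_(?<doy>\\d{1,3})_(?<seq>\\d+)\\.(png|PNG|jpe?g|JPE?G)$") {
  ph_assert(dir.exists(dir), paste0("no such directory: ", dir), "phenoring_io")
  files <- list.files(dir, full.names = TRUE)
  stamps <- parse_frame_filename(basename(files), pattern)
  keep <- !is.na(stamps$year)
  if (!any(keep)) {
    ph_stop(sprintf("no frames in %s match the timestamp pattern", dir),
            "phenoring_io")
  }
  files <- files[keep]
  stamps <- stamps[keep, , drop = FALSE]
  ord <- order(stamps$year, stamps$doy, stamps$seq)
  lapply(ord, function(i) {
    list(year = stamps$year[i], doy = stamps$doy[i], seq = stamps$seq[i],
         image = read_rgb_frame(files[i]))
  })
}

#' @rdname read_frames_dir
#' @param filenames character vector of file names (no directory part needed)
#' @export
parse_frame_filename <- function(filenames,
                                 pattern = "^.*_(?<year>\\d{4})_(?<doy>\\d{1,3})_(?<seq>\\d+)\\.(png|PNG|jpe?g|JPE?G)$") {
  m <- regexpr(pattern, filenames, perl = TRUE)
  grab <- function(group) {
    st <- attr(m, "capture.start")[, group]
    len <- attr(m, "capture.length")[, group]
    out <- rep(NA_integer_, length(filenames))
    hit <- m > 0 & st > 0
    out[hit] <- as.integer(substr(filenames[hit], st[hit], st[hit] + len[hit] - 1))
    out
  }
  groups <- colnames(attr(m, "capture.start"))
  ph_assert(all(c("year", "doy") %in% groups),
            "pattern must define named groups 'year' and 'doy'",
            "phenoring_parameter")
  tibble(
    year = grab("year"),
    doy = grab("doy"),
    seq = if ("seq" %in% groups) grab("seq") else 1L
  )
}

# 8-bit RGB image file -> height x width x 3 array on the 0-255 scale;
# PNG via the png package, JPEG via EBImage when it is installed
read_rgb_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(read_rgb_png(path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      ph_stop("reading JPEG frames requires the EBImage package",
              "phenoring_io")
    }
    img <- EBImage::imageData(EBImage::readImage(path)) # width x height x ch
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    return(aperm(img[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255)
  }
  ph_stop(paste0("unsupported frame format: ", path), "phenoring_io")
}

read_rgb_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  arr[, , 1:3, drop = FALSE] * 255
}

# write a 0-255 RGB array as PNG
write_rgb_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
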