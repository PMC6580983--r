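#' Phenology time-series tables
#'
#' A `pheno_table` is a validated long-format daily time series: one row per
#' (year, doy) with columns `year`, `month`, `doy` followed by one or more
#' named numeric phenology variables (for instance the green chromatic
#' coordinate of an individual tree crown). Missing values are allowed in any
#' variable cell. A subset of the variables may be flagged as ground-based
#' observation series, which downstream comparison views render as distinct
#' rings.
#'
#' Invariants enforced by [validate_pheno_table()]:
#' \itemize{
#'   \item no duplicate (year, doy) keys; rows sorted ascending by (year, doy)
#'   \item 1 <= doy <= 365 (366 in leap years); month matches the calendar
#'     month containing that doy
#'   \item at least one variable column table-wide
#' }
#'
#' @param data data frame with `year`, `doy`, optionally `month`, and
#'   variable columns. `month` is derived from (year, doy) when absent.
#' @param variables character vector naming the variable columns, in display
#'   order. Defaults to every non-time column of `data`, in column order.
#' @param ground_vars character vector, subset of `variables`, flagging
#'   ground-observation series.
#' @return a `pheno_table` (a tibble with attributes `variables` and
#'   `ground_vars`).
#' @export
pheno_table <- function(data, variables = NULL, ground_vars = character()) {
  data <- as_tibble(data)
  ph_assert(all(c("year", "doy") %in% names(data)),
            "data must have 'year' and 'doy' columns", "phenoring_schema")
  if (is.null(variables)) {
    variables <- setdiff(names(data), c("year", "month", "doy"))
  }
  ph_assert(length(variables) >= 1,
            "a pheno_table needs at least one variable column",
            "phenoring_schema")
  ph_assert(all(variables %in% names(data)),
            paste0("variable column(s) not found: ",
                   paste(setdiff(variables, names(data)), collapse = ", ")),
            "phenoring_schema")

  data$year <- as.integer(data$year)
  data$doy <- as.integer(data$doy)
  if (!"month" %in% names(data)) {
    data$month <- if (nrow(data)) month_from_doy(data$year, data$doy) else integer()
  } else {
    data$month <- as.integer(data$month)
  }
  for (v in variables) data[[v]] <- as.numeric(data[[v]])

  data <- data[, c("year", "month", "doy", variables)]
  data <- arrange(data, .data$year, .data$doy)

  out <- structure(data,
                   variables = variables,
                   ground_vars = intersect(ground_vars, variables),
                   class = c("pheno_table", class(data)))
  validate_pheno_table(out)
}

#' @rdname pheno_table
#' @param x object to validate / test
#' @export
validate_pheno_table <- function(x) {
  ph_assert(inherits(x, "pheno_table"), "not a pheno_table", "phenoring_schema")
  vars <- pheno_vars(x)
  ph_assert(length(vars) >= 1, "no variable columns", "phenoring_schema")
  if (nrow(x) > 0) {
    bad <- which(!doy_valid(x$year, x$doy))
    if (length(bad)) {
      ph_stop(sprintf("doy out of range for its year at row %d (year=%d, doy=%d)",
                      bad[1], x$year[bad[1]], x$doy[bad[1]]),
              "phenoring_validation")
    }
    expected <- month_from_doy(x$year, x$doy)
    mis <- which(x$month != expected)
    if (length(mis)) {
      ph_stop(sprintf(
        "month column inconsistent with (year, doy) at row %d: month=%d but doy %d of %d falls in month %d",
        mis[1], x$month[mis[1]], x$doy[mis[1]], x$year[mis[1]], expected[mis[1]]),
        "phenoring_validation")
    }
    key <- paste(x$year, x$doy)
    if (anyDuplicated(key)) {
      d <- key[which(duplicated(key))[1]]
      ph_stop(sprintf("duplicate (year, doy) key: (%s)", gsub(" ", ", ", d)),
              "phenoring_validation")
    }
    ph_assert(!is.unsorted(order(x$year, x$doy)),
              "records not sorted by (year, doy)", "phenoring_validation")
  }
  x
}

#' @rdname pheno_table
#' @export
is_pheno_table <- function(x) inherits(x, "pheno_table")

#' Variable names of a pheno table or binned series
#' @param x a `pheno_table` or `pheno_bins` object
#' @return character vector of variable names, in display order
#' @export
pheno_vars <- function(x) attr(x, "variables")

#' Ground-observation variable names
#' @rdname pheno_vars
#' @export
ground_vars <- function(x) attr(x, "ground_vars") %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag variables as ground-based observation series
#' @param table a `pheno_table`
#' @param vars character vector of variable names to flag
#' @return the table with its `ground_vars` attribute updated
#' @export
set_ground_vars <- function(table, vars) {
  unknown <- setdiff(vars, pheno_vars(table))
  if (length(unknown)) {
    ph_stop(paste0("unknown ground variable(s): ",
                   paste(unknown, collapse = ", "),
                   "; available: ", paste(pheno_vars(table), collapse = ", ")),
            "phenoring_lookup")
  }
  attr(table, "ground_vars") <- vars
  table
}

#' @export
print.pheno_table <- function(x, ...) {
  gv <- ground_vars(x)
  cat(sprintf("<pheno_table> %d record(s), %d variable(s): %s\n",
              nrow(x), length(pheno_vars(x)),
              paste(pheno_vars(x), collapse = ", ")))
  if (length(gv)) cat("  ground-observation variables:", paste(gv, collapse = ", "), "\n")
  if (nrow(x)) cat(sprintf("  years %d-%d\n", min(x$year), max(x$year)))
  NextMethod()
}
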