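#' @keywords internal
"_PACKAGE"

#' @importFrom dplyr %>% arrange bind_rows filter mutate select all_of group_by
#'   summarise ungroup left_join distinct .data
#' @importFrom tibble tibble as_tibble
NULL

# classed condition helper so callers can distinguish error families
ph_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "phenoring_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ph_assert <- function(cond, msg, class = "phenoring_invalid") {
  if (!isTRUE(cond)) ph_stop(msg, class)
  invisible(TRUE)
}

#' Run code with a private, restored RNG state
#'
#' All stochastic generators in the package take explicit seeds; this keeps
#' them from disturbing (or being disturbed by) the caller's random stream.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Leap-year predicate (proleptic Gregorian)
#' @param year integer vector of calendar years
#' @return logical vector
#' @export
is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
}

#' Number of days in a calendar year
#' @param year integer vector
#' @return integer vector (365 or 366)
#' @export
days_in_year <- function(year) {
  ifelse(is_leap_year(year), 366L, 365L)
}

#' Derive the calendar month from (year, doy)
#'
#' Uses base Date arithmetic: doy 1 is 1 January of `year`.
#' @param year integer vector
#' @param doy integer vector, 1-based day of year
#' @return integer vector of months 1-12
#' @export
month_from_doy <- function(year, doy) {
  d <- as.Date(sprintf("%d-01-01", year)) + (doy - 1L)
  as.integer(format(d, "%m"))
}

# vectorized doy-validity check: 1..365, 366 only in leap years
doy_valid <- function(year, doy) {
  doy >= 1L & doy <= days_in_year(year)
}
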