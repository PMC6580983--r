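#' Aggregate a daily phenology table to a display timescale
#'
#' Bins each year's days and averages the non-missing daily values per bin:
#' \itemize{
#'   \item `daily`: one bin per day (365, or 366 in leap years)
#'   \item `weekly`: blocks of 7 consecutive doys anchored at doy 1, giving
#'     53 bins per year; the last bin holds the 1-2 remainder days (doy 365,
#'     and 366 in leap years). Weeks are doy-blocks, not ISO weeks — ISO
#'     weeks straddle year boundaries, which would break the one-ring-per-year
#'     radial model.
#'   \item `monthly`: calendar months, 12 bins per year; doy 366 belongs to
#'     December.
#' }
#' Bins are enumerated for the whole year of every year present in the
#' table, so sparse series (e.g. monthly ground observations) still yield a
#' full ring of bins; a bin with no non-missing day is missing.
#'
#' @param table a [pheno_table()]
#' @param scale `"daily"`, `"weekly"`, or `"monthly"`
#' @return a `pheno_bins` tibble with columns `year`, `bin` (1-based),
#'   `doy_start`, `doy_end`, `n_days` (calendar days in the bin) and one
#'   column per variable (bin mean of non-missing daily values). Attributes
#'   `timescale`, `variables` and `ground_vars` are carried along.
#' @export
resample_table <- function(table, scale = c("daily", "weekly", "monthly")) {
  scale <- match.arg(scale)
  validate_pheno_table(table)
  vars <- pheno_vars(table)
  years <- sort(unique(table$year))

  grid <- bind_rows(lapply(years, function(y) bin_grid(y, scale)))
  if (length(years) == 0) {
    grid <- bin_grid(integer(), scale)[0, ]
  }

  daily <- as_tibble(table)
  daily$bin <- bin_of_doy(daily$year, daily$doy, scale)
  agg <- daily %>%
    group_by(.data$year, .data$bin) %>%
    summarise(dplyr::across(all_of(vars), function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else mean(x)
    }), .groups = "drop")

  out <- left_join(grid, agg, by = c("year", "bin"))
  for (v in vars) if (!v %in% names(out)) out[[v]] <- NA_real_
  out <- out[, c("year", "bin", "doy_start", "doy_end", "n_days", vars)]
  structure(arrange(out, .data$year, .data$bin),
            timescale = scale,
            variables = vars,
            ground_vars = ground_vars(table),
            class = c("pheno_bins", class(out)))
}

#' Number of bins a year holds at a timescale
#' @param year integer vector of years
#' @param scale timescale name
#' @return integer vector (365/366, 53, or 12)
#' @export
bins_in_year <- function(year, scale = c("daily", "weekly", "monthly")) {
  scale <- match.arg(scale)
  switch(scale,
    daily = days_in_year(year),
    weekly = rep(53L, length(year)),
    monthly = rep(12L, length(year))
  )
}

# bin index (1-based) of each (year, doy) at a timescale
bin_of_doy <- function(year, doy, scale) {
  switch(scale,
    daily = as.integer(doy),
    weekly = pmin((as.integer(doy) - 1L) %/% 7L + 1L, 53L),
    monthly = month_from_doy(year, doy)
  )
}

# full bin enumeration (doy spans and day counts) for one year
bin_grid <- function(year, scale) {
  if (length(year) == 0) {
    return(tibble(year = integer(), bin = integer(), doy_start = integer(),
                  doy_end = integer(), n_days = integer()))
  }
  nd <- days_in_year(year)
  doys <- seq_len(nd)
  b <- bin_of_doy(rep(year, nd), doys, scale)
  tibble(year = year, bin = sort(unique(b))) %>%
    mutate(doy_start = vapply(.data$bin, function(k) min(doys[b == k]), integer(1)),
           doy_end = vapply(.data$bin, function(k) max(doys[b == k]), integer(1)),
           n_days = .data$doy_end - .data$doy_start + 1L)
}

#' @export
print.pheno_bins <- function(x, ...) {
  cat(sprintf("<pheno_bins> timescale=%s, %d bin-row(s), variables: %s\n",
              attr(x, "timescale"), nrow(x),
              paste(pheno_vars(x), collapse = ", ")))
  NextMethod()
}
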