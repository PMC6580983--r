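#' Read a phenology CSV file
#'
#' Expects a header row with `year` and `doy` columns (and optionally
#' `month`); every other column is treated as a phenology variable, names
#' kept verbatim and case-sensitive, in header order. The dialect is fixed:
#' comma separator, `.` decimal mark, UTF-8, no sniffing. Non-numeric and
#' empty variable cells become missing (`NA`). When `month` is absent it is
#' derived from (year, doy); when present it is cross-checked and a mismatch
#' is an error (we refuse to guess which of the two is right).
#'
#' @param path path to a CSV file
#' @param ground_vars optional character vector of variable names to flag as
#'   ground-observation series
#' @return a [pheno_table()]
#' @export
read_pheno_csv <- function(path, ground_vars = character()) {
  ph_assert(file.exists(path), paste0("file not found: ", path), "phenoring_io")
  raw <- utils::read.csv(path, header = TRUE, sep = ",", dec = ".",
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8", na.strings = NULL,
                         strip.white = TRUE)
  for (required in c("year", "doy")) {
    if (!required %in% names(raw)) {
      ph_stop(sprintf("missing required column '%s' in %s", required, path),
              "phenoring_schema")
    }
  }
  vars <- setdiff(names(raw), c("year", "month", "doy"))
  if (length(vars) == 0) {
    ph_stop("no variable columns found (need at least one non-time column)",
            "phenoring_schema")
  }

  to_int <- function(col, name) {
    v <- suppressWarnings(as.integer(col))
    bad <- which(is.na(v) & nzchar(col))
    if (length(bad) || (nrow(raw) && anyNA(v))) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      ph_stop(sprintf("non-integer value in column '%s' at data row %d", name, row),
              "phenoring_validation")
    }
    v
  }
  df <- tibble(
    year = to_int(raw$year, "year"),
    doy = to_int(raw$doy, "doy")
  )
  if ("month" %in% names(raw)) df$month <- to_int(raw$month, "month")
  for (v in vars) {
    cell <- raw[[v]]
    num <- suppressWarnings(as.numeric(cell))
    num[!nzchar(cell)] <- NA_real_   # empty field -> missing
    df[[v]] <- num                   # non-numeric text -> missing (NA via coercion)
  }

  if (nrow(df) > 0) {
    bad <- which(!doy_valid(df$year, df$doy))
    if (length(bad)) {
      ph_stop(sprintf("doy out of range at data row %d (year=%d, doy=%d)",
                      bad[1], df$year[bad[1]], df$doy[bad[1]]),
              "phenoring_validation")
    }
    key <- paste(df$year, df$doy)
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1]
      ph_stop(sprintf(
        "duplicate (year, doy) = (%d, %d) at data row %d; one value per day expected",
        df$year[d], df$doy[d], d), "phenoring_validation")
    }
    if ("month" %in% names(df)) {
      expected <- month_from_doy(df$year, df$doy)
      mis <- which(df$month != expected)
      if (length(mis)) {
        ph_stop(sprintf(
          "month/doy mismatch at data row %d: month=%d but doy %d of %d is in month %d",
          mis[1], df$month[mis[1]], df$doy[mis[1]], df$year[mis[1]], expected[mis[1]]),
          "phenoring_validation")
      }
    }
  }
  pheno_table(df, variables = vars, ground_vars = ground_vars)
}

#' Write a phenology CSV file
#'
#' Emits the header `year,month,doy,<variables...>`. Missing cells are empty
#' fields. Numeric values are written with the fewest significant digits that
#' reproduce the stored double exactly, so `read_pheno_csv(write_pheno_csv(t))`
#' is an identity.
#'
#' @param table a [pheno_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pheno_csv <- function(table, path) {
  validate_pheno_table(table)
  vars <- pheno_vars(table)
  cols <- c("year", "month", "doy", vars)
  mat <- vapply(cols, function(cl) {
    x <- table[[cl]]
    if (cl %in% vars) format_roundtrip(x) else as.character(x)
  }, character(nrow(table)))
  if (nrow(table) == 1) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, cols))
  body <- if (nrow(table)) apply(mat, 1, paste, collapse = ",") else character()
  lines <- c(paste(cols, collapse = ","), body)
  ok <- tryCatch({
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) ph_stop(paste0("cannot write ", path, ": ",
                                  conditionMessage(ok)), "phenoring_io")
  invisible(path)
}

# shortest decimal representation that round-trips the double exactly
format_roundtrip <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (is.na(v)) { out[i] <- ""; next }
    s <- NULL
    for (d in c(15L, 16L, 17L)) {
      cand <- sprintf("%.*g", d, v)
      if (as.numeric(cand) == v) { s <- cand; break }
    }
    out[i] <- s %||% sprintf("%.17g", v)
  }
  out
}

#' Merge several phenology tables
#'
#' Takes the union of records on the (year, doy) key and the union of
#' variable sets; cells absent from a source table become missing. Two tables
#' may carry the same variable only if their values agree wherever their keys
#' overlap (both non-missing); a disagreement is a merge conflict, not an
#' average. Ground-observation flags are unioned.
#'
#' @param tables list of [pheno_table()] objects (a single table is returned
#'   unchanged)
#' @return a merged [pheno_table()]
#' @export
merge_tables <- function(tables) {
  ph_assert(is.list(tables) && length(tables) >= 1,
            "merge_tables() needs a non-empty list of pheno_tables",
            "phenoring_schema")
  for (t in tables) validate_pheno_table(t)
  tables <- Filter(function(t) length(pheno_vars(t)) > 0, tables)
  if (length(tables) == 1) return(tables[[1]])

  all_vars <- unique(unlist(lapply(tables, pheno_vars)))
  all_ground <- unique(unlist(lapply(tables, ground_vars)))

  keys <- unique(bind_rows(lapply(tables, function(t) t[, c("year", "doy")])))
  keys <- arrange(keys, .data$year, .data$doy)
  out <- keys
  for (v in all_vars) out[[v]] <- NA_real_

  for (t in tables) {
    idx <- match(paste(t$year, t$doy), paste(out$year, out$doy))
    for (v in pheno_vars(t)) {
      new <- t[[v]]
      cur <- out[[v]][idx]
      clash <- !is.na(cur) & !is.na(new) & cur != new
      if (any(clash)) {
        i <- which(clash)[1]
        ph_stop(sprintf(
          "merge conflict for variable '%s' at (year=%d, doy=%d): %g vs %g",
          v, t$year[i], t$doy[i], cur[i], new[i]), "phenoring_merge")
      }
      take <- !is.na(new)
      out[[v]][idx[take]] <- new[take]
    }
  }
  pheno_table(out, variables = all_vars, ground_vars = all_ground)
}

#' Filter a table by years and variables
#'
#' @param table a [pheno_table()]
#' @param years integer vector of years to keep, or `NULL` for all
#' @param variables character vector of variables to keep (order respected),
#'   or `NULL` for all
#' @return the filtered [pheno_table()]
#' @export
filter_table <- function(table, years = NULL, variables = NULL) {
  validate_pheno_table(table)
  if (is.null(variables)) variables <- pheno_vars(table)
  unknown <- setdiff(variables, pheno_vars(table))
  if (length(unknown)) {
    ph_stop(paste0("unknown variable(s): ", paste(unknown, collapse = ", "),
                   "; available: ", paste(pheno_vars(table), collapse = ", ")),
            "phenoring_lookup")
  }
  df <- table
  if (!is.null(years)) df <- df[df$year %in% as.integer(years), , drop = FALSE]
  df <- df[, c("year", "month", "doy", variables), drop = FALSE]
  pheno_table(as_tibble(df), variables = variables,
              ground_vars = intersect(ground_vars(table), variables))
}
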