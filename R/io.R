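#' Read a Tucson/RWL ring-width file
#'
#' Parses the decadal-row Tucson dendrochronology dialect: each row holds a
#' series id, the year of the first value, and up to ten values; the
#' end-of-series marker is `999` (0.01 mm precision) or `-9999` (0.001 mm
#' precision, detected automatically). Malformed rows raise an error that
#' names the line.
#'
#' @param path Path to the RWL file.
#' @param units Measurement unit in mm per integer count; `NULL` infers
#'   0.01 mm (marker 999) or 0.001 mm (marker -9999) per series.
#' @return Named list of [ring_series()] objects, one per series id.
#' @export
read_rwl <- function(path, units = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  series <- list()
  acc_year <- list()
  acc_val <- list()
  done <- character(0)
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 3) {
      stop(sprintf("line %d: expected id, year and values", ln))
    }
    id <- tok[1]
    yr <- suppressWarnings(as.integer(tok[2]))
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (is.na(yr) || anyNA(vals) || any(vals != round(vals))) {
      stop(sprintf("line %d: malformed decade row", ln))
    }
    if (id %in% done) stop(sprintf("line %d: data after series terminator", ln))
    stop_at <- suppressWarnings(min(which(vals %in% c(999, -9999))))
    terminated <- is.finite(stop_at)
    unit_here <- units
    if (terminated) {
      if (is.null(unit_here)) {
        unit_here <- if (vals[stop_at] == 999) 0.01 else 0.001
      }
      vals <- vals[seq_len(stop_at - 1)]
      done <- c(done, id)
    }
    if (length(vals) > 0) {
      if (any(vals < 0)) stop(sprintf("line %d: negative ring width", ln))
      acc_year[[id]] <- c(acc_year[[id]], seq(yr, length.out = length(vals)))
      acc_val[[id]] <- c(acc_val[[id]], vals)
    }
    if (terminated) {
      years <- acc_year[[id]]
      if (is.null(years)) stop(sprintf("line %d: empty series %s", ln, id))
      if (anyDuplicated(years) || any(diff(years) != 1)) {
        stop(sprintf("series %s: years not contiguous", id))
      }
      series[[id]] <- ring_series(years, acc_val[[id]] * unit_here)
    }
  }
  open_series <- setdiff(names(acc_year), done)
  if (length(open_series) > 0) {
    stop("series without terminator: ", paste(open_series, collapse = ", "))
  }
  series
}

#' Write a ring-width series in Tucson/RWL format
#'
#' Encodes widths as integers at 0.01 mm (default) with the conventional
#' `999` terminator, in decade-aligned rows. Widths above the largest
#' representable value raise an error.
#'
#' @param series A [ring_series()].
#' @param path Output path.
#' @param series_id Series identifier (at most 8 characters).
#' @param units mm per integer count: `0.01` (terminator 999) or `0.001`
#'   (terminator -9999).
#' @return The path, invisibly.
#' @export
write_rwl <- function(series, path, series_id = "SER01", units = 0.01) {
  stopifnot(inherits(series, "ring_series"), units %in% c(0.01, 0.001),
            nchar(series_id) <= 8, all(series$rw_mm >= 0))
  terminator <- if (units == 0.01) 999 else -9999
  max_mm <- if (units == 0.01) 99.99 else 9.999
  if (any(series$rw_mm > max_mm)) {
    stop(sprintf("width above %.3f mm not representable at %g mm units",
                 max_mm, units))
  }
  vals <- round(series$rw_mm / units)
  if (any(vals == terminator)) {
    stop("a width encodes to the terminator value; use the other unit")
  }
  years <- series$year
  codes <- c(vals, terminator)
  code_years <- c(years, years[length(years)] + 1)
  rows <- character(0)
  i <- 1
  while (i <= length(codes)) {
    y <- code_years[i]
    n_row <- min(10 - (y %% 10), length(codes) - i + 1)
    rows <- c(rows, paste0(formatC(series_id, width = -8),
                           formatC(y, width = 4),
                           paste0(formatC(codes[i:(i + n_row - 1)],
                                          width = 6), collapse = "")))
    i <- i + n_row
  }
  writeLines(rows, path)
  invisible(path)
}

#' Mean ring-width series across a collection
#'
#' Year-by-year arithmetic mean of the series returned by [read_rwl()].
#'
#' @param collection Named list of [ring_series()].
#' @return A [ring_series()] of annual means over the union of years.
#' @export
rwl_site_mean <- function(collection) {
  stopifnot(is.list(collection), length(collection) >= 1)
  years <- sort(unique(unlist(lapply(collection, function(s) s$year))))
  means <- vapply(years, function(y) {
    v <- unlist(lapply(collection, function(s) s$rw_mm[s$year == y]))
    mean(v)
  }, numeric(1))
  ring_series(years, means)
}

#' Read a monthly climate table
#'
#' Reads the plain tabular climate dialect written by
#' [write_climate_table()]: whitespace-separated with a header row and
#' columns `year`, `month`, `tmp`, `dtr`, `pre`, `vap`, `cld`. Rows may be
#' in any order; gaps, duplicates and out-of-range values are rejected
#' with explicit messages.
#'
#' @param path Path to the table.
#' @param site A [site_meta()] for the series.
#' @return A [forcing_series()].
#' @export
read_climate_table <- function(path, site) {
  tab <- read.table(path, header = TRUE)
  forcing_series(tab, site = site)
}

#' Write a forcing series as a monthly climate table
#'
#' @param series A [forcing_series()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_climate_table <- function(series, path) {
  stopifnot(inherits(series, "forcing_series"))
  tab <- as.data.frame(series)[c("year", "month", "tmp", "dtr", "pre",
                                 "vap", "cld")]
  write.table(format(tab, digits = 10, scientific = FALSE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an annual CO2 table
#'
#' Two-column whitespace-separated text with a header row (`year`, `ppm`).
#'
#' @param path Path to the table.
#' @return `read_co2_table()`: data frame `year`, `ppm`.
#' @export
read_co2_table <- function(path) {
  tab <- read.table(path, header = TRUE)
  validate_co2(tab)
}

#' @rdname read_co2_table
#' @param co2 Data frame with columns `year`, `ppm`.
#' @return `write_co2_table()`: the path, invisibly.
#' @export
write_co2_table <- function(co2, path) {
  co2 <- validate_co2(co2)
  write.table(format(co2, digits = 10, scientific = FALSE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
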