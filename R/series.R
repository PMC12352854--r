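#' Hourly time-indexed PM2.5 series
#'
#' The universal carrier between package stages: a data frame with a regular
#' hourly `timestamp` column (POSIXct, UTC), a `pm25` column where `NA` marks
#' a missing hour, and optional meteorological covariates using the weather
#' archive's column convention: `T` (air temperature, degC), `U` (relative
#' humidity, %), `Ff` (wind speed, m/s), `DD` (wind direction, degrees).
#' Derived temporal columns `hour` (0-23) and `season` (1 = winter,
#' 2 = spring, 3 = summer, 4 = autumn) are added automatically.
#'
#' @param timestamp POSIXct vector, strictly increasing, hourly spacing.
#' @param pm25 numeric vector of concentrations (ug/m3), `NA` = missing.
#' @param ... further equal-length covariate columns (e.g. `T`, `U`, `Ff`,
#'   `DD`).
#' @return an object of class `pm_series` (a data frame).
#' @export
pm_series <- function(timestamp, pm25, ...) {
  if (!inherits(timestamp, "POSIXct")) {
    timestamp <- as.POSIXct(timestamp, tz = "UTC")
  }
  n <- length(timestamp)
  if (length(pm25) != n) stop_contract("pm25 and timestamp lengths differ")
  if (n > 1) {
    dt <- as.numeric(diff(timestamp), units = "secs")
    if (any(dt <= 0)) stop_contract("timestamps must be strictly increasing")
    if (any(dt != 3600)) stop_contract("timestamps must be hourly spaced")
  }
  extra <- list(...)
  for (nm in names(extra)) {
    if (length(extra[[nm]]) != n) {
      stop_contract(sprintf("column '%s' has wrong length", nm))
    }
  }
  df <- data.frame(timestamp = timestamp, pm25 = as.numeric(pm25),
                   check.names = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df$hour <- hour_of_day(timestamp)
  df$season <- season_of(timestamp)
  class(df) <- c("pm_series", "data.frame")
  df
}

#' @export
print.pm_series <- function(x, ...) {
  n <- nrow(x)
  miss <- sum(is.na(x$pm25))
  cat(sprintf("<pm_series> %d hourly records, %d missing (%.1f%%)\n",
              n, miss, if (n) 100 * miss / n else 0))
  cat(sprintf("  span: %s .. %s\n", format(x$timestamp[1]),
              format(x$timestamp[n])))
  cat(sprintf("  columns: %s\n", paste(names(x), collapse = ", ")))
  invisible(x)
}

hour_of_day <- function(ts) as.integer(format(ts, "%H", tz = "UTC"))

#' Meteorological season code of a timestamp
#'
#' Encoded 1 = winter (Dec-Feb), 2 = spring (Mar-May), 3 = summer (Jun-Aug),
#' 4 = autumn (Sep-Nov).
#'
#' @param ts POSIXct vector.
#' @return integer vector in 1..4.
#' @export
season_of <- function(ts) {
  m <- as.integer(format(ts, "%m", tz = "UTC"))
  c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 1L)[m]
}

series_values <- function(series) {
  if (inherits(series, "pm_series") || is.data.frame(series)) series$pm25
  else as.numeric(series)
}

#' Write / read an hourly series as CSV
#'
#' ISO-8601 timestamps; missing values are encoded as empty fields.
#'
#' @param series a [pm_series()].
#' @param path file path.
#' @return `read_hourly_csv` returns a [pm_series()]; `write_hourly_csv`
#'   returns `path` invisibly.
#' @export
write_hourly_csv <- function(series, path) {
  out <- as.data.frame(series)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_hourly_csv
#' @export
read_hourly_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S"))
  extra <- df[setdiff(names(df), c("timestamp", "pm25", "hour", "season"))]
  do.call(pm_series, c(list(timestamp = ts, pm25 = as.numeric(df$pm25)),
                       as.list(extra)))
}
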