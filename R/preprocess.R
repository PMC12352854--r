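#' Quality-control configuration for minute-level sensor records
#'
#' Houses the thresholds of the two-stage outlier filtering and aggregation
#' pipeline. Boundary conventions mirror the rules' wording: a spike must
#' *exceed* the threshold, a delayed timestamp must be *under* the tolerance
#' (strict), a short gap must be *shorter than* `short_gap_max` (runs of at
#' most `short_gap_max - 1` minutes are interpolated), and an hour needs
#' *at least* `min_valid_minutes` valid minutes (inclusive).
#'
#' @param spike_threshold minute-level spike threshold, ug/m3.
#' @param spike_ratio spike must exceed `spike_ratio` x previous reading.
#' @param iqr_multiplier Tukey fence multiplier.
#' @param delay_tolerance seconds; delayed readings under this are snapped
#'   back to the intended minute.
#' @param short_gap_max minutes (exclusive bound) for linear interpolation.
#' @param min_valid_minutes minimum valid minutes for an hourly mean.
#' @param hourly_hard_threshold hourly values above this are masked.
#' @param hourly_spike_threshold,hourly_spike_ratio secondary hourly spike
#'   rule: value > threshold and > ratio x previous hour.
#' @return a `qc_config` list.
#' @export
qc_config <- function(spike_threshold = 200, spike_ratio = 3,
                      iqr_multiplier = 1.5, delay_tolerance = 15,
                      short_gap_max = 5, min_valid_minutes = 40,
                      hourly_hard_threshold = 270,
                      hourly_spike_threshold = 200, hourly_spike_ratio = 3) {
  vals <- c(spike_threshold, spike_ratio, iqr_multiplier, delay_tolerance,
            short_gap_max, min_valid_minutes, hourly_hard_threshold,
            hourly_spike_threshold, hourly_spike_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_config("all QC thresholds must be positive")
  }
  structure(list(spike_threshold = spike_threshold, spike_ratio = spike_ratio,
                 iqr_multiplier = iqr_multiplier,
                 delay_tolerance = delay_tolerance,
                 short_gap_max = short_gap_max,
                 min_valid_minutes = min_valid_minutes,
                 hourly_hard_threshold = hourly_hard_threshold,
                 hourly_spike_threshold = hourly_spike_threshold,
                 hourly_spike_ratio = hourly_spike_ratio,
                 quartile_type = 7L),  # linear interpolation of order stats
            class = "qc_config")
}

#' Flag spike outliers in a value sequence
#'
#' A point is flagged iff it exceeds `threshold` AND is more than
#' `ratio` x the previous reading, with the previous reading present.
#' Missing predecessors never flag.
#'
#' @param values numeric vector (may contain `NA`).
#' @param threshold,ratio rule parameters.
#' @return logical mask, `TRUE` = flagged.
#' @export
flag_spike_outliers <- function(values, threshold = 200, ratio = 3) {
  n <- length(values)
  prev <- c(NA_real_, values[-n])
  mask <- !is.na(values) & !is.na(prev) &
    values > threshold & values > ratio * prev
  mask[is.na(mask)] <- FALSE
  mask
}

#' Flag interquartile-range outliers
#'
#' Flags points lying strictly outside
#' `[Q1 - multiplier * IQR, Q3 + multiplier * IQR]`, with quartiles computed
#' over non-missing values by linear interpolation of order statistics. The
#' strict comparison means a constant series yields no flags.
#'
#' @param values numeric vector with at least 4 non-missing entries.
#' @param multiplier fence multiplier.
#' @return logical mask, `TRUE` = flagged.
#' @export
flag_iqr_outliers <- function(values, multiplier = 1.5) {
  obs <- values[!is.na(values)]
  if (length(obs) < 4) {
    stop_pm("IQR flagging needs at least 4 non-missing values",
            "pmgapfill_degenerate_input")
  }
  q <- quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - multiplier * iqr
  hi <- q[2] + multiplier * iqr
  mask <- !is.na(values) & (values < lo | values > hi)
  mask
}

floor_minute <- function(ts) as.POSIXct(floor(as.numeric(ts) / 60) * 60,
                                        origin = "1970-01-01", tz = "UTC")

#' Correct slightly delayed minute timestamps
#'
#' A record timestamped at `hh:mm:ss` with `0 < ss < delay_tolerance` is
#' reassigned to `hh:mm:00`, provided no record already occupies that
#' minute. On collision the record is left in place with a warning.
#'
#' @param records data frame with a POSIXct `timestamp` column (second
#'   resolution) and measurement columns.
#' @param delay_tolerance seconds, strict upper bound.
#' @return the records with corrected timestamps, sorted by time.
#' @export
correct_delayed_timestamps <- function(records, delay_tolerance = 15) {
  if (nrow(records) == 0) return(records)
  records <- records[order(records$timestamp), , drop = FALSE]
  secs <- as.numeric(records$timestamp) %% 60
  target <- floor_minute(records$timestamp)
  movable <- secs > 0 & secs < delay_tolerance
  occupied <- as.numeric(records$timestamp[secs == 0])
  moved <- 0L
  for (i in which(movable)) {
    t0 <- as.numeric(target[i])
    if (t0 %in% occupied) {
      warning(sprintf("delayed record at %s not moved: minute occupied",
                      format(records$timestamp[i])))
    } else {
      records$timestamp[i] <- target[i]
      occupied <- c(occupied, t0)
      moved <- moved + 1L
    }
  }
  records[order(records$timestamp), , drop = FALSE]
}

#' Regularize records onto a complete minute grid
#'
#' Output spans the floor-minute of the first record through the last at
#' 1-minute steps; minutes absent from the input become rows of `NA`.
#' Records not on the minute grid (leftover delayed readings) are dropped
#' with a warning.
#'
#' @param records data frame with POSIXct `timestamp` plus value columns.
#' @return data frame on the complete minute grid.
#' @export
regularize_timeline <- function(records) {
  if (nrow(records) == 0) return(records)
  records <- records[order(records$timestamp), , drop = FALSE]
  off <- as.numeric(records$timestamp) %% 60 != 0
  if (any(off)) {
    warning(sprintf("%d off-grid records dropped during regularization",
                    sum(off)))
    records <- records[!off, , drop = FALSE]
    if (nrow(records) == 0) return(records)
  }
  grid <- seq(floor_minute(records$timestamp[1]),
              floor_minute(records$timestamp[nrow(records)]), by = 60)
  out <- data.frame(timestamp = grid)
  idx <- match(as.numeric(grid), as.numeric(records$timestamp))
  for (nm in setdiff(names(records), "timestamp")) {
    out[[nm]] <- records[[nm]][idx]
  }
  out
}

#' Linearly interpolate short missing runs
#'
#' Contiguous missing runs shorter than `short_gap_max` (i.e. of length
#' `<= short_gap_max - 1`) that are bounded by observed values on both sides
#' are filled by linear interpolation; longer and boundary-touching runs are
#' left untouched.
#'
#' @param values numeric vector.
#' @param short_gap_max exclusive length bound, minutes.
#' @return numeric vector with short gaps filled.
#' @export
fill_short_gaps <- function(values, short_gap_max = 5) {
  n <- length(values)
  gaps <- find_gaps(values)
  if (nrow(gaps) == 0) return(values)
  for (i in seq_len(nrow(gaps))) {
    s <- gaps$start[i]; L <- gaps$length[i]; e <- s + L - 1L
    if (L >= short_gap_max) next
    if (s == 1L || e == n) next
    values[s:e] <- approx(x = c(s - 1L, e + 1L),
                          y = values[c(s - 1L, e + 1L)],
                          xout = s:e)$y
  }
  values
}

#' Aggregate a minute-level series to hourly means
#'
#' An hour's value is the mean of its valid minutes when at least
#' `min_valid_minutes` minutes are present; otherwise the hour is missing.
#' The output covers every hour spanned by the minute grid.
#'
#' @param records minute-grid data frame (from [regularize_timeline()]) with
#'   `timestamp` and `pm25` columns; other numeric columns are averaged over
#'   whatever minutes are present.
#' @param min_valid_minutes inclusive threshold.
#' @return a [pm_series()].
#' @export
aggregate_hourly <- function(records, min_valid_minutes = 40) {
  hour_start <- as.POSIXct(floor(as.numeric(records$timestamp) / 3600) * 3600,
                           origin = "1970-01-01", tz = "UTC")
  grid <- seq(min(hour_start), max(hour_start), by = 3600)
  f <- factor(as.numeric(hour_start), levels = as.numeric(grid))
  counts <- tapply(!is.na(records$pm25), f, sum)
  counts[is.na(counts)] <- 0
  means <- tapply(records$pm25, f, function(v) mean(v, na.rm = TRUE))
  pm <- ifelse(counts >= min_valid_minutes, means, NA_real_)
  extra <- list()
  for (nm in setdiff(names(records), c("timestamp", "pm25"))) {
    if (!is.numeric(records[[nm]])) next
    m <- tapply(records[[nm]], f, function(v) mean(v, na.rm = TRUE))
    m[is.nan(m)] <- NA_real_
    extra[[nm]] <- as.numeric(m)
  }
  do.call(pm_series, c(list(timestamp = grid, pm25 = as.numeric(pm)), extra))
}

#' Secondary outlier flags on the hourly series
#'
#' An hour is flagged iff its value exceeds the hard threshold, OR it
#' exceeds the spike threshold and is more than `ratio` x the previous
#' hourly reading (previous present).
#'
#' @param values hourly numeric vector.
#' @param config a [qc_config()].
#' @return logical mask.
#' @export
flag_hourly_outliers <- function(values, config = qc_config()) {
  n <- length(values)
  prev <- c(NA_real_, values[-n])
  hard <- !is.na(values) & values > config$hourly_hard_threshold
  spike <- !is.na(values) & !is.na(prev) &
    values > config$hourly_spike_threshold &
    values > config$hourly_spike_ratio * prev
  hard | spike
}

#' Run the full minute-to-hourly QC pipeline
#'
#' Stages, in order: minute-level spike and IQR outlier masks (computed on
#' the raw values and applied as a union), delayed-timestamp correction,
#' timeline regularization, short-gap linear interpolation, hourly
#' aggregation, secondary hourly outlier masking. No stage deletes rows:
#' outliers become missing values, preserving them for gap-filling.
#'
#' @param records minute-level data frame with POSIXct `timestamp` and
#'   `pm25` (plus optional covariate columns).
#' @param config a [qc_config()].
#' @return list with `hourly` (a [pm_series()]), `minute` (the cleaned
#'   minute grid), and `flags` (counts per stage).
#' @export
qc_pipeline <- function(records, config = qc_config()) {
  spike <- flag_spike_outliers(records$pm25, config$spike_threshold,
                               config$spike_ratio)
  iqr <- flag_iqr_outliers(records$pm25, config$iqr_multiplier)
  records$pm25[spike | iqr] <- NA_real_

  records <- correct_delayed_timestamps(records, config$delay_tolerance)
  records <- regularize_timeline(records)
  records$pm25 <- fill_short_gaps(records$pm25, config$short_gap_max)

  hourly <- aggregate_hourly(records, config$min_valid_minutes)
  hflags <- flag_hourly_outliers(hourly$pm25, config)
  hourly$pm25[hflags] <- NA_real_

  list(hourly = hourly, minute = records,
       flags = c(minute_spike = sum(spike), minute_iqr = sum(iqr),
                 hourly = sum(hflags)))
}

#' Plain-text completeness report
#'
#' @param series a [pm_series()].
#' @return a data frame with per-month record counts and completeness
#'   percentages.
#' @export
completeness_report <- function(series) {
  mon <- format(series$timestamp, "%Y-%m", tz = "UTC")
  agg <- tapply(!is.na(series$pm25), mon, mean)
  data.frame(month = names(agg), n_hours = as.integer(table(mon)[names(agg)]),
             completeness_pct = round(100 * as.numeric(agg), 1),
             row.names = NULL)
}

#' Read minute-level records from CSV or the deposited SQLite database
#'
#' The SQLite reader targets a single measurement table; column names are
#' configurable to match the deposit's schema. Requires the RSQLite package.
#'
#' @param path file path.
#' @param table table name (SQLite only).
#' @param columns named character vector mapping standard names
#'   (`timestamp`, `pm25`, `temperature`, `humidity`) to source columns;
#'   entries absent from the source are skipped.
#' @return data frame with POSIXct `timestamp` and numeric value columns.
#' @export
read_minute_sqlite <- function(path, table = "measurements",
                               columns = c(timestamp = "timestamp",
                                           pm25 = "pm25",
                                           temperature = "temperature",
                                           humidity = "humidity")) {
  if (!requireNamespace("RSQLite", quietly = TRUE) ||
      !requireNamespace("DBI", quietly = TRUE)) {
    stop_config("read_minute_sqlite requires the RSQLite and DBI packages")
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  df <- DBI::dbReadTable(con, table)
  standardize_minute_columns(df, columns)
}

#' @rdname read_minute_sqlite
#' @export
read_minute_csv <- function(path,
                            columns = c(timestamp = "timestamp",
                                        pm25 = "pm25",
                                        temperature = "temperature",
                                        humidity = "humidity")) {
  standardize_minute_columns(read.csv(path, stringsAsFactors = FALSE), columns)
}

standardize_minute_columns <- function(df, columns) {
  if (!columns[["timestamp"]] %in% names(df)) {
    stop_config(sprintf("source has no '%s' column", columns[["timestamp"]]))
  }
  ts_raw <- df[[columns[["timestamp"]]]]
  ts <- if (is.numeric(ts_raw)) {
    as.POSIXct(ts_raw, origin = "1970-01-01", tz = "UTC")
  } else {
    as.POSIXct(ts_raw, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                              "%Y-%m-%d %H:%M:%S"))
  }
  out <- data.frame(timestamp = ts)
  for (std in setdiff(names(columns), "timestamp")) {
    src <- columns[[std]]
    if (src %in% names(df)) out[[std]] <- as.numeric(df[[src]])
  }
  out[order(out$timestamp), , drop = FALSE]
}
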