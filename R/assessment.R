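WHO_BAND_LABELS <- c("below", "1-2x", "2-4x", "4-8x", ">8x")

#' Classify PM2.5 against the WHO daily guideline
#'
#' Bands partition `[0, Inf)` in multiples of the WHO 24-hour guideline
#' (15 ug/m3): below, 1-2x [15, 30), 2-4x [30, 60), 4-8x [60, 120),
#' >8x [120, Inf). Boundary values go to the upper band. Hourly values are
#' compared against the daily guideline - a deliberate convention of this
#' assessment style, flagged in the documentation.
#'
#' @param pm25 numeric vector of concentrations.
#' @param who_threshold guideline value, ug/m3.
#' @return factor with the band labels above.
#' @export
classify_exceedance <- function(pm25, who_threshold = 15) {
  breaks <- who_threshold * c(0, 1, 2, 4, 8, Inf)
  cut(pm25, breaks = breaks, labels = WHO_BAND_LABELS, right = FALSE,
      include.lowest = TRUE)
}

group_keys <- function(series, by) {
  switch(by,
         overall = rep("overall", nrow(series)),
         month = format(series$timestamp, "%Y-%m", tz = "UTC"),
         season = c("winter", "spring", "summer",
                    "autumn")[season_of(series$timestamp)],
         stop_config("by must be one of overall/month/season"))
}

#' Exceedance-band fractions per group
#'
#' @param series a filled [pm_series()].
#' @param by grouping: `"overall"`, `"month"`, or `"season"`.
#' @param who_threshold guideline value, ug/m3.
#' @return data frame, one row per group, one column per band (fractions
#'   summing to 1) plus `exceeding`, the total fraction above the
#'   guideline.
#' @export
exceedance_summary <- function(series, by = c("overall", "month", "season"),
                               who_threshold = 15) {
  by <- match.arg(by)
  band <- classify_exceedance(series$pm25, who_threshold)
  keep <- !is.na(band)
  key <- group_keys(series, by)[keep]
  band <- band[keep]
  tab <- prop.table(table(key, band), margin = 1)
  out <- data.frame(group = rownames(tab))
  for (b in WHO_BAND_LABELS) out[[b]] <- as.numeric(tab[, b])
  out$exceeding <- 1 - out$below
  out
}

#' Default AQI breakpoint table for PM2.5
#'
#' US EPA PM2.5 breakpoints (pre-2024 revision): concentration intervals
#' mapped piecewise-linearly onto index intervals, with the standard six
#' category names. Breakpoints are configuration data, not code - pass a
#' modified table to [compute_aqi()] to use another national index.
#'
#' @return data frame with `c_lo`, `c_hi`, `i_lo`, `i_hi`, `category`.
#' @export
aqi_breakpoints <- function() {
  data.frame(
    c_lo = c(0.0, 12.1, 35.5, 55.5, 150.5, 250.5, 350.5),
    c_hi = c(12.0, 35.4, 55.4, 150.4, 250.4, 350.4, 500.4),
    i_lo = c(0, 51, 101, 151, 201, 301, 401),
    i_hi = c(50, 100, 150, 200, 300, 400, 500),
    category = c("Good", "Moderate", "Unhealthy for Sensitive Groups",
                 "Unhealthy", "Very Unhealthy", "Hazardous", "Hazardous"))
}

#' Compute the air quality index for PM2.5 concentrations
#'
#' Piecewise-linear interpolation over a configurable breakpoint table;
#' concentrations are truncated to 0.1 ug/m3 (the table's resolution)
#' before lookup, indices rounded to the nearest integer. Monotone
#' non-decreasing in PM2.5. Values above the table's last breakpoint are
#' capped at the top index.
#'
#' @param pm25 numeric vector of concentrations.
#' @param breakpoints breakpoint table, see [aqi_breakpoints()].
#' @return data frame with `index` and `category`.
#' @export
compute_aqi <- function(pm25, breakpoints = aqi_breakpoints()) {
  c_trunc <- floor(pm25 * 10) / 10
  idx <- rep(NA_real_, length(pm25))
  cat_ <- rep(NA_character_, length(pm25))
  for (r in seq_len(nrow(breakpoints))) {
    b <- breakpoints[r, ]
    sel <- !is.na(c_trunc) & c_trunc >= b$c_lo & c_trunc <= b$c_hi
    idx[sel] <- b$i_lo + (c_trunc[sel] - b$c_lo) /
      (b$c_hi - b$c_lo) * (b$i_hi - b$i_lo)
    cat_[sel] <- b$category
  }
  over <- !is.na(c_trunc) & c_trunc > max(breakpoints$c_hi)
  idx[over] <- max(breakpoints$i_hi)
  cat_[over] <- breakpoints$category[nrow(breakpoints)]
  data.frame(index = round(idx), category = cat_)
}

# adjusted Fisher-Pearson moment coefficients (the bias-corrected
# definitions common statistical software reports)
sample_skewness <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (n < 3 || s == 0) return(NA_real_)
  g1 <- mean((x - mean(x))^3) / (sqrt(mean((x - mean(x))^2)))^3
  sqrt(n * (n - 1)) / (n - 2) * g1
}

sample_kurtosis <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (n < 4 || s == 0) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  g2 <- mean((x - mean(x))^4) / m2^2 - 3
  ((n - 1) / ((n - 2) * (n - 3))) * ((n + 1) * g2 + 6)
}

#' Descriptive statistics of a series per group
#'
#' Count, mean, SD, minimum, quartiles, maximum, skewness and excess
#' kurtosis (bias-corrected moment definitions) per group.
#'
#' @param series a [pm_series()].
#' @param by `"overall"`, `"month"`, or `"season"`.
#' @return data frame, one row per group.
#' @export
descriptive_stats <- function(series, by = c("overall", "month", "season")) {
  by <- match.arg(by)
  key <- group_keys(series, by)
  groups <- split(series$pm25, key)
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    v <- v[!is.na(v)]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, count = length(v), mean = mean(v), sd = sd(v),
               min = min(v), q25 = q[1], median = q[2], q75 = q[3],
               max = max(v), skewness = sample_skewness(v),
               kurtosis = sample_kurtosis(v))
  })
  do.call(rbind, rows)
}

#' Per-hour assessment records on a filled series
#'
#' Joins the filled series with its exceedance band, AQI index/category and
#' fill provenance (observed vs. imputed).
#'
#' @param filled a filled [pm_series()].
#' @param original the pre-fill series (same grid) used to derive
#'   provenance; if omitted, everything is marked observed.
#' @param who_threshold guideline value, ug/m3.
#' @return data frame with one row per hour.
#' @export
assessment_records <- function(filled, original = NULL, who_threshold = 15) {
  aqi <- compute_aqi(filled$pm25)
  provenance <- if (is.null(original)) {
    rep("observed", nrow(filled))
  } else {
    ifelse(is.na(original$pm25), "imputed", "observed")
  }
  data.frame(timestamp = filled$timestamp, pm25 = filled$pm25,
             band = classify_exceedance(filled$pm25, who_threshold),
             aqi = aqi$index, aqi_category = aqi$category,
             provenance = provenance)
}
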