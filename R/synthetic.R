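#' Configuration for the synthetic PM2.5 generator
#'
#' The generator emulates the qualitative structure of urban PM2.5 exposure
#' series from a continental-climate city: positive, right-skewed
#' (lognormal-ish) marginals, a bimodal diurnal cycle with morning and
#' evening peaks, a winter-elevated seasonal cycle, autocorrelated
#' multiplicative noise, a negative wind-speed coupling, and weakly coupled
#' temperature/humidity covariates.
#'
#' Concentrations are built as
#' `base_level * seasonal * diurnal * exp(AR(1) noise) + wind_coupling * (Ff - mean(Ff))`
#' and clipped at zero.
#'
#' @param n_hours number of hourly records (>= 48).
#' @param start_timestamp first timestamp (parsed as UTC).
#' @param base_level baseline concentration, ug/m3.
#' @param diurnal_peaks list of two `c(hour, amplitude)` pairs; amplitudes
#'   are fractions of the baseline. Defaults place peaks at 08:00 and 19:00,
#'   matching the morning (7-9 h) / evening (18-21 h) rush structure of
#'   urban PM2.5.
#' @param seasonal_amplitude fractional amplitude of the annual cosine
#'   (peak mid-January). The default 0.175 yields winter means ~35-40%
#'   above summer means.
#' @param ar_coefficient AR(1) coefficient of the log-scale noise, in [0, 1).
#' @param noise_scale innovation SD of the log-scale AR(1) noise.
#' @param wind_coupling additive coupling (ug/m3 per m/s) to the wind-speed
#'   anomaly; must be <= 0 so PM2.5 and wind speed correlate negatively.
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_hours = 8760,
                             start_timestamp = "2024-01-01 00:00:00",
                             base_level = 20,
                             diurnal_peaks = list(c(8, 0.5), c(19, 0.6)),
                             seasonal_amplitude = 0.175,
                             ar_coefficient = 0.8,
                             noise_scale = 0.3,
                             wind_coupling = -2.0,
                             seed = 1L) {
  if (!is_count(n_hours)) stop_config("n_hours must be a positive count")
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    stop_config("ar_coefficient must lie in [0, 1)")
  }
  if (wind_coupling > 0) stop_config("wind_coupling must be <= 0")
  if (base_level <= 0 || noise_scale < 0) {
    stop_config("base_level must be positive and noise_scale non-negative")
  }
  structure(list(n_hours = as.integer(n_hours),
                 start_timestamp = as.POSIXct(start_timestamp, tz = "UTC"),
                 base_level = base_level, diurnal_peaks = diurnal_peaks,
                 seasonal_amplitude = seasonal_amplitude,
                 ar_coefficient = ar_coefficient, noise_scale = noise_scale,
                 wind_coupling = wind_coupling, seed = as.integer(seed)),
            class = "generator_config")
}

ar1_path <- function(n, phi, sd_innov) {
  e <- numeric(n)
  if (sd_innov == 0) return(e)
  marg <- sd_innov / sqrt(1 - phi^2)
  e[1] <- rnorm(1, 0, marg)
  innov <- rnorm(n - 1, 0, sd_innov)
  for (i in seq_len(n - 1)) e[i + 1] <- phi * e[i] + innov[i]
  e
}

# circular gaussian bump profile over hours 0..23
diurnal_profile <- function(hours, peaks, width = 2.5) {
  f <- rep(1, length(hours))
  for (p in peaks) {
    d <- abs(hours - p[1])
    d <- pmin(d, 24 - d)
    f <- f + p[2] * exp(-0.5 * (d / width)^2)
  }
  f
}

#' Generate a synthetic hourly PM2.5 series with covariates
#'
#' @param config a [generator_config()].
#' @return a [pm_series()] with columns `pm25`, `T`, `U`, `Ff`, `DD`,
#'   `hour`, `season`. Concentrations are non-negative; a fixed seed gives
#'   bit-identical output.
#' @export
generate_series <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop_config("config must be a generator_config")
  }
  if (config$n_hours < 48) stop_config("n_hours must be >= 48")
  n <- config$n_hours
  ts <- config$start_timestamp + 3600 * (seq_len(n) - 1)
  hrs <- hour_of_day(ts)
  doy <- as.integer(format(ts, "%j", tz = "UTC"))

  with_seed(config$seed, {
    seasonal <- 1 + config$seasonal_amplitude *
      cos(2 * pi * (doy - 15) / 365.25)
    diurnal <- diurnal_profile(hrs, config$diurnal_peaks)
    logn <- ar1_path(n, config$ar_coefficient, config$noise_scale)

    # wind speed: positive, autocorrelated, slightly stronger by day
    ff <- 3 + 0.5 * sin(2 * pi * (hrs - 14) / 24) +
      ar1_path(n, 0.7, 1.8 * sqrt(1 - 0.7^2))
    ff <- pmax(ff, 0)
    # wind direction: wrapped random walk in degrees
    dd <- (cumsum(rnorm(n, 0, 25)) + runif(1, 0, 360)) %% 360
    # temperature: seasonal + diurnal + AR noise (continental amplitude)
    temp <- 7 - 18 * cos(2 * pi * (doy - 196) / 365.25) +
      4 * sin(2 * pi * (hrs - 15) / 24) + ar1_path(n, 0.9, 1.2)
    # humidity: anti-coupled to temperature anomaly, clamped
    u <- 70 - 0.8 * (temp - mean(temp)) + ar1_path(n, 0.8, 4)
    u <- pmin(pmax(u, 15), 100)

    pm <- config$base_level * seasonal * diurnal * exp(logn) +
      config$wind_coupling * (ff - mean(ff))
    pm <- pmax(pm, 0)

    pm_series(ts, pm, `T` = round(temp, 2), U = round(u, 1),
              Ff = round(ff, 2), DD = round(dd, 1))
  })
}

#' Inject synthetic gaps into a series
#'
#' Carves `floor(fraction * N / gap_length)` non-overlapping gaps of equal
#' length into the series, each at least `min_separation` points from every
#' other gap and from both series boundaries, so that full fixed-size
#' contexts always exist around every gap. Placement is rejection sampling,
#' deterministic for a fixed seed. The held-out true values are returned in
#' the gap table for later scoring.
#'
#' @param series a [pm_series()] (or numeric vector).
#' @param gap_length gap length L in hours.
#' @param fraction missing fraction f; number of gaps is
#'   `floor(f * N / L)`.
#' @param seed integer seed controlling placement.
#' @param min_separation minimum distance (points) between gaps and from the
#'   series boundaries; default 32, the maximum context any fixed-context
#'   imputer uses.
#' @param n_gaps optional explicit number of gaps, overriding the fraction
#'   rule (used by the benchmark harness to guarantee at least one gap).
#' @return list with `series` (values at gap positions set to `NA`) and
#'   `gaps`, a data frame with columns `start`, `length`, `left_context`,
#'   `right_context` and a list-column `truth` holding the removed values.
#' @export
inject_missingness <- function(series, gap_length, fraction = 0.05,
                               seed = 1L, min_separation = 32L,
                               n_gaps = NULL) {
  vals <- series_values(series)
  n <- length(vals)
  if (!is_count(gap_length)) stop_config("gap_length must be a positive count")
  if (fraction < 0 || fraction >= 1) stop_config("fraction must be in [0, 1)")
  L <- as.integer(gap_length)
  sep <- as.integer(min_separation)
  k <- if (is.null(n_gaps)) floor(fraction * n / L) else as.integer(n_gaps)

  empty <- data.frame(start = integer(), length = integer(),
                      left_context = integer(), right_context = integer())
  empty$truth <- list()
  if (k == 0) return(list(series = series, gaps = empty))

  if (k * L + (k + 1) * sep > n) {
    stop_pm(sprintf(paste0("cannot place %d gaps of length %d in %d points ",
                           "with separation %d: need %d points (boundary/",
                           "separation constraint is binding)"),
                    k, L, n, sep, k * L + (k + 1) * sep),
            "pmgapfill_placement")
  }

  lo <- sep + 1L
  hi <- n - L - sep + 1L
  starts <- integer(0)
  with_seed(seed, {
    tries <- 0L
    cap <- 1000L * k
    while (length(starts) < k) {
      tries <- tries + 1L
      if (tries > cap) {
        stop_pm(sprintf(paste0("gap placement failed after %d rejection-",
                               "sampling iterations: separation constraint ",
                               "(>= %d points between gaps) is binding"),
                        cap, sep), "pmgapfill_placement")
      }
      cand <- sample.int(hi - lo + 1L, 1L) + lo - 1L
      ok <- all(abs(starts - cand) >= L + sep)
      if (ok) starts <- c(starts, cand)
    }
  })
  starts <- sort(starts)

  out <- vals
  truth <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- starts[i]:(starts[i] + L - 1L)
    truth[[i]] <- vals[idx]
    out[idx] <- NA_real_
  }
  if (inherits(series, "pm_series") || is.data.frame(series)) {
    series$pm25 <- out
    res_series <- series
  } else {
    res_series <- out
  }
  gaps <- find_gap_table(out, starts, rep(L, k))
  gaps$truth <- truth
  list(series = res_series, gaps = gaps)
}
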