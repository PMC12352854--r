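# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# one year of default synthetic data
year_series <- function() {
  fixture("year_series", function() {
    generate_series(generator_config(n_hours = 8760, seed = 1))
  })
}

# small series for fast supervised-imputer tests
small_series <- function() {
  fixture("small_series", function() {
    generate_series(generator_config(n_hours = 1200, seed = 42))
  })
}

# simple gap descriptor
gap_at <- function(start, length) list(start = as.integer(start),
                                       length = as.integer(length))

# minute-level records fixture: a clean day of minute data plus seeded
# defects (spikes, an extreme outlier, a delayed timestamp, short gaps)
minute_fixture <- function() {
  fixture("minute_fixture", function() {
    ts <- seq(as.POSIXct("2024-06-01 00:00:00", tz = "UTC"),
              by = 60, length.out = 24 * 60)
    set.seed(99)
    pm <- 30 + 10 * sin(2 * pi * seq_along(ts) / (24 * 60)) + rnorm(length(ts))
    df <- data.frame(timestamp = ts, pm25 = pm)
    df$pm25[500] <- 250                      # spike: > 200 and > 3x prev
    df$pm25[900] <- 5000                     # extreme IQR outlier
    df$pm25[300:302] <- NA                   # short gap (3 min)
    df$pm25[700:720] <- NA                   # long gap (21 min)
    df$timestamp[1000] <- df$timestamp[1000] + 10  # delayed reading
    df <- df[-c(1100:1105), ]                # absent minutes
    df
  })
}
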