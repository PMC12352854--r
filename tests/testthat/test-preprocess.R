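test_that("spike rule flags only the stated conjunction", {
  expect_identical(flag_spike_outliers(c(50, 210)), c(FALSE, TRUE))
  expect_identical(flag_spike_outliers(c(100, 210)), c(FALSE, FALSE))
  expect_identical(flag_spike_outliers(c(10, 150, 199)), rep(FALSE, 3))
  # missing predecessor never flags; first point has no predecessor
  expect_identical(flag_spike_outliers(c(NA, 500, 10)), c(FALSE, FALSE, FALSE))
  expect_identical(flag_spike_outliers(c(500, 10)), c(FALSE, FALSE))
})

test_that("IQR rule uses strict fences and linear-interpolated quartiles", {
  expect_false(any(flag_iqr_outliers(rep(5, 10))))
  v <- c(1:100, 10000)
  mask <- flag_iqr_outliers(v)
  # brute-force oracle
  q1 <- quantile(v, 0.25, type = 7); q3 <- quantile(v, 0.75, type = 7)
  fence <- c(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1))
  expect_identical(mask, v < fence[1] | v > fence[2])
  expect_true(mask[101]); expect_false(any(mask[1:100]))
  expect_error(flag_iqr_outliers(c(1, 2, 3)),
               class = "pmgapfill_degenerate_input")
})

test_that("delayed timestamps snap back under a strict tolerance", {
  t0 <- as.POSIXct("2024-06-01 12:07:00", tz = "UTC")
  rec <- data.frame(timestamp = c(t0 - 60, t0 + 14, t0 + 60 + 15),
                    pm25 = c(1, 2, 3))
  out <- correct_delayed_timestamps(rec, 15)
  expect_equal(out$timestamp[out$pm25 == 2], t0)        # 14 s: moved
  expect_equal(out$timestamp[out$pm25 == 3], t0 + 75)   # 15 s: not moved
  expect_equal(out$timestamp[out$pm25 == 1], t0 - 60)   # on-grid: unchanged
  # collision: target minute occupied -> left in place with warning
  rec2 <- data.frame(timestamp = c(t0, t0 + 10), pm25 = c(1, 2))
  expect_warning(out2 <- correct_delayed_timestamps(rec2, 15), "occupied")
  expect_equal(out2$timestamp[out2$pm25 == 2], t0 + 10)
})

test_that("timeline regularization inserts NA rows on the minute grid", {
  t0 <- as.POSIXct("2024-06-01 00:00:00", tz = "UTC")
  rec <- data.frame(timestamp = t0 + 60 * c(0, 1, 3), pm25 = c(1, 2, 4))
  out <- regularize_timeline(rec)
  expect_equal(nrow(out), 4)
  expect_equal(out$pm25, c(1, 2, NA, 4))
  # already complete grid: unchanged
  full <- data.frame(timestamp = t0 + 60 * 0:3, pm25 = 1:4)
  expect_equal(regularize_timeline(full)$pm25, 1:4)
  # empty input passes through
  expect_equal(nrow(regularize_timeline(full[0, ])), 0)
})

test_that("short-gap interpolation fills runs strictly shorter than the bound", {
  v <- c(10, NA, NA, NA, NA, 20)
  expect_equal(fill_short_gaps(v, 5), c(10, 12, 14, 16, 18, 20))
  v5 <- c(10, rep(NA, 5), 20)
  expect_identical(fill_short_gaps(v5, 5), v5)   # 5 is not shorter than 5
  vb <- c(NA, NA, 5, 6)
  expect_identical(fill_short_gaps(vb, 5), vb)   # no left anchor
})

test_that("hourly aggregation honours the inclusive minute threshold", {
  t0 <- as.POSIXct("2024-06-01 00:00:00", tz = "UTC")
  mk <- function(n_valid) {
    pm <- c(rep(30, n_valid), rep(NA, 60 - n_valid))
    data.frame(timestamp = t0 + 60 * 0:59, pm25 = pm)
  }
  expect_equal(aggregate_hourly(mk(40))$pm25, 30)
  expect_true(is.na(aggregate_hourly(mk(39))$pm25))
  expect_equal(aggregate_hourly(mk(60))$pm25, 30)
})

test_that("secondary hourly rule applies both disjuncts", {
  expect_identical(flag_hourly_outliers(c(100, 271)), c(FALSE, TRUE))
  expect_identical(flag_hourly_outliers(c(100, 210)), c(FALSE, FALSE))
  expect_identical(flag_hourly_outliers(c(60, 210)), c(FALSE, TRUE))
  # first disjunct is neighbour-independent
  expect_identical(flag_hourly_outliers(c(NA, 271)), c(FALSE, TRUE))
})

test_that("full pipeline masks defects, preserves rows and is idempotent", {
  res <- qc_pipeline(minute_fixture())
  expect_s3_class(res$hourly, "pm_series")
  # hourly output count equals hours spanned by the minute grid
  expect_equal(nrow(res$hourly), 24)
  # the injected spike and extreme value were masked, not deleted
  expect_gte(res$flags[["minute_spike"]], 1)
  expect_gte(res$flags[["minute_iqr"]], 1)
  expect_equal(nrow(res$minute), 24 * 60)
  # short 3-minute gap interpolated away; 21-minute gap survives
  expect_false(anyNA(res$minute$pm25[300:302]))
  expect_true(anyNA(res$minute$pm25[700:720]))
  # idempotence: re-running the minute stages on the cleaned grid changes
  # nothing
  again <- qc_pipeline(res$minute)
  expect_equal(again$minute$pm25, res$minute$pm25)
  expect_equal(again$hourly$pm25, res$hourly$pm25)
  expect_true(all(again$flags == 0))
})

test_that("minute CSV and SQLite readers agree on the same records", {
  rec <- minute_fixture()
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(timestamp = format(rec$timestamp, "%Y-%m-%d %H:%M:%S",
                                          tz = "UTC"),
                       pm25 = rec$pm25), csv, row.names = FALSE)
  from_csv <- read_minute_csv(csv)
  db <- tempfile(fileext = ".sqlite")
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  DBI::dbWriteTable(con, "measurements",
                    data.frame(timestamp = as.numeric(rec$timestamp),
                               pm25 = rec$pm25))
  DBI::dbDisconnect(con)
  from_db <- read_minute_sqlite(db)
  expect_equal(from_csv$timestamp, from_db$timestamp)
  expect_equal(from_csv$pm25, from_db$pm25)
})

test_that("completeness report fractions are sane", {
  s <- small_series()
  s$pm25[1:100] <- NA
  rep_ <- completeness_report(s)
  expect_true(all(rep_$completeness_pct >= 0 & rep_$completeness_pct <= 100))
  expect_equal(sum(rep_$n_hours), nrow(s))
})
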