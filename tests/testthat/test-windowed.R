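const_series <- function(n, value = 25) {
  ts <- seq(as.POSIXct("2024-01-01", tz = "UTC"), by = 3600, length.out = n)
  pm_series(ts, rep(value, n))
}

test_that("training window counts match the sliding-window arithmetic", {
  s <- small_series()[1:100, ]
  ar <- imputer_spec("autoregressive", window = 32, horizon = 12)
  expect_equal(nrow(build_training_windows(s, ar)$inputs), 68)  # 100 - 32
  s2s <- imputer_spec("seq2seq", "bidirectional", window = 32, horizon = 12)
  # single-flank seq2seq examples: 100 - 32 - 12 + 1
  expect_equal(nrow(build_training_windows(s, s2s, sides = "left")$inputs), 57)
  # dual-flank examples: 100 - 2*32 - 12 + 1
  uni <- imputer_spec("seq2seq", "unidirectional", window = 32, horizon = 12)
  ws <- build_training_windows(s, uni)
  expect_equal(nrow(ws$inputs), 25)
  expect_equal(ncol(ws$inputs), 64)
  expect_equal(ncol(ws$targets), 12)
  # a hole every 33rd position starves a window-32 builder
  holey <- small_series()[1:300, ]
  holey$pm25[seq(33, 300, by = 33)] <- NA
  expect_error(build_training_windows(holey, ar),
               class = "pmgapfill_insufficient_data")
})

test_that("window examples and targets are fully observed", {
  s <- small_series()[1:200, ]
  s$pm25[c(50, 120)] <- NA
  ws <- build_training_windows(s, imputer_spec("seq2seq", "bidirectional",
                                               window = 10, horizon = 5),
                               sides = "left")
  expect_false(anyNA(ws$inputs))
  expect_false(anyNA(ws$targets))
})

test_that("multivariate flattening is time-major then feature", {
  s <- small_series()[1:60, ]
  spec <- imputer_spec("autoregressive", variables = "multivariate",
                       window = 3, horizon = 1)
  ws <- build_training_windows(s, spec)
  # 5 features x window 3 = 15 columns; first example covers rows 1:3
  expect_equal(ncol(ws$inputs), 15)
  feats <- assemble_features(s, 1:3, "multivariate", spec$feature_names)
  expect_equal(ws$inputs[1, ], as.numeric(t(feats)))
  # multivariate window-32 rows have 160 columns
  spec32 <- imputer_spec("autoregressive", variables = "multivariate",
                         window = 32, horizon = 1)
  expect_equal(ncol(build_training_windows(s, spec32)$inputs), 160)
})

test_that("temporal feature encoding follows the convention", {
  ts <- as.POSIXct("2024-12-15 13:00:00", tz = "UTC")
  expect_equal(season_of(ts), 1)          # December -> winter
  expect_equal(hour_of_day(ts), 13)
  expect_equal(season_of(as.POSIXct("2024-04-01", tz = "UTC")), 2)
  expect_equal(season_of(as.POSIXct("2024-07-01", tz = "UTC")), 3)
  expect_equal(season_of(as.POSIXct("2024-10-01", tz = "UTC")), 4)
  s <- small_series()
  f <- assemble_features(s, 1:5, "univariate")
  expect_equal(colnames(f), "pm25")
  expect_error(assemble_features(s, 1:5, "multivariate",
                                 c("pm25", "nope")),
               class = "pmgapfill_invalid_config")
})

test_that("scaler standardizes on train only, inverts exactly, guards constants", {
  ts <- seq(as.POSIXct("2024-01-01", tz = "UTC"), by = 3600, length.out = 2)
  train <- pm_series(ts, c(0, 2))
  sc <- scaler_fit(train, "pm25")
  expect_equal(scaler_transform(sc, c(0, 2)), c(-1, 1))  # population SD = 1
  x <- rnorm(50, 10, 4)
  expect_equal(scaler_inverse(sc, scaler_transform(sc, x)), x,
               tolerance = 1e-12)
  const <- pm_series(ts, c(5, 5))
  sc2 <- scaler_fit(const, "pm25")
  expect_equal(scaler_transform(sc2, c(5, 5)), c(0, 0))  # SD-floor guard
})

test_that("chronological split has no shuffling and validates fractions", {
  s <- small_series()[1:10, ]
  parts <- split_time_based(s, 0.8)
  expect_equal(nrow(parts$train), 8)
  expect_equal(nrow(parts$test), 2)
  expect_true(max(parts$train$timestamp) < min(parts$test$timestamp))
  expect_equal(floor(0.8 * 5791), 4632)  # the deposit-scale arithmetic
  parts1 <- split_time_based(s, 1.0)
  expect_equal(nrow(parts1$test), 0)
  expect_error(run_benchmark(s, benchmark_methods("global-mean"),
                             benchmark_config(gap_lengths = 5L,
                                              train_fraction = 1.0)),
               class = "pmgapfill_invalid_config")
})

test_that("bidirectional fusion weights are the declared linear scheme", {
  expect_equal(fuse_bidirectional(1, 0), 0.5)          # L = 1: plain average
  expect_equal(fuse_bidirectional(c(1, 1, 1), c(0, 0, 0)),
               c(0.75, 0.5, 0.25))                     # (L+1-i)/(L+1)
  v <- rnorm(7)
  expect_equal(fuse_bidirectional(v, v), v)            # convexity
  set.seed(3)
  f <- rnorm(12); b <- rnorm(12)
  fused <- fuse_bidirectional(f, b)
  expect_true(all(fused >= pmin(f, b) - 1e-12 & fused <= pmax(f, b) + 1e-12))
  expect_error(fuse_bidirectional(1:3, 1:2), class = "pmgapfill_contract")
  expect_error(fuse_bidirectional(numeric(0), numeric(0)),
               class = "pmgapfill_contract")
})

test_that("autoregressive roll extrapolates a last-value backend constantly", {
  # a fitted imputer whose backend always returns the last input value
  spec <- imputer_spec("autoregressive", window = 4, horizon = 1)
  sc <- structure(list(center = c(pm25 = 0), scale = c(pm25 = 1),
                       features = "pm25"), class = "pm_scaler")
  last_value_backend <- structure(
    list(backend = "linear", p = 4, h = 1,
         models = list(list(kind = "linear", beta = c(0, 0, 0, 0, 1)))),
    class = "fitted_backend")
  fit <- structure(list(spec = spec, scaler = sc,
                        forward = last_value_backend, backward = NULL),
                   class = "fitted_imputer")
  expect_equal(predict_autoregressive(fit, c(5, 6, 7, 8), 5), rep(8, 5))
  expect_error(predict_autoregressive(fit, c(5, 6, 7), 2),
               class = "pmgapfill_contract")
})

test_that("seq2seq and autoregressive agree at horizon 1 with identical fits", {
  s <- small_series()[1:300, ]
  spec <- imputer_spec("autoregressive", window = 8, horizon = 1)
  sc <- scaler_fit(s, "pm25")
  scaled <- scale_series(s, sc)
  ws <- build_training_windows(scaled, spec, sides = "left")
  backend <- backend_fit("forest", ws$inputs, ws$targets, 20, seed = 5)
  fit_ar <- structure(list(spec = spec, scaler = sc, forward = backend,
                           backward = NULL), class = "fitted_imputer")
  ctx <- s$pm25[101:108]
  one_step <- predict_autoregressive(fit_ar, ctx, 1)
  x <- matrix(scaler_transform(sc, ctx), nrow = 1)
  direct <- scaler_inverse(sc, backend_predict(backend, x)[1, 1])
  expect_equal(one_step, direct)
})

test_that("fitted seq2seq imputers respect contracts and fill gaps", {
  s <- small_series()
  parts <- split_time_based(s)
  spec <- imputer_spec("seq2seq", "unidirectional", window = 16, horizon = 6,
                       n_estimators = 10)
  fit <- fit_imputer(parts$train, spec, seed = 2, max_examples = 400)
  inj <- inject_missingness(parts$test, 6, 0.05, seed = 4,
                            min_separation = 16)
  g <- inj$gaps[1, ]
  pred <- impute_gap(fit, inj$series, g)
  expect_length(pred, 6)
  expect_true(all(is.finite(pred)))
  # context contract violations
  expect_error(predict_seq2seq(fit, rnorm(10), rnorm(16), 6),
               class = "pmgapfill_contract")
  expect_error(predict_seq2seq(fit, rnorm(16), rnorm(16), 5),
               class = "pmgapfill_contract")
  expect_error(predict_seq2seq(fit, rnorm(16), NULL, 6),
               class = "pmgapfill_contract")
  # gap at the series edge is inapplicable for a fixed-context method
  edge <- list(series = parts$test, gaps = NULL)
  expect_error(impute_gap(fit, parts$test, gap_at(3, 6)),
               class = "pmgapfill_inapplicable")
})

test_that("constant training data yields constant seq2seq predictions", {
  s <- const_series(400, 25)
  spec <- imputer_spec("seq2seq", "bidirectional", window = 8, horizon = 4,
                       n_estimators = 10)
  fit <- fit_imputer(s, spec, seed = 1)
  s2 <- const_series(400, 25)
  s2$pm25[200:203] <- NA
  pred <- impute_gap(fit, s2, gap_at(200, 4))
  expect_equal(pred, rep(25, 4))
})

test_that("bidirectional fill is deterministic and uses both flanks", {
  s <- small_series()
  parts <- split_time_based(s)
  spec <- imputer_spec("seq2seq", "bidirectional", window = 12, horizon = 5,
                       n_estimators = 10)
  fit <- fit_imputer(parts$train, spec, seed = 7, max_examples = 400)
  inj <- inject_missingness(parts$test, 5, 0.05, seed = 8,
                            min_separation = 12)
  g <- inj$gaps[1, ]
  p1 <- impute_gap(fit, inj$series, g)
  p2 <- impute_gap(fit, inj$series, g)
  expect_identical(p1, p2)
  # perturbing the right flank changes the fused prediction
  pert <- inj$series
  ridx <- (g$start + g$length):(g$start + g$length + 11)
  pert$pm25[ridx] <- pert$pm25[ridx] + 20
  expect_false(identical(impute_gap(fit, pert, g), p1))
})
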