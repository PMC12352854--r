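small_dyn_cfg <- function(variables = "univariate") {
  dynamic_config(c_max = 8, max_trained_gap = 12,
                 trained_gap_lengths = c(2L, 5L, 12L), variables = variables,
                 n_estimators = 10, examples_per_length = 60)
}

test_that("dynamic context sizing follows the factor-with-cap rule", {
  expect_equal(dynamic_context_size(5), 15)
  expect_equal(dynamic_context_size(24), 32)
  expect_equal(dynamic_context_size(10), 30)
  expect_equal(dynamic_context_size(1), 3)
  expect_equal(dynamic_context_size(11), 32)
  expect_equal(dynamic_context_size(c(5, 24, 10, 1)), c(15, 32, 30, 3))
})

test_that("position-aware padding keeps observed values adjacent to the gap", {
  p <- pad_context(c(10, 11), c(12, 13), c_max = 4)
  expect_equal(p$left_block, c(0, 0, 10, 11))
  expect_equal(p$right_block, c(12, 13, 0, 0))
  full <- pad_context(1:4, 5:8, c_max = 4)
  expect_equal(full$left_block, 1:4)
  expect_equal(full$right_block, 5:8)
  empty <- pad_context(numeric(0), numeric(0), c_max = 3)
  expect_equal(empty$left_block, c(0, 0, 0))
  expect_error(pad_context(1:5, 1:2, c_max = 4), class = "pmgapfill_contract")
})

test_that("dynamic training set has masked targets and metadata", {
  cfg <- small_dyn_cfg()
  s <- small_series()[1:400, ]
  sc <- scaler_fit(s, "pm25")
  set <- build_dynamic_training_set(scale_series(s, sc), cfg, seed = 1)
  expect_equal(ncol(set$inputs), 2 * 8 + 2)
  expect_equal(ncol(set$targets), 12)
  # a length-5 example: 5 valid target positions of 12, context metadata 15
  # capped at c_max = 8
  i5 <- which(set$gap_length == 5)[1]
  expect_equal(sum(set$mask[i5, ]), 5)
  expect_equal(set$inputs[i5, 17], 5)                 # gap length metadata
  expect_equal(set$inputs[i5, 18],
               dynamic_context_size(5, cfg))          # context metadata
  i12 <- which(set$gap_length == 12)[1]
  expect_equal(sum(set$mask[i12, ]), 12)
  expect_true(all(set$mask[, 1]))                     # position 1 always valid
})

test_that("over-fragmented training data skips lengths with a warning", {
  cfg <- small_dyn_cfg()
  s <- small_series()[1:400, ]
  s$pm25[seq(26, 400, by = 26)] <- NA                 # no 12-gap span fits
  sc <- scaler_fit(s, "pm25")
  expect_warning(set <- build_dynamic_training_set(scale_series(s, sc),
                                                   cfg, seed = 1),
                 "fragmented")
  expect_false(12 %in% set$gap_length)
})

test_that("the dynamic model predicts gaps of any trained length and respects bounds", {
  cfg <- small_dyn_cfg()
  s <- small_series()
  parts <- split_time_based(s)
  fit <- fit_dynamic(parts$train, cfg, seed = 1)
  inj <- inject_missingness(parts$test, 5, 0.05, seed = 2)
  g <- inj$gaps[1, ]
  pred <- predict_gap(fit, inj$series, g)
  expect_length(pred, 5)
  expect_true(all(is.finite(pred)))
  expect_identical(pred, predict_gap(fit, inj$series, g))  # deterministic
  # lengths beyond the trained maximum must be chunked
  expect_error(predict_gap(fit, inj$series, gap_at(500, 13)),
               class = "pmgapfill_contract")
  expect_error(fill_long_gap(fit, inj$series, gap_at(500, 12)),
               class = "pmgapfill_contract")
})

test_that("gaps at the series boundary are predicted from one side alone", {
  cfg <- small_dyn_cfg()
  s <- small_series()
  parts <- split_time_based(s)
  fit <- fit_dynamic(parts$train, cfg, seed = 1)
  test <- parts$test
  test$pm25[1:5] <- NA                                # zero left context
  pred <- predict_gap(fit, test, gap_at(1, 5))
  expect_length(pred, 5)
  expect_true(all(is.finite(pred)))
})

test_that("constant training data yields constant dynamic predictions", {
  ts <- seq(as.POSIXct("2024-01-01", tz = "UTC"), by = 3600,
            length.out = 500)
  s <- pm_series(ts, rep(40, 500))
  cfg <- small_dyn_cfg()
  fit <- fit_dynamic(s, cfg, seed = 1)
  s2 <- s; s2$pm25[200:204] <- NA
  expect_equal(predict_gap(fit, s2, gap_at(200, 5)), rep(40, 5))
})

test_that("chunking splits long gaps into trained-size pieces plus remainder", {
  expect_equal(gap_chunk_sizes(191, 72), c(72, 72, 47))
  expect_equal(gap_chunk_sizes(72, 72), 72)
  expect_equal(gap_chunk_sizes(144, 72), c(72, 72))
  expect_equal(gap_chunk_sizes(73, 72), c(72, 1))

  cfg <- small_dyn_cfg()                              # max trained length 12
  s <- small_series()
  parts <- split_time_based(s)
  fit <- fit_dynamic(parts$train, cfg, seed = 1)
  test <- parts$test
  test$pm25[50:79] <- NA                              # 30-hour gap
  pred <- fill_long_gap(fit, test, gap_at(50, 30))
  expect_length(pred, 30)
  expect_false(anyNA(pred))
  expect_equal(gap_chunk_sizes(30, 12), c(12, 12, 6))
})

test_that("fill_all fills everything, clips negatives and reports paths", {
  cfg <- small_dyn_cfg()
  s <- small_series()
  parts <- split_time_based(s)
  fit <- fit_dynamic(parts$train, cfg, seed = 1)
  test <- parts$test
  test$pm25[10] <- NA                                 # 1 h gap
  test$pm25[40:44] <- NA                              # 5 h gap
  test$pm25[100:129] <- NA                            # 30 h gap -> chunked
  res <- fill_all(fit, test)
  expect_false(anyNA(res$series$pm25))
  expect_true(all(res$series$pm25 >= 0))
  expect_equal(nrow(res$report), 3)
  expect_equal(res$report$path, c("direct", "direct", "chunked"))
  expect_equal(res$report$chunks[3], "12+12+6")
  expect_true(all(res$report$n_clipped >= 0))
  # observed values untouched
  obs <- !is.na(test$pm25)
  expect_identical(res$series$pm25[obs], test$pm25[obs])
  # gap-free series: identical output, empty report
  res0 <- fill_all(fit, parts$train)
  expect_identical(res0$series$pm25, parts$train$pm25)
  expect_equal(nrow(res0$report), 0)
})

test_that("multivariate dynamic inputs carry covariate and temporal metadata", {
  cfg <- small_dyn_cfg("multivariate")
  s <- small_series()
  sc <- scaler_fit(s, c("pm25", cfg$feature_names))
  set <- build_dynamic_training_set(scale_series(s, sc), cfg, seed = 1)
  expect_equal(ncol(set$inputs), 2 * 8 + 2 + 2 + 4 * 12)
  fit <- fit_dynamic(split_time_based(s)$train, cfg, seed = 1)
  test <- split_time_based(s)$test
  test$pm25[30:34] <- NA
  pred <- predict_gap(fit, test, gap_at(30, 5))
  expect_length(pred, 5)
  expect_true(all(is.finite(pred)))
})
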