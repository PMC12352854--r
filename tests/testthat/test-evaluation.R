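# independent brute-force metric oracles (deliberately naive loops)
naive_mae <- function(y, p) { s <- 0; for (i in seq_along(y)) s <- s + abs(y[i] - p[i]); s / length(y) }
naive_rmse <- function(y, p) { s <- 0; for (i in seq_along(y)) s <- s + (y[i] - p[i])^2; sqrt(s / length(y)) }
naive_mape <- function(y, p) { s <- 0; for (i in seq_along(y)) s <- s + abs(y[i] - p[i]) / (y[i] + 1e-8); 100 * s / length(y) }
naive_r2 <- function(y, p) 1 - sum((y - p)^2) / sum((y - mean(y))^2)

test_that("metric hand-arithmetic examples", {
  expect_equal(metric_mae(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_equal(metric_mae(1:5, 1:5), 0)
  expect_equal(metric_rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(metric_rmse(1:5, 1:5), 0)
  expect_equal(metric_mape(10, 9), 10, tolerance = 1e-8)
  expect_equal(metric_mape(1:5, 1:5), 0)
  expect_true(is.finite(metric_mape(c(0, 1), c(1, 1))))  # epsilon guard
  expect_equal(metric_r2(1:10, 1:10), 1)
  expect_equal(metric_r2(1:10, rep(mean(1:10), 10)), 0)
  expect_warning(r <- metric_r2(rep(2, 5), rnorm(5)), "constant")
  expect_true(is.na(r))
  expect_error(metric_mae(1:3, 1:4), class = "pmgapfill_contract")
})

test_that("metrics match a brute-force implementation on 1000 random draws", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    y <- runif(n, 0.5, 100)
    p <- y + rnorm(n, 0, 5)
    expect_equal(metric_mae(y, p), naive_mae(y, p), tolerance = 1e-10)
    expect_equal(metric_rmse(y, p), naive_rmse(y, p), tolerance = 1e-10)
    expect_equal(metric_mape(y, p), naive_mape(y, p), tolerance = 1e-10)
    expect_equal(metric_r2(y, p), naive_r2(y, p), tolerance = 1e-10)
  }
  # RMSE >= MAE on any input (Jensen)
  set.seed(78)
  for (i in 1:50) {
    y <- rnorm(20); p <- rnorm(20)
    expect_gte(metric_rmse(y, p), metric_mae(y, p))
  }
})

test_that("the harness scores a truth-returning oracle perfectly", {
  s <- small_series()
  cfg <- benchmark_config(gap_lengths = c(5L, 12L), n_runs = 2,
                          master_seed = 10)
  res <- run_benchmark(s, list(oracle = method_oracle(),
                               `global-mean` = benchmark_methods("global-mean")[[1]]),
                       cfg)
  orc <- res[res$method == "oracle", ]
  expect_true(all(orc$mae == 0))
  expect_true(all(orc$rmse == 0))
  expect_true(all(orc$r2 == 1))
  expect_true(all(orc$coverage == 1))
  # the baseline, by contrast, has positive error
  expect_true(all(res$mae[res$method == "global-mean"] > 0))
})

test_that("identical gap patterns across methods and reproducible runs", {
  s <- small_series()
  seen <- new.env(parent = emptyenv())
  spy <- function(id) make_method(id, "spy",
    fit = function(train, gap_length, seed) NULL,
    fill = function(state, series, gap) {
      key <- paste0("mask_", id)
      assign(key, c(get0(key, envir = seen, ifnotfound = integer()),
                    which(is.na(series$pm25))), envir = seen)
      rep(mean(series$pm25, na.rm = TRUE), gap$length)
    })
  cfg <- benchmark_config(gap_lengths = 12L, n_runs = 1, master_seed = 5)
  res1 <- run_benchmark(s, list(a = spy("a"), b = spy("b")), cfg)
  expect_identical(seen$mask_a, seen$mask_b)  # same injected gap pattern
  res2 <- run_benchmark(s, list(a = spy("a"), b = spy("b")), cfg)
  expect_equal(res1$mae, res2$mae)            # same master seed -> same cells
})

test_that("inapplicable methods are recorded via coverage, not as zeros", {
  s <- small_series()
  never <- make_method("never", "spy",
    fit = function(train, gap_length, seed) NULL,
    fill = function(state, series, gap) stop_inapplicable("no"))
  cfg <- benchmark_config(gap_lengths = 5L, n_runs = 1, master_seed = 2)
  res <- run_benchmark(s, list(never = never), cfg)
  expect_equal(res$coverage, 0)
  expect_true(is.na(res$mae))
  expect_equal(res$n_points, 0)
})

test_that("aggregation reports mean +/- SD per cell", {
  s <- small_series()
  cfg <- benchmark_config(gap_lengths = c(5L, 12L), n_runs = 3,
                          master_seed = 3)
  res <- run_benchmark(s, benchmark_methods(c("global-mean", "local-mean")),
                       cfg)
  agg <- aggregate_benchmark(res)
  expect_equal(nrow(agg), 4)
  expect_true(all(c("mae_mean", "mae_sd", "mae_label") %in% names(agg)))
  cell <- res[res$method == "local-mean" & res$gap_length == 5, ]
  expect_equal(agg$mae_mean[agg$method == "local-mean" &
                              agg$gap_length == 5], mean(cell$mae))
  expect_match(agg$mae_label[1], "\\d+\\.\\d{3} ± \\d+\\.\\d{3}")
})

test_that("paired t-test behaves per the closed form", {
  grid <- expand.grid(gap_length = c(5, 12), run = 1:5)
  a <- data.frame(gap_length = grid$gap_length, run = grid$run,
                  mae = 10 + seq_len(10) / 10)
  b <- a; b$mae <- a$mae - 1          # constant unit improvement: t -> Inf
  expect_lt(paired_method_test(a, b), 0.05)
  expect_warning(p0 <- paired_method_test(a, a), "zero-variance")
  expect_true(is.na(p0))
  # noisy improvement matches the closed-form t statistic
  set.seed(1)
  b2 <- a; b2$mae <- a$mae - 1 + rnorm(10, 0, 0.01)
  p2 <- paired_method_test(a, b2)
  d <- a$mae - b2$mae
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_closed <- 2 * stats::pt(-abs(t_stat), df = length(d) - 1)
  expect_equal(p2, p_closed, tolerance = 1e-12)
  expect_lt(p2, 0.05)
  # mismatched grids are a contract error
  expect_error(paired_method_test(a[-1, ], b),
               class = "pmgapfill_contract")
})
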