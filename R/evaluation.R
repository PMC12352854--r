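check_pair <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop_contract("observed and predicted vectors differ in length")
  }
  if (length(y) == 0) stop_contract("empty metric input")
}

#' Imputation error metrics
#'
#' Standard complementary metrics on the raw concentration scale:
#' mean absolute error (ug/m3), root mean square error (ug/m3), mean
#' absolute percentage error (%, with a 1e-8 guard against division by
#' zero), and the coefficient of determination (1 - SS_res / SS_tot about
#' the mean of `y`; `NA` with a warning when `y` is constant).
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @param epsilon denominator guard for MAPE.
#' @return a single numeric value.
#' @export
metric_mae <- function(y, yhat) {
  check_pair(y, yhat)
  mean(abs(y - yhat))
}

#' @rdname metric_mae
#' @export
metric_rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' @rdname metric_mae
#' @export
metric_mape <- function(y, yhat, epsilon = 1e-8) {
  check_pair(y, yhat)
  100 * mean(abs(y - yhat) / (y + epsilon))
}

#' @rdname metric_mae
#' @export
metric_r2 <- function(y, yhat) {
  check_pair(y, yhat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("R^2 undefined for constant observations; returning NA")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

metric_report <- function(y, yhat) {
  c(mae = metric_mae(y, yhat), rmse = metric_rmse(y, yhat),
    mape = metric_mape(y, yhat),
    r2 = suppressWarnings(metric_r2(y, yhat)), n_points = length(y))
}

#' Benchmark configuration
#'
#' @param gap_lengths synthetic gap lengths to test, hours.
#' @param missing_fraction fraction of the injected split turned into gaps.
#' @param n_runs experimental repetitions; runs differ only in gap
#'   placement seed.
#' @param master_seed master seed; per-(run, gap-length) placement seeds and
#'   per-method fit seeds are derived from it.
#' @param train_fraction chronological training fraction.
#' @param min_separation separation/boundary margin for injected gaps.
#' @return a `benchmark_config` list.
#' @export
benchmark_config <- function(gap_lengths = c(5L, 12L, 24L, 48L, 72L),
                             missing_fraction = 0.05, n_runs = 5L,
                             master_seed = 1L, train_fraction = 0.8,
                             min_separation = 32L) {
  if (!is_count(n_runs)) stop_config("n_runs must be >= 1")
  if (missing_fraction <= 0 || missing_fraction >= 0.5) {
    stop_config("missing_fraction must lie in (0, 0.5)")
  }
  structure(list(gap_lengths = as.integer(gap_lengths),
                 missing_fraction = missing_fraction,
                 n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed),
                 train_fraction = train_fraction,
                 min_separation = as.integer(min_separation)),
            class = "benchmark_config")
}

#' Run the synthetic-gap benchmark
#'
#' The unified evaluation protocol: split the series chronologically, fit
#' every registered method once per gap length on the training split
#' (fit seeds are held constant across runs to isolate placement
#' variance), then for every (run, gap length) inject identical synthetic
#' gaps into the test split and score every method on the same gap
#' pattern. Metrics are pooled over all gap positions within a run and
#' computed on the raw scale. Method-inapplicable failures are recorded
#' per gap and excluded from that method's pooled metrics, with a
#' coverage column.
#'
#' At least one gap is injected per cell even when
#' `floor(f * N_test / L)` is zero, so long-gap cells are never empty.
#'
#' @param series a complete (or mostly complete) [pm_series()].
#' @param methods named list of method objects from [benchmark_methods()]
#'   or [make_method()].
#' @param config a [benchmark_config()].
#' @return a `benchmark_result` data frame with one row per
#'   (method, gap_length, run).
#' @export
run_benchmark <- function(series, methods, config = benchmark_config()) {
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop_config("methods must be a named list")
  }
  parts <- split_time_based(series, config$train_fraction)
  if (nrow(parts$test) == 0) {
    stop_config("empty test split: benchmark refuses to run")
  }
  n_train <- nrow(parts$train)

  rows <- list()
  for (L in config$gap_lengths) {
    fitted <- lapply(names(methods), function(nm) {
      methods[[nm]]$fit(parts$train, L,
                        derive_seed(config$master_seed, "fit", nm, L))
    })
    names(fitted) <- names(methods)

    for (run in seq_len(config$n_runs)) {
      n_test <- nrow(parts$test)
      k <- max(1L, floor(config$missing_fraction * n_test / L))
      inj <- inject_missingness(parts$test, L, config$missing_fraction,
                                seed = derive_seed(config$master_seed,
                                                   "gaps", run, L),
                                min_separation = config$min_separation,
                                n_gaps = k)
      # fill on the full series (train prefix + holed test split): simple
      # imputers see whole-series statistics and fixed-context methods can
      # draw context across the split boundary, as in operational filling
      full <- rbind(as.data.frame(parts$train), as.data.frame(inj$series))
      class(full) <- class(series)
      inj$gaps$start <- inj$gaps$start + n_train
      for (nm in names(methods)) {
        t0 <- proc.time()[["elapsed"]]
        truth <- numeric(0)
        pred <- numeric(0)
        failed <- 0L
        for (gi in seq_len(nrow(inj$gaps))) {
          g <- inj$gaps[gi, ]
          res <- tryCatch(
            methods[[nm]]$fill(fitted[[nm]], full, g),
            pmgapfill_inapplicable = function(e) NULL)
          if (is.null(res)) {
            failed <- failed + 1L
            next
          }
          truth <- c(truth, g$truth[[1]])
          pred <- c(pred, res)
        }
        dt <- proc.time()[["elapsed"]] - t0
        met <- if (length(truth)) metric_report(truth, pred) else
          c(mae = NA, rmse = NA, mape = NA, r2 = NA, n_points = 0)
        rows[[length(rows) + 1L]] <- data.frame(
          method = nm, category = methods[[nm]]$category,
          gap_length = L, run = run,
          mae = met[["mae"]], rmse = met[["rmse"]], mape = met[["mape"]],
          r2 = met[["r2"]], n_points = met[["n_points"]],
          coverage = 1 - failed / nrow(inj$gaps), runtime_s = dt)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Aggregate benchmark results to mean +/- SD over runs
#'
#' @param results a `benchmark_result` from [run_benchmark()].
#' @return data frame with one row per (method, gap_length) and
#'   `<metric>_mean` / `<metric>_sd` columns plus a formatted
#'   `mae_label` ("mean+/-sd").
#' @export
aggregate_benchmark <- function(results) {
  key <- interaction(results$method, results$gap_length, drop = TRUE)
  agg <- lapply(split(results, key), function(d) {
    row <- data.frame(method = d$method[1], category = d$category[1],
                      gap_length = d$gap_length[1])
    for (m in c("mae", "rmse", "mape", "r2", "runtime_s")) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- sd(d[[m]], na.rm = TRUE)
    }
    row$coverage <- mean(d$coverage)
    row$mae_label <- sprintf("%.3f ± %.3f", row$mae_mean,
                             ifelse(is.na(row$mae_sd), 0, row$mae_sd))
    row
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$gap_length, out$mae_mean), ]
}

#' Paired comparison of two methods' MAE cells
#'
#' Paired t-test over matched (gap_length, run) MAE cells of two benchmark
#' results (e.g. a univariate model vs. its multivariate counterpart).
#'
#' @param results_a,results_b `benchmark_result` rows for one method each.
#' @return the p-value (`NA` with a warning when the paired differences
#'   have zero variance).
#' @export
paired_method_test <- function(results_a, results_b) {
  key_a <- paste(results_a$gap_length, results_a$run)
  key_b <- paste(results_b$gap_length, results_b$run)
  if (!setequal(key_a, key_b) || anyDuplicated(key_a) ||
      anyDuplicated(key_b)) {
    stop_contract("results do not share an identical (gap_length, run) grid")
  }
  a <- results_a$mae[order(key_a)]
  b <- results_b$mae[order(key_b)]
  d <- a - b
  if (length(d) < 2 || sd(d) == 0) {
    # degenerate limits of the t statistic: no difference anywhere is
    # undefined evidence; a constant nonzero improvement is t -> Inf
    if (all(d == 0)) {
      warning("zero-variance paired differences; p-value undefined")
      return(NA_real_)
    }
    return(0)
  }
  t.test(a, b, paired = TRUE)$p.value
}
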