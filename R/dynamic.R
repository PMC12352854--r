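#' Configuration of the dynamic adaptive-context imputer
#'
#' One model handles gaps of any length: the context window is sized from
#' the gap length (3x the gap for short gaps, capped at `c_max`), contexts
#' are zero-padded position-aware so observed values always sit adjacent to
#' the gap, gap metadata (length, context size) is fed as explicit features,
#' and the model is trained once on simulated gaps of several lengths,
#' emitting `max_trained_gap` outputs of which the first `L` are used.
#'
#' @param c_max maximum context per side, hours.
#' @param context_factor context multiplier for short gaps.
#' @param short_gap_cutoff gap length (hours) up to which the factor rule
#'   applies; longer gaps use the `c_max` cap.
#' @param max_trained_gap maximum gap length covered by the multi-output
#'   head; longer gaps are chunked.
#' @param trained_gap_lengths gap lengths simulated during training.
#' @param variables `"univariate"` or `"multivariate"`.
#' @param feature_names covariates used in multivariate mode (the gap-start
#'   hour and season are always added as metadata there).
#' @param n_estimators ensemble size per output position.
#' @param examples_per_length cap on simulated training gaps per length.
#' @return a `dynamic_config` list.
#' @export
dynamic_config <- function(c_max = 32L, context_factor = 3L,
                           short_gap_cutoff = 10L, max_trained_gap = 72L,
                           trained_gap_lengths = c(5L, 12L, 24L, 48L, 72L),
                           variables = c("univariate", "multivariate"),
                           feature_names = c("Ff", "DD", "T", "U"),
                           n_estimators = 50L,
                           examples_per_length = 300L) {
  variables <- match.arg(variables)
  if (any(trained_gap_lengths < 1) ||
      any(trained_gap_lengths > max_trained_gap)) {
    stop_config("trained_gap_lengths must lie in [1, max_trained_gap]")
  }
  structure(list(c_max = as.integer(c_max),
                 context_factor = as.integer(context_factor),
                 short_gap_cutoff = as.integer(short_gap_cutoff),
                 max_trained_gap = as.integer(max_trained_gap),
                 trained_gap_lengths = as.integer(trained_gap_lengths),
                 variables = variables, feature_names = feature_names,
                 n_estimators = as.integer(n_estimators),
                 examples_per_length = as.integer(examples_per_length)),
            class = "dynamic_config")
}

#' Dynamic context sizing rule
#'
#' For gaps up to the short-gap cutoff (10 h), the context is
#' `min(3 x gap length, 32)`; longer gaps are capped at 32 time steps.
#'
#' @param gap_length gap length in hours (vectorized).
#' @param config a [dynamic_config()].
#' @return context length in hours.
#' @export
dynamic_context_size <- function(gap_length, config = dynamic_config()) {
  as.integer(ifelse(gap_length <= config$short_gap_cutoff,
                    pmin(config$context_factor * gap_length, config$c_max),
                    config$c_max))
}

#' Position-aware zero padding of context blocks
#'
#' The left context is padded with zeros on its far (distal) left, the
#' right context on its far right, so observed values always occupy the
#' positions adjacent to the gap.
#'
#' @param left,right numeric vectors of length `<= c_max` (may be empty).
#' @param c_max padded block size.
#' @return list with `left_block` and `right_block`, each of length
#'   `c_max`.
#' @export
pad_context <- function(left, right, c_max = 32L) {
  if (length(left) > c_max || length(right) > c_max) {
    stop_contract("context longer than c_max")
  }
  list(left_block = c(rep(0, c_max - length(left)), left),
       right_block = c(right, rep(0, c_max - length(right))))
}

# one input row on the standardized scale; gap_rows = scaled covariate rows
# over the gap (multivariate), NULL otherwise
dynamic_input_row <- function(left, right, gap_length, config,
                              start_hour = NULL, start_season = NULL,
                              gap_cov = NULL) {
  blocks <- pad_context(left, right, config$c_max)
  meta <- c(gap_length, dynamic_context_size(gap_length, config))
  row <- c(blocks$left_block, blocks$right_block, meta)
  if (config$variables == "multivariate") {
    covs <- numeric(0)
    for (j in seq_len(ncol(gap_cov))) {
      block <- c(gap_cov[, j], rep(0, config$max_trained_gap - nrow(gap_cov)))
      covs <- c(covs, block)
    }
    row <- c(row, start_hour, start_season, covs)
  }
  row
}

dynamic_input_width <- function(config) {
  w <- 2L * config$c_max + 2L
  if (config$variables == "multivariate") {
    w <- w + 2L + length(config$feature_names) * config$max_trained_gap
  }
  w
}

#' Build the unified multi-length training set
#'
#' For every trained gap length, simulated gaps are carved from fully
#' observed stretches of the (standardized) training series, with contexts
#' sized by [dynamic_context_size()] and padded by [pad_context()]. Targets
#' are blocks of `max_trained_gap` values with a validity mask: positions
#' beyond each example's true gap length are masked out of the fit.
#'
#' @param series a [pm_series()] on the standardized scale (see
#'   [fit_dynamic()], which handles scaling).
#' @param config a [dynamic_config()].
#' @param seed placement seed.
#' @return list with `inputs`, `targets`, `mask` matrices and
#'   `gap_length` per example.
#' @export
build_dynamic_training_set <- function(series, config, seed = 1L) {
  y <- as.numeric(series$pm25)
  n <- length(y)
  use_cov <- config$variables == "multivariate"
  cov_mat <- if (use_cov) {
    assemble_features(series, seq_len(n), "multivariate",
                      config$feature_names)
  }
  obs <- !is.na(y)
  if (use_cov) obs <- obs & stats::complete.cases(cov_mat)

  rows <- list(); targs <- list(); masks <- list(); lens <- integer(0)
  for (L in config$trained_gap_lengths) {
    ctx <- dynamic_context_size(L, config)
    span <- L + 2L * ctx
    starts <- window_spans(obs, span)      # span start; gap begins at +ctx
    if (length(starts) == 0) {
      warning(sprintf(
        "training split too fragmented for %d-hour gaps; length skipped", L))
      next
    }
    if (length(starts) > config$examples_per_length) {
      starts <- with_seed(derive_seed(seed, "len", L),
                          sort(sample(starts, config$examples_per_length)))
    }
    for (t0 in starts) {
      gs <- t0 + ctx                      # gap start
      gi <- gs:(gs + L - 1L)
      left <- y[(gs - ctx):(gs - 1L)]
      right <- y[(gs + L):(gs + L + ctx - 1L)]
      gap_cov <- if (use_cov) cov_mat[gi, , drop = FALSE]
      rows[[length(rows) + 1L]] <- dynamic_input_row(
        left, right, L, config,
        start_hour = series$hour[gs], start_season = series$season[gs],
        gap_cov = gap_cov)
      tg <- rep(0, config$max_trained_gap)
      tg[seq_len(L)] <- y[gi]
      targs[[length(targs) + 1L]] <- tg
      mk <- rep(FALSE, config$max_trained_gap)
      mk[seq_len(L)] <- TRUE
      masks[[length(masks) + 1L]] <- mk
      lens <- c(lens, L)
    }
  }
  if (length(rows) == 0) {
    stop_insufficient("no trainable gap examples in the training split")
  }
  list(inputs = do.call(rbind, rows), targets = do.call(rbind, targs),
       mask = do.call(rbind, masks), gap_length = lens)
}

#' Fit the dynamic adaptive-context imputer
#'
#' Fits the scaler on the training split, builds the unified multi-length
#' training set on the standardized scale (zero padding then equals the
#' training mean), and fits one backend regressor per output position,
#' each using only the examples whose mask covers that position. Output
#' positions with no covering examples degenerate to the training-target
#' mean (logged with a warning).
#'
#' @param train a [pm_series()] training split (raw scale).
#' @param config a [dynamic_config()].
#' @param seed master seed.
#' @param backend backend name, see [backend_fit()].
#' @return a `fitted_dynamic` object.
#' @export
fit_dynamic <- function(train, config = dynamic_config(), seed = 1L,
                        backend = "forest") {
  feats <- c("pm25",
             if (config$variables == "multivariate") config$feature_names)
  scaler <- scaler_fit(train, feats)
  scaled <- scale_series(train, scaler)
  set <- build_dynamic_training_set(scaled, config, seed)

  models <- vector("list", config$max_trained_gap)
  target_mean <- mean(set$targets[set$mask])
  for (j in seq_len(config$max_trained_gap)) {
    cover <- set$mask[, j]
    if (!any(cover)) {
      warning(sprintf(
        "no training example covers output position %d; using target mean",
        j))
      models[[j]] <- list(kind = "mean", value = target_mean)
      next
    }
    models[[j]] <- backend_fit(backend,
                               set$inputs[cover, , drop = FALSE],
                               set$targets[cover, j],
                               n_estimators = config$n_estimators,
                               seed = derive_seed(seed, "dyn", j))
  }
  structure(list(config = config, scaler = scaler, models = models,
                 backend = backend, n_examples = nrow(set$inputs)),
            class = "fitted_dynamic")
}

dynamic_predict_row <- function(fitted, row, L) {
  x <- matrix(row, nrow = 1)
  vapply(seq_len(L), function(j) {
    m <- fitted$models[[j]]
    if (identical(m$kind, "mean")) m$value else backend_predict(m, x)[1, 1]
  }, numeric(1))
}

# observed run lengths immediately flanking a gap, capped at `cap`
available_context <- function(y, s, e, cap) {
  n <- length(y)
  left <- 0L
  while (left < cap && s - left - 1L >= 1 && !is.na(y[s - left - 1L])) {
    left <- left + 1L
  }
  right <- 0L
  while (right < cap && e + right + 1L <= n && !is.na(y[e + right + 1L])) {
    right <- right + 1L
  }
  c(left = left, right = right)
}

#' Predict one gap with the dynamic model
#'
#' Uses `min(available, dynamic size)` context on each side - a side with
#' no observed neighbour is legal and fully padded - and returns the first
#' `gap$length` outputs of the multi-output head.
#'
#' @param fitted a `fitted_dynamic`.
#' @param series the [pm_series()] containing the gap (raw scale).
#' @param gap gap description (`start`, `length`); must not exceed
#'   `max_trained_gap` (longer gaps go through [fill_long_gap()]).
#' @return numeric vector of `gap$length` raw-scale predictions.
#' @export
predict_gap <- function(fitted, series, gap) {
  config <- fitted$config
  L <- gap$length
  if (L > config$max_trained_gap) {
    stop_contract(sprintf(
      "gap length %d exceeds max trained length %d; use fill_long_gap()",
      L, config$max_trained_gap))
  }
  scaled <- scale_series(series, fitted$scaler)
  y <- as.numeric(scaled$pm25)
  s <- gap$start
  e <- s + L - 1L
  ctx <- dynamic_context_size(L, config)
  avail <- available_context(y, s, e, ctx)
  left <- if (avail["left"] > 0) y[(s - avail["left"]):(s - 1L)] else numeric(0)
  right <- if (avail["right"] > 0) y[(e + 1L):(e + avail["right"])] else numeric(0)

  gap_cov <- NULL
  if (config$variables == "multivariate") {
    spec_like <- list(variables = "multivariate",
                      feature_names = c("pm25", config$feature_names))
    gap_cov <- context_rows(scaled, s:e, spec_like)[, -1, drop = FALSE]
  }
  row <- dynamic_input_row(left, right, L, config,
                           start_hour = series$hour[s],
                           start_season = series$season[s],
                           gap_cov = gap_cov)
  preds <- dynamic_predict_row(fitted, row, L)
  scaler_inverse(fitted$scaler, preds)
}

#' Chunked filling of gaps longer than the trained maximum
#'
#' Segments the gap into full `max_trained_gap`-hour chunks left to right
#' plus a remainder. Each chunk is predicted with [predict_gap()]; chunk
#' `i > 1` uses the just-predicted values as its left context, so seams
#' stay continuous; only the final chunk sees the real right context.
#'
#' @inheritParams predict_gap
#' @return numeric vector of `gap$length` predictions.
#' @export
fill_long_gap <- function(fitted, series, gap) {
  config <- fitted$config
  L <- gap$length
  if (L <= config$max_trained_gap) {
    stop_contract("gap fits the trained maximum; use predict_gap()")
  }
  sizes <- gap_chunk_sizes(L, config$max_trained_gap)
  working <- series
  out <- numeric(0)
  pos <- gap$start
  for (sz in sizes) {
    chunk_gap <- list(start = pos, length = sz)
    pred <- predict_gap(fitted, working, chunk_gap)
    working$pm25[pos:(pos + sz - 1L)] <- pred
    out <- c(out, pred)
    pos <- pos + sz
  }
  out
}

gap_chunk_sizes <- function(L, max_len) {
  k <- L %/% max_len
  r <- L %% max_len
  sizes <- rep(max_len, k)
  if (r > 0) sizes <- c(sizes, r)
  sizes
}

#' Fill every gap in a series with the dynamic model
#'
#' Gaps up to the trained maximum are predicted directly; longer ones are
#' chunked. Negative predictions (physically meaningless for PM2.5) are
#' clipped to zero and counted. Contexts are drawn from the observed
#' series; only within-gap chunk chaining uses predicted values.
#'
#' @param fitted a `fitted_dynamic`.
#' @param series a [pm_series()] with missing values.
#' @return list with `series` (no missing, no negative values) and
#'   `report`, a data frame with per-gap start timestamp, length, method
#'   path (`direct`/`chunked`), chunk sizes, context actually available,
#'   and clipped-value count.
#' @export
fill_all <- function(fitted, series) {
  gaps <- find_gaps(series)
  out <- series
  if (nrow(gaps) == 0) {
    report <- data.frame(start_timestamp = character(), length = integer(),
                         path = character(), chunks = character(),
                         left_context = integer(), right_context = integer(),
                         n_clipped = integer())
    return(list(series = out, report = report))
  }
  rows <- vector("list", nrow(gaps))
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    long <- g$length > fitted$config$max_trained_gap
    pred <- if (long) fill_long_gap(fitted, series, g)
            else predict_gap(fitted, series, g)
    clipped <- sum(pred < 0)
    pred <- pmax(pred, 0)
    out$pm25[g$start:(g$start + g$length - 1L)] <- pred
    rows[[i]] <- data.frame(
      start_timestamp = format(series$timestamp[g$start],
                               "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      length = g$length,
      path = if (long) "chunked" else "direct",
      chunks = paste(gap_chunk_sizes(g$length,
                                     fitted$config$max_trained_gap),
                     collapse = "+"),
      left_context = g$left_context, right_context = g$right_context,
      n_clipped = clipped)
  }
  list(series = out, report = do.call(rbind, rows))
}
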