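#' Declarative description of a fixed-context supervised imputer
#'
#' Mirrors one row of the method hierarchy: forecasting strategy
#' (autoregressive one-step recursion vs. direct sequence-to-sequence),
#' directionality (one model vs. a forward/backward pair fused by
#' distance weights), variable usage, regression backend, and context
#' lengths.
#'
#' Context conventions: autoregressive models use a left context of
#' `window` points; unidirectional seq2seq models use both flanks
#' (`window`/`window`, one forward pass over the concatenated input);
#' bidirectional models fit two single-flank models, the backward one on
#' the globally reversed training series.
#'
#' @param strategy `"seq2seq"` or `"autoregressive"`.
#' @param directionality `"unidirectional"` or `"bidirectional"`.
#' @param variables `"univariate"` (PM2.5 only) or `"multivariate"`.
#' @param backend backend name, see [backend_fit()].
#' @param window context length per side, hours.
#' @param horizon gap length the model is trained for (seq2seq).
#' @param n_estimators ensemble size.
#' @param feature_names multivariate feature columns; default PM2.5 +
#'   temperature, humidity, hour, season.
#' @return an `imputer_spec` list.
#' @export
imputer_spec <- function(strategy = c("seq2seq", "autoregressive"),
                         directionality = c("unidirectional",
                                            "bidirectional"),
                         variables = c("univariate", "multivariate"),
                         backend = "forest", window = 32L, horizon = 12L,
                         n_estimators = 50L,
                         feature_names = c("pm25", "T", "U", "hour",
                                           "season")) {
  strategy <- match.arg(strategy)
  directionality <- match.arg(directionality)
  variables <- match.arg(variables)
  if (!is_count(window) || !is_count(horizon)) {
    stop_config("window and horizon must be positive counts")
  }
  if (variables == "univariate") feature_names <- "pm25"
  if (!"pm25" %in% feature_names) feature_names <- c("pm25", feature_names)
  structure(list(strategy = strategy, directionality = directionality,
                 variables = variables, backend = backend,
                 window = as.integer(window), horizon = as.integer(horizon),
                 n_estimators = as.integer(n_estimators),
                 feature_names = feature_names),
            class = "imputer_spec")
}

#' Feature matrix at given series positions
#'
#' Univariate mode yields the PM2.5 column only; multivariate mode adds the
#' configured covariates. Temporal encodings follow the package convention:
#' hour as a 0-23 integer, season as 1 = winter .. 4 = autumn, wind
#' direction in degrees.
#'
#' @param series a [pm_series()].
#' @param positions integer row indices.
#' @param variables `"univariate"` or `"multivariate"`.
#' @param feature_names columns to use in multivariate mode.
#' @return numeric matrix, one row per position, one column per feature.
#' @export
assemble_features <- function(series, positions,
                              variables = c("univariate", "multivariate"),
                              feature_names = c("pm25", "T", "U", "hour",
                                                "season")) {
  variables <- match.arg(variables)
  feats <- if (variables == "univariate") "pm25" else feature_names
  missing_cols <- setdiff(feats, names(series))
  if (length(missing_cols)) {
    stop_config(sprintf("series lacks feature column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  m <- vapply(feats, function(f) as.numeric(series[[f]][positions]),
              numeric(length(positions)))
  m <- matrix(m, nrow = length(positions),
              dimnames = list(NULL, feats))
  m
}

#' Leak-free standardization fitted on the training split
#'
#' Per-feature standardization to zero mean and unit (population) variance
#' computed on the training portion only; the same affine map is then
#' applied everywhere else. Constant features are guarded with a unit SD
#' floor, so they map to exactly 0.
#'
#' @param train a [pm_series()] (training split).
#' @param features feature columns to standardize.
#' @return a `pm_scaler` with `$center` and `$scale`.
#' @export
scaler_fit <- function(train, features = "pm25") {
  center <- numeric(length(features))
  scale <- numeric(length(features))
  names(center) <- names(scale) <- features
  for (f in features) {
    v <- as.numeric(train[[f]])
    v <- v[!is.na(v)]
    if (length(v) == 0) stop_insufficient(sprintf("feature '%s' all missing", f))
    center[f] <- mean(v)
    s <- sqrt(mean((v - center[f])^2))
    scale[f] <- if (s < 1e-8) 1 else s
  }
  structure(list(center = center, scale = scale, features = features),
            class = "pm_scaler")
}

#' @param scaler a `pm_scaler`.
#' @param x numeric vector (single feature) or feature matrix with columns
#'   matching the scaler.
#' @param feature feature name when `x` is a vector.
#' @rdname scaler_fit
#' @export
scaler_transform <- function(scaler, x, feature = "pm25") {
  if (is.matrix(x)) {
    sweep(sweep(x, 2, scaler$center[colnames(x)]), 2,
          scaler$scale[colnames(x)], "/")
  } else {
    (x - scaler$center[feature]) / scaler$scale[feature]
  }
}

#' @rdname scaler_fit
#' @export
scaler_inverse <- function(scaler, x, feature = "pm25") {
  if (is.matrix(x)) {
    sweep(sweep(x, 2, scaler$scale[colnames(x)], "*"), 2,
          scaler$center[colnames(x)], "+")
  } else {
    x * scaler$scale[feature] + scaler$center[feature]
  }
}

#' Chronological train/test split
#'
#' The first `floor(train_fraction * n)` records form the training set; the
#' remainder is the test set. No shuffling.
#'
#' @param series a [pm_series()].
#' @param train_fraction fraction in (0, 1].
#' @return list with `train` and `test` series.
#' @export
split_time_based <- function(series, train_fraction = 0.8) {
  if (train_fraction <= 0 || train_fraction > 1) {
    stop_config("train_fraction must be in (0, 1]")
  }
  n <- nrow(series)
  k <- floor(train_fraction * n)
  list(train = series[seq_len(k), , drop = FALSE],
       test = series[setdiff(seq_len(n), seq_len(k)), , drop = FALSE])
}

# windows over complete stretches; `sides` = "left" (context -> next block)
# or "both" (left flank + right flank -> middle block).
# Flattening is time-major then feature (row-major over the window).
window_spans <- function(complete, span) {
  n <- length(complete)
  if (n < span) return(integer(0))
  cs <- cumsum(complete)
  full <- cs[span:n] - c(0, cs)[1:(n - span + 1)]
  which(full == span)
}

#' Build a supervised window set from a series
#'
#' Slides (step 1) over the training series, keeping only examples whose
#' input window(s) and target block are entirely observed in all features.
#'
#' @param series a [pm_series()] (training split, raw or scaled values).
#' @param spec an [imputer_spec()].
#' @param sides `"left"` for single-flank examples (autoregressive training
#'   and the members of bidirectional pairs), `"both"` for dual-flank
#'   seq2seq examples. Defaults to the imputer's convention.
#' @param max_examples optional cap; a deterministic subsample (by
#'   `seed`) is taken when more examples qualify.
#' @param seed seed for the subsample.
#' @return list with `inputs` (n x (window x features) or doubled for
#'   dual-flank) and `targets` (n x horizon for seq2seq, n x 1 for
#'   autoregressive).
#' @export
build_training_windows <- function(series, spec, sides = NULL,
                                   max_examples = Inf, seed = 1L) {
  if (is.null(sides)) {
    sides <- if (spec$strategy == "seq2seq" &&
                 spec$directionality == "unidirectional") "both" else "left"
  }
  w <- spec$window
  h <- if (spec$strategy == "autoregressive") 1L else spec$horizon
  feats <- assemble_features(series, seq_len(nrow(series)), spec$variables,
                             spec$feature_names)
  y <- as.numeric(series$pm25)
  complete <- stats::complete.cases(feats) & !is.na(y)

  span <- if (sides == "both") 2L * w + h else w + h
  starts <- window_spans(complete, span)
  if (length(starts) == 0) {
    stop_insufficient(sprintf(
      "no fully observed stretch of length %d in the training split", span))
  }
  if (length(starts) > max_examples) {
    starts <- with_seed(seed,
      sort(sample(starts, as.integer(max_examples))))
  }
  nf <- ncol(feats)
  flat <- function(rows) as.numeric(t(feats[rows, , drop = FALSE]))
  inputs <- matrix(0, nrow = length(starts),
                   ncol = (if (sides == "both") 2L else 1L) * w * nf)
  targets <- matrix(0, nrow = length(starts), ncol = h)
  for (i in seq_along(starts)) {
    t0 <- starts[i]
    if (sides == "both") {
      inputs[i, ] <- c(flat(t0:(t0 + w - 1L)),
                       flat((t0 + w + h):(t0 + 2L * w + h - 1L)))
    } else {
      inputs[i, ] <- flat(t0:(t0 + w - 1L))
    }
    targets[i, ] <- y[(t0 + w):(t0 + w + h - 1L)]
  }
  list(inputs = inputs, targets = targets, sides = sides,
       n_features = nf)
}

#' Fit a fixed-context supervised imputer
#'
#' Fits the scaler on the training split, builds supervised windows on the
#' standardized scale, and fits the backend(s): one model for
#' unidirectional specs, a forward and a backward model (trained on the
#' globally reversed series) for bidirectional specs. Sequence-to-sequence
#' targets are fitted as independent per-horizon-step regressors.
#'
#' @param train a [pm_series()] training split.
#' @param spec an [imputer_spec()].
#' @param seed master seed for the backend fits.
#' @param max_examples cap on training examples per model.
#' @return a `fitted_imputer`.
#' @export
fit_imputer <- function(train, spec, seed = 1L, max_examples = 4000L) {
  scaler <- scaler_fit(train, spec$feature_names)
  scaled <- scale_series(train, scaler)

  fit_one <- function(s, sides, sub_seed) {
    ws <- build_training_windows(s, spec, sides = sides,
                                 max_examples = max_examples,
                                 seed = sub_seed)
    backend_fit(spec$backend, ws$inputs, ws$targets,
                n_estimators = spec$n_estimators, seed = sub_seed)
  }

  if (spec$directionality == "unidirectional") {
    sides <- if (spec$strategy == "seq2seq") "both" else "left"
    forward <- fit_one(scaled, sides, derive_seed(seed, "fwd"))
    backward <- NULL
  } else {
    forward <- fit_one(scaled, "left", derive_seed(seed, "fwd"))
    backward <- fit_one(reverse_series(scaled), "left",
                        derive_seed(seed, "bwd"))
  }
  structure(list(spec = spec, scaler = scaler, forward = forward,
                 backward = backward),
            class = "fitted_imputer")
}

scale_series <- function(series, scaler) {
  for (f in scaler$features) {
    if (f %in% names(series)) {
      series[[f]] <- scaler_transform(scaler, as.numeric(series[[f]]), f)
    }
  }
  series
}

reverse_series <- function(series) {
  out <- series[rev(seq_len(nrow(series))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance-weighted fusion of forward and backward predictions
#'
#' `fused_i = w_i * forward_i + (1 - w_i) * backward_i` with
#' `w_i = (L + 1 - i) / (L + 1)`: the forward model dominates near the
#' gap's left edge and the backward model near its right edge; a singleton
#' gap reduces to the plain average.
#'
#' @param forward,backward numeric vectors of equal length L >= 1; the
#'   backward input must already be in gap time order.
#' @return fused numeric vector of length L.
#' @export
fuse_bidirectional <- function(forward, backward) {
  L <- length(forward)
  if (L < 1 || length(backward) != L) {
    stop_contract("forward and backward predictions must share length >= 1")
  }
  i <- seq_len(L)
  w <- (L + 1 - i) / (L + 1)
  w * forward + (1 - w) * backward
}

# scaled feature rows for positions, interpolating missing covariates
# (covariates are assumed near-complete; PM2.5 missingness is the caller's
# concern)
context_rows <- function(series_scaled, positions, spec) {
  m <- assemble_features(series_scaled, positions, spec$variables,
                         spec$feature_names)
  for (j in seq_len(ncol(m))[-1]) {
    if (anyNA(m[, j])) {
      obs <- which(!is.na(m[, j]))
      if (length(obs) == 0) {
        m[, j] <- 0  # scaled mean
      } else {
        m[, j] <- approx(obs, m[obs, j], xout = seq_len(nrow(m)),
                         rule = 2)$y
      }
    }
  }
  m
}

#' One-step-recursive prediction from a left context
#'
#' Rolls the fitted one-step model forward, appending each prediction to
#' the context window.
#'
#' @param fitted a `fitted_imputer` with autoregressive strategy (its
#'   forward model is used).
#' @param left_context raw-scale feature rows: numeric vector of
#'   `spec$window` PM2.5 values (univariate) or a `window x features`
#'   matrix; the rows immediately preceding the gap.
#' @param length number of steps to predict.
#' @param future_covariates optional `length x features` matrix of raw
#'   covariate rows at the predicted positions (multivariate mode).
#' @return numeric vector of `length` raw-scale predictions.
#' @export
predict_autoregressive <- function(fitted, left_context, length,
                                   future_covariates = NULL) {
  spec <- fitted$spec
  rows <- as_feature_rows(left_context, spec)
  if (nrow(rows) != spec$window) {
    stop_contract(sprintf("left context has %d rows, spec window is %d",
                          nrow(rows), spec$window))
  }
  rows <- scaler_transform(fitted$scaler, rows)
  preds <- numeric(length)
  for (i in seq_len(length)) {
    x <- matrix(as.numeric(t(rows)), nrow = 1)
    p <- backend_predict(fitted$forward, x)[1, 1]
    preds[i] <- p
    new_row <- if (!is.null(future_covariates)) {
      r <- scaler_transform(
        fitted$scaler,
        as_feature_rows(future_covariates, spec)[i, , drop = FALSE])
      r[1, "pm25"] <- p
      r
    } else {
      r <- matrix(0, nrow = 1, ncol = ncol(rows),
                  dimnames = list(NULL, colnames(rows)))
      r[1, "pm25"] <- p
      r
    }
    rows <- rbind(rows[-1, , drop = FALSE], new_row)
  }
  scaler_inverse(fitted$scaler, preds)
}

#' Single-pass sequence prediction from fixed context windows
#'
#' @param fitted a `fitted_imputer` with seq2seq strategy.
#' @param left_context,right_context raw-scale feature rows (vector or
#'   matrix) of exactly `spec$window` rows each; `right_context` is
#'   required for unidirectional dual-flank specs and ignored otherwise.
#' @param length gap length; must equal the trained horizon.
#' @return numeric vector of raw-scale predictions.
#' @export
predict_seq2seq <- function(fitted, left_context, right_context = NULL,
                            length = fitted$spec$horizon) {
  spec <- fitted$spec
  if (length != spec$horizon) {
    stop_contract(sprintf("gap length %d differs from trained horizon %d",
                          length, spec$horizon))
  }
  left <- scaler_transform(fitted$scaler, as_feature_rows(left_context, spec))
  if (nrow(left) != spec$window) {
    stop_contract(sprintf("left context has %d rows, spec window is %d",
                          nrow(left), spec$window))
  }
  if (spec$directionality == "unidirectional") {
    if (is.null(right_context)) {
      stop_contract("unidirectional seq2seq needs both context flanks")
    }
    right <- scaler_transform(fitted$scaler,
                              as_feature_rows(right_context, spec))
    if (nrow(right) != spec$window) {
      stop_contract(sprintf("right context has %d rows, spec window is %d",
                            nrow(right), spec$window))
    }
    x <- matrix(c(as.numeric(t(left)), as.numeric(t(right))), nrow = 1)
    preds <- backend_predict(fitted$forward, x)[1, ]
  } else {
    if (is.null(right_context)) {
      stop_contract("bidirectional seq2seq needs both context flanks")
    }
    right <- scaler_transform(fitted$scaler,
                              as_feature_rows(right_context, spec))
    xf <- matrix(as.numeric(t(left)), nrow = 1)
    fwd <- backend_predict(fitted$forward, xf)[1, ]
    # backward model sees the reversed right flank and predicts the gap in
    # reversed time order
    xb <- matrix(as.numeric(t(right[rev(seq_len(nrow(right))), ,
                                    drop = FALSE])), nrow = 1)
    bwd <- rev(backend_predict(fitted$backward, xb)[1, ])
    preds <- fuse_bidirectional(fwd, bwd)
  }
  scaler_inverse(fitted$scaler, preds)
}

as_feature_rows <- function(x, spec) {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- spec$feature_names
    return(x)
  }
  matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, "pm25"))
}

#' Fill one gap with a fitted fixed-context imputer
#'
#' Extracts the context flanks around the gap from the series, checks
#' applicability (a full observed window on every required side), and
#' dispatches to the strategy's prediction routine. Bidirectional
#' autoregressive gaps are filled by fusing a forward roll from the left
#' flank with a backward roll from the reversed right flank.
#'
#' @param fitted a `fitted_imputer`.
#' @param series the [pm_series()] containing the gap.
#' @param gap gap description (`start`, `length`).
#' @return numeric vector of `gap$length` imputed values.
#' @export
impute_gap <- function(fitted, series, gap) {
  spec <- fitted$spec
  w <- spec$window
  n <- nrow(series)
  s <- gap$start
  e <- s + gap$length - 1L

  need_left <- TRUE
  need_right <- spec$strategy == "seq2seq" ||
    spec$directionality == "bidirectional"

  if (s - w < 1) stop_inapplicable("insufficient left context")
  left_idx <- (s - w):(s - 1L)
  if (anyNA(series$pm25[left_idx])) {
    stop_inapplicable("left context window contains missing values")
  }
  right_idx <- NULL
  if (need_right) {
    if (e + w > n) stop_inapplicable("insufficient right context")
    right_idx <- (e + 1L):(e + w)
    if (anyNA(series$pm25[right_idx])) {
      stop_inapplicable("right context window contains missing values")
    }
  }

  scaled <- scale_series(series, fitted$scaler)
  left <- context_rows(scaled, left_idx, spec)
  left_raw <- raw_rows(fitted, left)
  right_raw <- if (!is.null(right_idx)) {
    raw_rows(fitted, context_rows(scaled, right_idx, spec))
  }

  if (spec$strategy == "seq2seq") {
    if (gap$length != spec$horizon) {
      stop_inapplicable(sprintf(
        "gap length %d differs from trained horizon %d", gap$length,
        spec$horizon))
    }
    return(predict_seq2seq(fitted, left_raw, right_raw, gap$length))
  }

  gap_cov <- if (spec$variables == "multivariate") {
    raw_rows(fitted, context_rows(scaled, s:e, spec))
  }
  if (spec$directionality == "unidirectional") {
    return(predict_autoregressive(fitted, left_raw, gap$length, gap_cov))
  }
  fwd <- predict_autoregressive(fitted, left_raw, gap$length, gap_cov)
  bwd_fit <- structure(list(spec = spec, scaler = fitted$scaler,
                            forward = fitted$backward, backward = NULL),
                       class = "fitted_imputer")
  rev_right <- right_raw[rev(seq_len(nrow(right_raw))), , drop = FALSE]
  rev_cov <- if (!is.null(gap_cov)) {
    gap_cov[rev(seq_len(nrow(gap_cov))), , drop = FALSE]
  }
  bwd <- rev(predict_autoregressive(bwd_fit, rev_right, gap$length, rev_cov))
  fuse_bidirectional(fwd, bwd)
}

# undo scaling so the predict_* entry points (which scale internally) can be
# reused by impute_gap
raw_rows <- function(fitted, scaled_rows) {
  scaler_inverse(fitted$scaler, scaled_rows)
}
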