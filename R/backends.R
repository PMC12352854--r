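#' Regression backends for the supervised imputers
#'
#' The imputer framing is backend-agnostic: any regressor that maps a
#' flattened context window to one target value can be plugged in. Two
#' backends ship with the package:
#'
#' * `"boost"` - gradient boosting with squared loss over randomized
#'   regression trees (compiled); the analog of an XGBoost-style backend
#'   and the default for the supervised imputers. Defaults: 50 rounds,
#'   learning rate 0.3, depth 6.
#' * `"forest"` - a bagged randomized regression-tree ensemble (extra-trees
#'   style splits, compiled), the random-forest-style family. Defaults:
#'   50 estimators, `mtry = floor(p / 3)`, minimum node size 5.
#' * `"linear"` - ridge regression with a tiny penalty; fast, used mainly in
#'   tests and as a sanity baseline.
#'
#' Multi-target (sequence-to-sequence) fits are one independent single-output
#' regressor per horizon step over the shared input matrix.
#'
#' @param backend backend name.
#' @param X numeric input matrix (n x p).
#' @param Y numeric target matrix (n x h) or vector.
#' @param n_estimators ensemble size (tree backend).
#' @param seed integer seed; fits are deterministic given the seed.
#' @param ... backend-specific parameters (`mtry`, `min_node`, `max_depth`).
#' @return a `fitted_backend` object usable with [backend_predict()].
#' @export
backend_fit <- function(backend, X, Y, n_estimators = 50, seed = 1L, ...) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  if (nrow(X) != nrow(Y)) stop_contract("X and Y row counts differ")
  if (nrow(X) == 0) stop_insufficient("no training examples")
  fitter <- switch(backend,
                   forest = fit_forest_column,
                   boost = fit_boost_column,
                   linear = fit_linear_column,
                   stop_config(sprintf("unknown backend '%s'", backend)))
  models <- lapply(seq_len(ncol(Y)), function(j) {
    fitter(X, Y[, j], n_estimators = n_estimators,
           seed = derive_seed(seed, "col", j), ...)
  })
  structure(list(backend = backend, models = models, p = ncol(X),
                 h = ncol(Y)),
            class = "fitted_backend")
}

fit_forest_column <- function(X, y, n_estimators, seed, mtry = NULL,
                              min_node = 5L, max_depth = 25L) {
  if (is.null(mtry)) mtry <- max(1L, ncol(X) %/% 3L)
  trees <- forest_fit_cpp(X, y, as.integer(n_estimators), as.integer(mtry),
                          as.integer(min_node), as.integer(max_depth),
                          TRUE, as.double(seed))
  list(kind = "forest", trees = trees)
}

fit_boost_column <- function(X, y, n_estimators, seed, learning_rate = 0.3,
                             min_node = 2L, max_depth = 6L, mtry = NULL) {
  if (is.null(mtry)) mtry <- ncol(X)
  model <- boost_fit_cpp(X, y, as.integer(n_estimators), learning_rate,
                         as.integer(mtry), as.integer(min_node),
                         as.integer(max_depth), as.double(seed))
  list(kind = "boost", model = model)
}

fit_linear_column <- function(X, y, n_estimators, seed, lambda = 1e-4, ...) {
  Xi <- cbind(1, X)
  A <- crossprod(Xi) + diag(lambda, ncol(Xi))
  beta <- tryCatch(solve(A, crossprod(Xi, y)),
                   error = function(e) stop_pm(
                     paste("linear backend fit failed:", conditionMessage(e)),
                     "pmgapfill_fit_error"))
  list(kind = "linear", beta = as.numeric(beta))
}

#' @param fitted a `fitted_backend`.
#' @param X numeric input matrix (m x p).
#' @rdname backend_fit
#' @return `backend_predict` returns an m x h prediction matrix.
#' @export
backend_predict <- function(fitted, X) {
  X <- as.matrix(X)
  if (ncol(X) != fitted$p) {
    stop_contract(sprintf("input has %d columns, backend expects %d",
                          ncol(X), fitted$p))
  }
  out <- vapply(fitted$models, function(m) {
    switch(m$kind,
           forest = as.numeric(forest_predict_cpp(m$trees, X)),
           boost = as.numeric(boost_predict_cpp(m$model, X)),
           as.numeric(cbind(1, X) %*% m$beta))
  }, numeric(nrow(X)))
  matrix(out, nrow = nrow(X), ncol = fitted$h)
}
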