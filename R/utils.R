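#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @useDynLib pmgapfill, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx arima lm median na.omit predict quantile rnorm
#'   runif sd t.test var
#' @importFrom utils read.csv write.csv head tail
## usethis namespace: end
NULL

MOD31 <- 2147483647  # 2^31 - 1; all derived seeds stay below this

#' Derive a reproducible sub-seed from a master seed
#'
#' A fixed multiplicative hash combining the master seed with any number of
#' integer or character tokens. Used to give every (model, run, gap-length)
#' combination its own deterministic RNG stream while keeping all seeds
#' within the 32-bit range R requires.
#'
#' @param master integer master seed.
#' @param ... integer or character tokens identifying the consumer.
#' @return a positive integer strictly below 2^31.
#' @export
derive_seed <- function(master, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(paste(p, collapse = "|")) else as.integer(p)
  }), use.names = FALSE)
  h <- (abs(as.double(master)) + 1) %% MOD31
  for (p in parts) h <- (h * 48271 + abs(as.double(p)) + 1) %% MOD31
  as.integer(max(1, h))
}

# Evaluate `code` under `seed` and restore the caller's RNG state afterwards,
# so generators are bit-reproducible without clobbering the session stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_pm <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pmgapfill_error")))
}

# method cannot be applied to this gap (benchmark records it as a failure)
stop_inapplicable <- function(msg) stop_pm(msg, "pmgapfill_inapplicable")
stop_config       <- function(msg) stop_pm(msg, "pmgapfill_invalid_config")
stop_contract     <- function(msg) stop_pm(msg, "pmgapfill_contract")
stop_insufficient <- function(msg) stop_pm(msg, "pmgapfill_insufficient_data")

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)
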