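#' Detect contiguous missing runs in a series
#'
#' Finds all maximal runs of `NA` in the PM2.5 values and describes each by
#' its start index (1-based), length, and the amount of observed context
#' available on each side (distance to the previous/next missing value or
#' series boundary).
#'
#' @param series a [pm_series()] or numeric vector.
#' @return a data frame with columns `start`, `length`, `left_context`,
#'   `right_context`, sorted by `start`. Zero rows when nothing is missing.
#' @export
find_gaps <- function(series) {
  vals <- series_values(series)
  miss <- is.na(vals)
  if (!any(miss)) {
    return(data.frame(start = integer(), length = integer(),
                      left_context = integer(), right_context = integer()))
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gi <- which(r$values)
  find_gap_table(vals, starts[gi], r$lengths[gi])
}

# shared constructor: context = run of observed values flanking each gap
find_gap_table <- function(vals, starts, lengths) {
  n <- length(vals)
  miss_pos <- which(is.na(vals))
  k <- length(starts)
  left <- integer(k)
  right <- integer(k)
  for (i in seq_len(k)) {
    s <- starts[i]
    e <- starts[i] + lengths[i] - 1L
    prev_miss <- miss_pos[miss_pos < s]
    next_miss <- miss_pos[miss_pos > e]
    left[i] <- s - 1L - if (length(prev_miss)) max(prev_miss) else 0L
    right[i] <- (if (length(next_miss)) min(next_miss) else n + 1L) - e - 1L
  }
  data.frame(start = as.integer(starts), length = as.integer(lengths),
             left_context = left, right_context = right)
}

#' Histogram of gap lengths
#'
#' @param gaps a gap table from [find_gaps()] or [inject_missingness()].
#' @return a named integer vector mapping gap length to count (empty for an
#'   empty gap table).
#' @export
gap_length_histogram <- function(gaps) {
  if (nrow(gaps) == 0) return(integer(0))
  tab <- table(gaps$length)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Write a gap report as CSV
#'
#' One row per gap: start timestamp, length in hours, and available context
#' on each side.
#'
#' @param series the [pm_series()] the gaps were found in.
#' @param gaps gap table from [find_gaps()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(series, gaps, path) {
  out <- data.frame(
    start_timestamp = format(series$timestamp[gaps$start],
                             "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    length_hours = gaps$length,
    left_context = gaps$left_context,
    right_context = gaps$right_context)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
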