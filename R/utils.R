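#' Derive an independent sub-seed from a global seed
#'
#' Each stochastic stage of the pipeline consumes its own sub-seed so that
#' changing one stage's randomness leaves the others untouched. The stream
#' label is hashed into an integer offset; results stay below 2^31.
#'
#' @param seed Integer global seed.
#' @param stream Character label of the consuming stage.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587L) + 1L
}

#' Spike counts in half-open windows
#'
#' Counts spikes falling in `[lo, hi)` for each (lo, hi) pair. Spike times
#' must be sorted ascending.
#'
#' @param spikes Sorted numeric vector of spike times (s).
#' @param lo,hi Numeric vectors of window edges (s), recycled to equal length.
#' @return Integer vector of counts.
#' @keywords internal
count_in_windows <- function(spikes, lo, hi) {
  n <- max(length(lo), length(hi))
  lo <- rep_len(lo, n)
  hi <- rep_len(hi, n)
  # findInterval on sorted spikes: number strictly below x is
  # findInterval(x - eps)... use left.open to get [lo, hi) exactly:
  # count = #(spikes < hi) - #(spikes < lo)
  below <- function(x) findInterval(x, spikes, left.open = TRUE)
  below(hi) - below(lo)
}

#' Firing rate in a half-open window around events
#'
#' @param spikes Sorted spike times (s).
#' @param events Event times (s).
#' @param window Length-2 numeric, window relative to each event, `[lo, hi)`.
#' @return Numeric vector of rates (Hz), one per event.
#' @export
rate_in_window <- function(spikes, events, window) {
  if (length(events) == 0) return(numeric(0))
  count_in_windows(spikes, events + window[1], events + window[2]) /
    (window[2] - window[1])
}

run_starts <- function(flag, min_len) {
  # start indices of runs of TRUE with length >= min_len
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts[r$values & r$lengths >= min_len]
}
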