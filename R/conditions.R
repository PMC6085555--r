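# Classed error conditions: every contract violation raises a condition of
# class faceAOI_<name> so callers and tests can match on the specific failure.

aoi_error <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(paste0("faceAOI_", class), "faceAOI_error", "error")
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Strictly-increasing check shared by all timestamped readers.
check_monotonic <- function(t, what = "timestamp") {
  if (length(t) > 1L && any(diff(t) <= 0)) {
    aoi_error(
      "non_monotonic_timestamps",
      sprintf("%ss must be strictly increasing", what)
    )
  }
  invisible(t)
}

# Median inter-sample interval -> rate in Hz; NA when fewer than 2 samples.
estimate_rate <- function(t) {
  if (length(t) < 2L) return(NA_real_)
  1 / stats::median(diff(t))
}
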