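# Statistics for comparing two AOI-center tracks (e.g. a fully automatic
# landmark-based track against an independently obtained track of the same
# video), temporal-stability measures, and blink-spike handling.

check_comparable <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    aoi_error("length_mismatch", "center tracks differ in length")
  }
  ok <- as.logical(a$valid) & as.logical(b$valid)
  if (!any(ok)) {
    aoi_error("no_overlapping_valid_frames",
              "the tracks share no frame where both are valid")
  }
  ok
}

per_aoi_axis <- function(fun, aois = AOI_LABELS) {
  out <- expand.grid(aoi = aois, axis = c("x", "y"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$aoi, aois)), ]
  out$value <- mapply(function(aoi, axis) fun(paste0(aoi, "_", axis)),
                      out$aoi, out$axis)
  rownames(out) <- NULL
  out
}

#' Mean and maximum absolute coordinate difference between two center tracks
#'
#' Frame-wise `|a - b|` per AOI and axis, averaged (`mean_abs_diff`) or
#' maximised (`max_abs_diff`) over the frames where both tracks are valid.
#' The maximum corresponds to a single video frame, not an average. Both
#' statistics are symmetric in their arguments.
#'
#' @param a,b `aoi_center_track`s of equal length.
#' @return A data frame with columns `aoi`, `axis`, `value` (pixels).
#' @export
mean_abs_diff <- function(a, b) {
  ok <- check_comparable(a, b)
  per_aoi_axis(function(col) mean(abs(a[[col]][ok] - b[[col]][ok])))
}

#' @rdname mean_abs_diff
#' @export
max_abs_diff <- function(a, b) {
  ok <- check_comparable(a, b)
  per_aoi_axis(function(col) max(abs(a[[col]][ok] - b[[col]][ok])))
}

#' Temporal stability of a center track (RMS deviation)
#'
#' The default `"s2s"` method is the sample-to-sample RMS:
#' `sqrt(mean((x[i+1] - x[i])^2))` over consecutive pairs of valid frames.
#' It measures frame-to-frame jitter of the AOI centers and is insensitive
#' to slow genuine head motion. The alternative `"about_mean"` is the RMS
#' deviation about the track mean, which conflates jitter with motion.
#'
#' @param track An `aoi_center_track`.
#' @param method `"s2s"` (default) or `"about_mean"`.
#' @return A data frame with columns `aoi`, `axis`, `value` (pixels).
#' @export
rms_s2s <- function(track, method = c("s2s", "about_mean")) {
  method <- match.arg(method)
  ok <- as.logical(track$valid)
  if (method == "s2s") {
    pair <- ok[-length(ok)] & ok[-1]
    if (!any(pair)) {
      aoi_error("insufficient_data",
                "need at least 2 consecutive valid frames")
    }
    per_aoi_axis(function(col) {
      d <- diff(track[[col]])[pair]
      sqrt(mean(d^2))
    })
  } else {
    if (sum(ok) < 2L) {
      aoi_error("insufficient_data", "need at least 2 valid frames")
    }
    per_aoi_axis(function(col) {
      x <- track[[col]][ok]
      sqrt(mean((x - mean(x))^2))
    })
  }
}

#' Full comparison report for two center tracks
#'
#' Combines [mean_abs_diff()], [rms_s2s()] of each track, and
#' [max_abs_diff()], in pixels and in degrees of visual angle (the degree
#' columns map the pixel values through [px_to_deg()] on the matching
#' screen axis).
#'
#' @param a,b `aoi_center_track`s of equal length.
#' @param geom A [screen_geometry()].
#' @return A data frame with one row per AOI x axis and columns
#'   `mean_abs_diff_px/_deg`, `rms_a_px`, `rms_b_px`, `max_abs_diff_px/_deg`.
#' @export
track_comparison <- function(a, b, geom) {
  mad_ <- mean_abs_diff(a, b)
  mx <- max_abs_diff(a, b)
  ra <- rms_s2s(a)
  rb <- rms_s2s(b)
  to_deg <- function(px, axis) {
    mapply(function(p, ax) {
      px_to_deg(p, geom, if (ax == "x") "horizontal" else "vertical")
    }, px, axis)
  }
  data.frame(
    aoi = mad_$aoi, axis = mad_$axis,
    mean_abs_diff_px = mad_$value,
    mean_abs_diff_deg = to_deg(mad_$value, mad_$axis),
    rms_a_px = ra$value, rms_b_px = rb$value,
    max_abs_diff_px = mx$value,
    max_abs_diff_deg = to_deg(mx$value, mx$axis)
  )
}

#' Detect blink spikes in a center track (Hampel rule)
#'
#' Eyelid closure transiently drags landmark-derived eye centers downward
#' and toward the face midline. Such spikes are flagged with a Hampel
#' detector: a frame is flagged when any monitored coordinate deviates
#' from its rolling-window median by more than `n_mad` scaled median
#' absolute deviations (MAD x 1.4826) of that window. By default only the
#' two eye AOIs are monitored, since blinks do not displace the nose or
#' mouth centers. Windows are truncated at the track ends; invalid frames
#' are ignored and never flagged. The window median is robust to a spike
#' only while the spike occupies fewer than half the window, so `window`
#' should exceed twice the longest expected blink (in frames).
#'
#' @param track An `aoi_center_track`.
#' @param window Odd window length in frames, >= 3.
#' @param n_mad Flagging threshold in scaled-MAD units.
#' @param aois AOI labels to monitor.
#' @return Logical vector, one flag per frame.
#' @export
detect_spikes <- function(track, window = 7L, n_mad = 3,
                          aois = c("left_eye", "right_eye")) {
  n <- nrow(track)
  if (window %% 2L == 0L || window < 3L) {
    aoi_error("domain_error", "window must be odd and >= 3")
  }
  if (window > n) {
    aoi_error("window_too_large", "window exceeds the track length")
  }
  h <- (window - 1L) %/% 2L
  ok <- as.logical(track$valid)
  flags <- logical(n)
  for (col in center_cols(aois)) {
    x <- track[[col]]
    for (i in seq_len(n)) {
      if (!ok[i]) next
      win <- max(1L, i - h):min(n, i + h)
      vals <- x[win][ok[win]]
      med <- stats::median(vals)
      mad_s <- 1.4826 * stats::median(abs(vals - med))
      if (abs(x[i] - med) > n_mad * mad_s) flags[i] <- TRUE
    }
  }
  flags
}

#' Remove flagged spike frames from a center track
#'
#' Replaces the monitored coordinates of flagged frames either by linear
#' interpolation between the nearest unflagged valid frames
#' (`"interpolate"`; ends are extended from the nearest unflagged frame)
#' or by the median of the unflagged valid frames in the surrounding
#' window (`"median_replace"`). Unflagged frames are returned bit-identical.
#'
#' @param track An `aoi_center_track`.
#' @param flags Logical vector from [detect_spikes()], aligned with `track`.
#' @param method `"interpolate"` or `"median_replace"`.
#' @param window Window length for `"median_replace"`.
#' @param aois AOI labels whose coordinates are repaired.
#' @return An `aoi_center_track`.
#' @export
filter_spikes <- function(track, flags,
                          method = c("interpolate", "median_replace"),
                          window = 7L, aois = c("left_eye", "right_eye")) {
  method <- match.arg(method)
  n <- nrow(track)
  if (length(flags) != n) {
    aoi_error("length_mismatch", "flags must align with the track")
  }
  ok <- as.logical(track$valid)
  keep <- which(!flags & ok)
  if (!length(keep)) {
    aoi_error("all_frames_flagged", "no unflagged valid frame remains")
  }
  out <- track
  bad <- which(flags & ok)
  if (!length(bad)) return(out)
  h <- (window - 1L) %/% 2L
  for (col in center_cols(aois)) {
    x <- track[[col]]
    if (method == "interpolate") {
      out[[col]][bad] <- stats::approx(keep, x[keep], xout = bad,
                                       rule = 2)$y
    } else {
      out[[col]][bad] <- vapply(bad, function(i) {
        win <- max(1L, i - h):min(n, i + h)
        ref <- intersect(win, keep)
        if (!length(ref)) ref <- keep[which.min(abs(keep - i))]
        stats::median(x[ref])
      }, numeric(1))
    }
  }
  out
}
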