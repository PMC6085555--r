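# Dyadic paired-gaze states: combine two participants' AOI label streams
# into per-sample states two_way / one_way / no_eye_gaze / undefined.

#' Join two AOI label streams onto a common timeline
#'
#' Two recordings share no clock, so the streams are joined by nearest
#' timestamp onto the coarser (lower-rate) stream's timeline. A partner
#' sample farther away than `tolerance_s` contributes the label
#' `"missing"` (which classifies as `undefined`).
#'
#' @param a,b `aoi_label_stream`s for participants A and B.
#' @param tolerance_s Maximum timestamp mismatch; default half the coarser
#'   stream's sample interval.
#' @return A data frame with columns `time`, `label_a`, `label_b` and
#'   attribute `sampling_rate` (of the base timeline).
#' @export
join_timelines <- function(a, b, tolerance_s = NULL) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    aoi_error("empty_stream", "both label streams must be nonempty")
  }
  dt_a <- stream_dt(a)
  dt_b <- stream_dt(b)
  a_is_base <- dt_a >= dt_b  # coarser stream wins; ties keep A
  base <- if (a_is_base) a else b
  other <- if (a_is_base) b else a
  tol <- tolerance_s %||% (max(dt_a, dt_b) / 2)

  partner <- nearest_label(base$time, other$time, other$label, tol)
  out <- data.frame(
    time = base$time,
    label_a = if (a_is_base) base$label else partner,
    label_b = if (a_is_base) partner else base$label
  )
  structure(out, sampling_rate = 1 / max(dt_a, dt_b))
}

nearest_label <- function(t_query, t_ref, labels, tol) {
  lo <- findInterval(t_query, t_ref)
  hi <- pmin(lo + 1L, length(t_ref))
  lo <- pmax(lo, 1L)
  d_lo <- abs(t_query - t_ref[lo])
  d_hi <- abs(t_query - t_ref[hi])
  idx <- ifelse(d_lo <= d_hi, lo, hi)
  d <- pmin(d_lo, d_hi)
  out <- labels[idx]
  out[d > tol] <- MISSING_LABEL
  out
}

#' Classify a pair of AOI labels into a dyadic gaze state
#'
#' A participant is "looking at the eyes" when their label is `left_eye`
#' or `right_eye`. Both looking gives `two_way`, exactly one `one_way`,
#' neither (with both labels observed) `no_eye_gaze`. If either label is
#' `missing`, the state is `undefined`: absence of data is not evidence of
#' looking away. The classification is symmetric in its arguments.
#'
#' @param label_a,label_b Character vectors of stream labels.
#' @return Character vector of paired states.
#' @export
classify_state <- function(label_a, label_b) {
  eyes_a <- label_a %in% EYE_LABELS
  eyes_b <- label_b %in% EYE_LABELS
  miss <- label_a == MISSING_LABEL | label_b == MISSING_LABEL |
    is.na(label_a) | is.na(label_b)
  out <- ifelse(eyes_a & eyes_b, "two_way",
                ifelse(xor(eyes_a, eyes_b), "one_way", "no_eye_gaze"))
  out[miss] <- "undefined"
  out
}

#' Build a paired-gaze state stream from two label streams
#'
#' [join_timelines()] followed by [classify_state()].
#'
#' @inheritParams join_timelines
#' @return A `paired_gaze_stream`: data frame with columns `time`, `state`
#'   and attribute `sampling_rate`.
#' @export
pair_streams <- function(a, b, tolerance_s = NULL) {
  j <- join_timelines(a, b, tolerance_s)
  structure(data.frame(time = j$time,
                       state = classify_state(j$label_a, j$label_b)),
            sampling_rate = attr(j, "sampling_rate"),
            class = c("paired_gaze_stream", "data.frame"))
}

#' Summarise paired-gaze states
#'
#' An episode is a maximal run of one state. Reports, per state, the total
#' time, mean episode duration, episode count, and episode rate per minute
#' of joined session time. Durations follow the same convention as dwells:
#' each sample occupies one sample interval.
#'
#' @param stream A `paired_gaze_stream`.
#' @param states States to report.
#' @return A data frame with columns `state`, `total_time_s`,
#'   `mean_episode_s`, `n_episodes`, `episodes_per_min`.
#' @export
summarize_states <- function(stream, states = paired_states()) {
  n <- nrow(stream)
  if (n == 0L) aoi_error("empty_stream", "paired stream has no samples")
  dt <- stream_dt(stream)
  session_s <- n * dt
  r <- rle(stream$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- stream$time[ends] + dt - stream$time[starts]
  out <- do.call(rbind, lapply(states, function(s) {
    d <- dur[r$values == s]
    data.frame(state = s,
               total_time_s = sum(d),
               mean_episode_s = if (length(d)) mean(d) else 0,
               n_episodes = length(d),
               episodes_per_min = length(d) / (session_s / 60))
  }))
  rownames(out) <- NULL
  out
}
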