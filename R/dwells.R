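# Dwell segmentation and per-AOI dwell measures.
#
# Duration convention: each sample occupies one sample interval, so a dwell
# spanning samples i..j lasts (t_j + dt) - t_i and a one-sample dwell lasts
# dt = 1/sampling_rate. This makes time conservation exact: summed dwell
# time over all labels plus missing time equals the recording duration.

stream_dt <- function(stream) {
  sr <- attr(stream, "sampling_rate")
  if (!is.null(sr) && is.finite(sr) && sr > 0) return(1 / sr)
  if (nrow(stream) < 2L) {
    aoi_error("domain_error",
              "cannot infer the sample interval of a 1-sample stream")
  }
  stats::median(diff(stream$time))
}

#' Segment an AOI label stream into dwells
#'
#' A dwell is a maximal run of identical non-missing labels. Runs of
#' `"missing"` lasting at most `gap_tolerance_s` that are flanked by the
#' same label on both sides are bridged into a single dwell (missing
#' samples are not counted in `n_samples`).
#'
#' @param stream An `aoi_label_stream`.
#' @param gap_tolerance_s Longest missing gap (seconds) bridged when both
#'   flanks carry the same label; default 0 bridges nothing.
#' @param min_dwell_s Dwells shorter than this are dropped; default 0
#'   keeps everything.
#' @return A data frame with one row per dwell: `label`, `start`, `end`,
#'   `duration`, `n_samples`.
#' @export
segment_dwells <- function(stream, gap_tolerance_s = 0, min_dwell_s = 0) {
  n <- nrow(stream)
  if (n == 0L) aoi_error("empty_stream", "label stream has no samples")
  dt <- stream_dt(stream)
  r <- rle(stream$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  dwells <- list()
  last <- NULL  # open dwell: list(label, i0, i1, n_samples)
  pending_gap <- NULL  # duration of the missing run between last and now
  flush <- function() {
    if (!is.null(last)) dwells[[length(dwells) + 1L]] <<- last
    last <<- NULL
  }
  for (j in seq_along(r$values)) {
    lab <- r$values[j]
    if (lab == MISSING_LABEL) {
      pending_gap <- r$lengths[j] * dt
      next
    }
    bridge <- !is.null(last) && last$label == lab &&
      !is.null(pending_gap) && pending_gap <= gap_tolerance_s + 1e-12
    contiguous <- !is.null(last) && is.null(pending_gap) &&
      last$label == lab  # cannot happen with rle, kept for clarity
    if (bridge || contiguous) {
      last$i1 <- ends[j]
      last$n_samples <- last$n_samples + r$lengths[j]
    } else {
      flush()
      last <- list(label = lab, i0 = starts[j], i1 = ends[j],
                   n_samples = r$lengths[j])
    }
    pending_gap <- NULL
  }
  flush()

  if (!length(dwells)) {
    return(data.frame(label = character(), start = numeric(),
                      end = numeric(), duration = numeric(),
                      n_samples = integer()))
  }
  out <- data.frame(
    label = vapply(dwells, `[[`, "", "label"),
    start = stream$time[vapply(dwells, `[[`, 0L, "i0")],
    end = stream$time[vapply(dwells, `[[`, 0L, "i1")] + dt,
    n_samples = vapply(dwells, function(d) as.integer(d$n_samples), 0L)
  )
  out$duration <- out$end - out$start
  out <- out[, c("label", "start", "end", "duration", "n_samples")]
  out[out$duration >= min_dwell_s - 1e-12, , drop = FALSE]
}

merge_adjacent_dwells <- function(dwells, tol_s = 1e-9) {
  if (nrow(dwells) < 2L) return(dwells)
  keep <- logical(nrow(dwells))
  keep[1] <- TRUE
  cur <- 1L
  for (i in 2L:nrow(dwells)) {
    same <- dwells$label[i] == dwells$label[cur]
    adjacent <- abs(dwells$start[i] - dwells$end[cur]) <= tol_s
    if (same && adjacent) {
      dwells$end[cur] <- dwells$end[i]
      dwells$duration[cur] <- dwells$end[cur] - dwells$start[cur]
      dwells$n_samples[cur] <- dwells$n_samples[cur] + dwells$n_samples[i]
    } else {
      keep[i] <- TRUE
      cur <- i
    }
  }
  dwells[keep, , drop = FALSE]
}

#' Summarise dwells per AOI
#'
#' Computes total dwell time (TDT), mean dwell time and number of dwells
#' per AOI label, plus combined labels: by default `eyes`, aggregating the
#' left- and right-eye AOIs. Under a combined labeling, temporally adjacent
#' left/right-eye dwells merge into a single `eyes` dwell, so the combined
#' TDT is the sum of the member TDTs while the combined dwell count can be
#' smaller than the member counts' sum.
#'
#' @param dwells A dwell table from [segment_dwells()].
#' @param combine Named list mapping each combined label to the member
#'   labels it aggregates; member sets must be disjoint.
#' @param labels Base labels to report (a row is emitted even when a label
#'   has no dwells).
#' @return A data frame with columns `label`, `total_dwell_time_s`,
#'   `mean_dwell_time_s`, `n_dwells`.
#' @export
summarize_dwells <- function(dwells,
                             combine = list(eyes = c("left_eye",
                                                     "right_eye")),
                             labels = c(aoi_labels(), "non")) {
  members <- unlist(combine, use.names = FALSE)
  if (anyDuplicated(members)) {
    aoi_error("unknown_label", "combine member sets must be disjoint")
  }
  if (length(members) && !all(members %in% STREAM_LABELS)) {
    aoi_error("unknown_label",
              sprintf("unknown label(s) in combine: %s",
                      paste(setdiff(members, STREAM_LABELS),
                            collapse = ", ")))
  }
  one <- function(lab, d) {
    d <- d[d$label == lab, , drop = FALSE]
    n <- nrow(d)
    tot <- sum(d$duration)
    data.frame(label = lab, total_dwell_time_s = tot,
               mean_dwell_time_s = if (n > 0) tot / n else 0,
               n_dwells = n)
  }
  base <- do.call(rbind, lapply(labels, one, d = dwells))
  comb <- lapply(names(combine), function(new_lab) {
    d <- dwells
    d$label[d$label %in% combine[[new_lab]]] <- new_lab
    one(new_lab, merge_adjacent_dwells(d))
  })
  out <- rbind(base, do.call(rbind, comb))
  rownames(out) <- NULL
  out
}

#' Percent difference relative to a reference method
#'
#' `100 * |a - ref| / ref`, the "absolute difference (%)" used when
#' benchmarking one AOI method's measure against a reference method's.
#'
#' @param measure_a Value from the method under test.
#' @param measure_ref Value from the reference method (nonzero).
#' @return Percent difference (vectorised).
#' @export
percent_difference <- function(measure_a, measure_ref) {
  if (any(measure_ref == 0)) {
    aoi_error("division_by_zero", "reference measure must be nonzero")
  }
  100 * abs(measure_a - measure_ref) / measure_ref
}
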