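#' AOI definitions: landmark subsets per facial feature
#'
#' Maps each AOI label to the set of 1-based landmark numbers whose mean
#' coordinate is that AOI's cell center. The default is the standard
#' mapping for the 68-point scheme: left eye 37-42, right eye 43-48, nose
#' 31 (the nose tip, a single-landmark AOI), mouth 63 and 67 (upper and
#' lower inner-lip midpoints, so the center is the middle of the mouth
#' opening). "Left eye" is the eye on the left of the image (viewer
#' perspective).
#'
#' @param left_eye,right_eye,nose,mouth Integer vectors of 1-based landmark
#'   numbers in 1..68; the four sets must be disjoint and nonempty.
#' @return An `aoi_definition` (named list of integer vectors).
#' @export
aoi_definition <- function(left_eye = 37:42, right_eye = 43:48,
                           nose = 31L, mouth = c(63L, 67L)) {
  def <- list(left_eye = as.integer(left_eye),
              right_eye = as.integer(right_eye),
              nose = as.integer(nose), mouth = as.integer(mouth))
  all_pts <- unlist(def)
  if (any(lengths(def) == 0L)) {
    aoi_error("domain_error", "every AOI needs at least one landmark")
  }
  if (any(all_pts < 1L | all_pts > 68L)) {
    aoi_error("domain_error", "landmark numbers must be in 1..68")
  }
  if (anyDuplicated(all_pts)) {
    aoi_error("domain_error", "AOI landmark sets must be disjoint")
  }
  structure(def, class = "aoi_definition")
}

#' Derive AOI cell centers for one video frame
#'
#' Each AOI cell center is the arithmetic mean of the coordinates of its
#' landmark subset; a single-landmark AOI (the nose) therefore equals that
#' landmark's coordinate exactly.
#'
#' @param frame A single row of a `landmark_track` (or any list with the
#'   fields `success` and `x_1..x_68`/`y_1..y_68`).
#' @param definition An [aoi_definition()].
#' @return A named list with one `c(x, y)` pair per AOI label.
#' @export
derive_center_set <- function(frame, definition = aoi_definition()) {
  if (!isTRUE(as.logical(frame$success))) {
    aoi_error("invalid_frame",
              "landmark detection failed for this frame (success = FALSE)")
  }
  lapply(definition, function(pts) {
    c(x = mean(vapply(paste0("x_", pts), function(c) as.numeric(frame[[c]]),
                      numeric(1))),
      y = mean(vapply(paste0("y_", pts), function(c) as.numeric(frame[[c]]),
                      numeric(1))))
  })
}

#' Derive a per-frame AOI-center track from a landmark track
#'
#' Applies [derive_center_set()] to every frame. Frames where the detector
#' failed (`success = FALSE`, or confidence below `min_confidence`) are
#' handled by the gap policy: `carry_forward` repeats the last valid
#' centers for dropouts of at most `max_gap_frames` frames (such frames are
#' flagged `carried`), longer runs — and leading dropouts with nothing to
#' carry — become missing (`valid = FALSE`, coordinates `NaN`);
#' `mark_missing` marks every failed frame missing.
#'
#' @param track A `landmark_track`.
#' @param definition An [aoi_definition()].
#' @param gap_policy `"carry_forward"` or `"mark_missing"`.
#' @param max_gap_frames Longest dropout (in frames) bridged by
#'   carry-forward; the default 12 is about half a second at 25 fps.
#' @param min_confidence Frames below this detector confidence are treated
#'   as failed; default 0 applies no confidence filter.
#' @return An `aoi_center_track` with one row per video frame and columns
#'   `frame`, `timestamp`, `valid`, `<aoi>_x`/`<aoi>_y`, `carried`.
#' @export
derive_center_track <- function(track, definition = aoi_definition(),
                                gap_policy = c("carry_forward",
                                               "mark_missing"),
                                max_gap_frames = 12L, min_confidence = 0) {
  gap_policy <- match.arg(gap_policy)
  n <- nrow(track)
  if (n < 1L) aoi_error("empty_stream", "landmark track has no frames")
  ok <- as.logical(track$success) & track$confidence >= min_confidence
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) {
    aoi_error("all_frames_invalid", "no frame has a successful detection")
  }

  out <- data.frame(frame = track$frame, timestamp = track$timestamp,
                    valid = ok)
  # vectorised mean over each AOI's landmark columns
  for (aoi in names(definition)) {
    pts <- definition[[aoi]]
    xm <- as.matrix(track[, paste0("x_", pts), drop = FALSE])
    ym <- as.matrix(track[, paste0("y_", pts), drop = FALSE])
    out[[paste0(aoi, "_x")]] <- rowMeans(xm)
    out[[paste0(aoi, "_y")]] <- rowMeans(ym)
  }
  ccols <- center_cols(names(definition))
  out[!ok, ccols] <- NaN
  out$carried <- rep(FALSE, n)

  if (gap_policy == "carry_forward" && any(!ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] || starts[j] == 1L) next  # valid run, or nothing to carry
      if (r$lengths[j] <= max_gap_frames) {
        idx <- starts[j]:ends[j]
        src <- starts[j] - 1L
        out[idx, ccols] <- out[rep(src, length(idx)), ccols]
        out$valid[idx] <- TRUE
        out$carried[idx] <- TRUE
      }
    }
  }
  new_center_track(out, attr(track, "frame_rate"))
}
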