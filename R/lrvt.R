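#' Limited-Radius Voronoi Tessellation configuration
#'
#' The LRVT rule assigns a gaze coordinate to the facial AOI whose cell
#' center is Euclidean-nearest, provided that distance does not exceed a
#' maximum radius; otherwise the sample belongs to the `"non"` AOI. The
#' default radius is 4 degrees of visual angle.
#'
#' @param radius_deg Maximum center distance in degrees of visual angle.
#' @param tie_order Permutation of the four AOI labels used to break exact
#'   distance ties deterministically (ties have measure zero in practice).
#' @param boundary_inclusive If `TRUE` (default) a distance exactly equal
#'   to the radius is still inside the AOI ("does not exceed" reads as <=).
#' @return An `lrvt_config` list.
#' @export
lrvt_config <- function(radius_deg = 4, tie_order = aoi_labels(),
                        boundary_inclusive = TRUE) {
  if (!is.finite(radius_deg) || radius_deg <= 0) {
    aoi_error("domain_error", "radius_deg must be positive and finite")
  }
  if (!setequal(tie_order, AOI_LABELS) || length(tie_order) != 4L) {
    aoi_error("domain_error",
              "tie_order must be a permutation of the four AOI labels")
  }
  structure(list(radius_deg = radius_deg, tie_order = tie_order,
                 boundary_inclusive = isTRUE(boundary_inclusive)),
            class = "lrvt_config")
}

#' Align gaze timestamps to video frame indices
#'
#' Gaze is sampled faster than video; sample at time `t` falls in frame
#' `floor((t - offset) * frame_rate)`. Indices outside `[0, n_frames - 1]`
#' are clamped and flagged. A tiny guard (1e-9) absorbs floating-point
#' noise at exact frame boundaries.
#'
#' @param timestamps Sample times in seconds.
#' @param frame_rate Video frame rate in Hz (> 0).
#' @param offset Gaze-to-video clock offset in seconds (video frame 0
#'   starts at gaze time `offset`).
#' @param n_frames Number of frames available, for clamping; `NULL` skips
#'   the upper clamp.
#' @return A data frame with columns `frame` (integer) and `clamped`
#'   (logical).
#' @export
align_to_frames <- function(timestamps, frame_rate, offset = 0,
                            n_frames = NULL) {
  if (!is.finite(frame_rate) || frame_rate <= 0) {
    aoi_error("domain_error", "frame_rate must be > 0")
  }
  raw <- floor((timestamps - offset) * frame_rate + 1e-9)
  clamped <- raw < 0
  raw[raw < 0] <- 0
  if (!is.null(n_frames)) {
    over <- raw > n_frames - 1L
    clamped <- clamped | over
    raw[over] <- n_frames - 1L
  }
  data.frame(frame = as.integer(raw), clamped = clamped)
}

# Accepts a one-row slice of an aoi_center_track or a named list of c(x, y)
# pairs; returns a 4 x 2 matrix with AOI labels as rownames.
as_center_matrix <- function(centers) {
  if (is.data.frame(centers)) {
    if (!is.null(centers$valid) && !isTRUE(as.logical(centers$valid[1]))) {
      aoi_error("invalid_centers", "center set is marked invalid")
    }
    m <- matrix(
      unlist(centers[1, center_cols()], use.names = FALSE),
      ncol = 2, byrow = TRUE, dimnames = list(AOI_LABELS, c("x", "y")))
  } else {
    m <- do.call(rbind, centers[AOI_LABELS])
    colnames(m) <- c("x", "y")
  }
  if (any(!is.finite(m))) {
    aoi_error("invalid_centers", "center coordinates must be finite")
  }
  m
}

#' Assign one gaze coordinate to an AOI (LRVT rule)
#'
#' @param point Numeric `c(x, y)` in pixels.
#' @param centers A valid AOI center set: a one-row slice of an
#'   `aoi_center_track` or a named list of `c(x, y)` pairs.
#' @param radius_px LRVT radius in pixels (> 0).
#' @param config An [lrvt_config()] (`radius_deg` is ignored here — the
#'   radius is passed in pixels).
#' @return One of `r paste(c(aoi_labels(), "non"), collapse = ", ")`.
#' @examples
#' cs <- list(left_eye = c(100, 100), right_eye = c(200, 100),
#'            nose = c(150, 160), mouth = c(150, 220))
#' assign_point(c(110, 105), cs, radius_px = 80)
#' @export
assign_point <- function(point, centers, radius_px,
                         config = lrvt_config()) {
  if (!is.finite(radius_px) || radius_px <= 0) {
    aoi_error("domain_error", "radius_px must be positive")
  }
  m <- as_center_matrix(centers)[config$tie_order, , drop = FALSE]
  d2 <- (m[, "x"] - point[1])^2 + (m[, "y"] - point[2])^2
  k <- which.min(d2)  # first minimum -> tie broken by tie_order
  inside <- if (config$boundary_inclusive) d2[k] <= radius_px^2
            else d2[k] < radius_px^2
  if (inside) rownames(m)[k] else NON_LABEL
}

#' Assign a gaze recording to AOIs against a center track
#'
#' Converts the LRVT radius from degrees to pixels once (horizontal axis at
#' screen center), aligns each gaze sample to its video frame, and applies
#' the LRVT rule against that frame's centers. Samples that are invalid, or
#' whose aligned frame has missing centers, are labelled `"missing"`.
#'
#' @param gaze A `gaze_recording`.
#' @param centers An `aoi_center_track`.
#' @param config An [lrvt_config()].
#' @param geom A [screen_geometry()] (for the radius conversion).
#' @param frame_rate Video frame rate in Hz; defaults to the center track's
#'   `frame_rate` attribute.
#' @param offset Gaze-to-video clock offset in seconds.
#' @return An `aoi_label_stream` with columns `time`, `frame`, `label`.
#' @export
assign_stream <- function(gaze, centers, config = lrvt_config(), geom,
                          frame_rate = NULL, offset = 0) {
  frame_rate <- frame_rate %||% attr(centers, "frame_rate")
  radius_px <- deg_to_px(config$radius_deg, geom, "horizontal")
  al <- align_to_frames(gaze$time, frame_rate, offset,
                        n_frames = nrow(centers))
  idx <- al$frame + 1L
  n <- nrow(gaze)

  # distance to each AOI's center of the aligned frame, vectorised
  d2 <- matrix(Inf, n, 4L, dimnames = list(NULL, config$tie_order))
  for (aoi in config$tie_order) {
    cx <- centers[[paste0(aoi, "_x")]][idx]
    cy <- centers[[paste0(aoi, "_y")]][idx]
    d2[, aoi] <- (cx - gaze$x)^2 + (cy - gaze$y)^2
  }
  missing <- !as.logical(gaze$valid) | !as.logical(centers$valid[idx])
  d2[missing, ] <- 0  # placeholder; overwritten below

  k <- max.col(-d2, ties.method = "first")
  dmin2 <- d2[cbind(seq_len(n), k)]
  inside <- if (config$boundary_inclusive) dmin2 <= radius_px^2
            else dmin2 < radius_px^2
  label <- ifelse(inside, config$tie_order[k], NON_LABEL)
  label[missing] <- MISSING_LABEL

  new_label_stream(time = gaze$time, frame = al$frame, label = label,
                   sampling_rate = attr(gaze, "sampling_rate"))
}
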