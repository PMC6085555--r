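# File formats. All files are comma-separated with a mandatory header row,
# period decimal point, and the literal token NaN as the missing-value
# sentinel. Landmark numbering in memory is always the 1-based 1..68 scheme
# (the one AOI definitions cite); the reader translates detector CSVs whose
# columns are 0-based.

LANDMARK_META_COLS <- c("frame", "timestamp", "confidence", "success")

landmark_file_cols <- function(dialect) {
  idx <- if (dialect == "zero_based_columns") 0:67 else 1:68
  list(x = paste0("x_", idx), y = paste0("y_", idx))
}

landmark_mem_cols <- function() {
  list(x = paste0("x_", 1:68), y = paste0("y_", 1:68))
}

read_table_checked <- function(path) {
  if (!file.exists(path)) {
    aoi_error("io_failure", sprintf("file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) aoi_error("empty_file",
                                  sprintf("cannot parse %s: %s", path,
                                          conditionMessage(e)))
  )
  if (nrow(df) == 0L) {
    aoi_error("empty_file", sprintf("no data rows in %s", path))
  }
  df
}

require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    aoi_error("malformed_header",
              sprintf("%s: missing column(s) %s", path,
                      paste(utils::head(miss, 5L), collapse = ", ")))
  }
}

#' Read and write 68-point facial-landmark tracks
#'
#' A landmark track is the per-frame output of a 68-point facial-landmark
#' detector: columns `frame`, `timestamp`, `confidence`, `success`, then 68
#' x-coordinate and 68 y-coordinate columns in pixels. Two header dialects
#' exist in the wild: `zero_based_columns` names them `x_0..x_67`/`y_0..y_67`
#' (landmark k of the 1-based scheme lives in column `x_{k-1}`), while
#' `one_based_columns` names them `x_1..x_68`/`y_1..y_68`. In memory the
#' track always uses the 1-based numbering, so e.g. the nose tip is columns
#' `x_31`/`y_31` regardless of dialect.
#'
#' @param path Path to a CSV file.
#' @param dialect Column-naming dialect of the file.
#' @param frame_rate Video frame rate in Hz; estimated as 1 / median
#'   inter-frame interval when `NULL`.
#' @param source_id Identifier stored with the track (defaults to the file
#'   name).
#' @return A `landmark_track`: a data frame with columns `frame`,
#'   `timestamp`, `confidence`, `success`, `x_1..x_68`, `y_1..y_68` and
#'   attributes `frame_rate` and `source_id`.
#' @export
read_landmark_track <- function(path,
                                dialect = c("zero_based_columns",
                                            "one_based_columns"),
                                frame_rate = NULL,
                                source_id = basename(path)) {
  dialect <- match.arg(dialect)
  df <- read_table_checked(path)
  fc <- landmark_file_cols(dialect)
  require_cols(df, c(LANDMARK_META_COLS, fc$x, fc$y), path)
  extra <- grep("^[xy]_[0-9]+$", names(df), value = TRUE)
  extra <- setdiff(extra, c(fc$x, fc$y))
  if (length(extra)) {
    aoi_error("malformed_header",
              sprintf("%s: unexpected landmark column(s) %s", path,
                      paste(utils::head(extra, 5L), collapse = ", ")))
  }
  check_monotonic(df$timestamp)
  mem <- landmark_mem_cols()
  out <- data.frame(
    frame = as.integer(df$frame),
    timestamp = as.numeric(df$timestamp),
    confidence = as.numeric(df$confidence),
    success = as.logical(df$success)
  )
  out[mem$x] <- lapply(df[fc$x], as.numeric)
  out[mem$y] <- lapply(df[fc$y], as.numeric)
  new_landmark_track(out,
                     frame_rate = frame_rate %||% estimate_rate(out$timestamp),
                     source_id = source_id)
}

new_landmark_track <- function(df, frame_rate, source_id = "") {
  if (!identical(df$frame, seq_len(nrow(df)) - 1L)) {
    aoi_error("malformed_header",
              "frame indices must be contiguous from 0")
  }
  if (!is.na(frame_rate) && frame_rate <= 0) {
    aoi_error("domain_error", "frame_rate must be > 0")
  }
  structure(df, frame_rate = frame_rate, source_id = source_id,
            class = c("landmark_track", "data.frame"))
}

#' @rdname read_landmark_track
#' @param track A `landmark_track`.
#' @export
write_landmark_track <- function(track, path,
                                 dialect = c("zero_based_columns",
                                             "one_based_columns")) {
  dialect <- match.arg(dialect)
  fc <- landmark_file_cols(dialect)
  mem <- landmark_mem_cols()
  out <- track[, LANDMARK_META_COLS, drop = FALSE]
  out$success <- as.integer(track$success)
  out[fc$x] <- track[mem$x]
  out[fc$y] <- track[mem$y]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 68 x 2 matrix of landmark coordinates for one frame (row of a track).
landmark_points <- function(track, i) {
  mem <- landmark_mem_cols()
  cbind(x = as.numeric(track[i, mem$x]), y = as.numeric(track[i, mem$y]))
}

#' Read and write gaze recordings
#'
#' A gaze recording is a timestamped stream of screen coordinates: CSV
#' columns `time` (seconds, strictly increasing), `x`, `y` (pixels) and
#' `valid` (0/1). Invalid samples may hold any coordinate and never
#' influence downstream metrics.
#'
#' @param path Path to a CSV file.
#' @param sampling_rate Sampling rate in Hz; estimated as 1 / median
#'   inter-sample interval when `NULL`.
#' @return A `gaze_recording`: data frame with columns `time`, `x`, `y`,
#'   `valid` and attribute `sampling_rate`.
#' @export
read_gaze_recording <- function(path, sampling_rate = NULL) {
  df <- read_table_checked(path)
  require_cols(df, c("time", "x", "y", "valid"), path)
  check_monotonic(df$time, "time")
  new_gaze_recording(
    time = as.numeric(df$time), x = as.numeric(df$x), y = as.numeric(df$y),
    valid = as.logical(df$valid),
    sampling_rate = sampling_rate %||% estimate_rate(df$time)
  )
}

new_gaze_recording <- function(time, x, y, valid, sampling_rate) {
  df <- data.frame(time = time, x = x, y = y, valid = valid)
  structure(df, sampling_rate = sampling_rate,
            class = c("gaze_recording", "data.frame"))
}

#' @rdname read_gaze_recording
#' @param gaze A `gaze_recording`.
#' @export
write_gaze_recording <- function(gaze, path) {
  out <- data.frame(time = gaze$time, x = gaze$x, y = gaze$y,
                    valid = as.integer(gaze$valid))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

center_track_cols <- function() c("frame", "timestamp", "valid", center_cols())

#' Read and write AOI-center tracks
#'
#' An AOI-center track holds, for every video frame, the (x, y) cell center
#' of each facial AOI: CSV columns `frame`, `timestamp`, `valid`, then
#' `left_eye_x`, `left_eye_y`, `right_eye_x`, `right_eye_y`, `nose_x`,
#' `nose_y`, `mouth_x`, `mouth_y`, plus an optional `carried` column marking
#' frames whose centers were carried forward over a detector dropout.
#' Missing centers are written as the token `NaN` with `valid = 0`.
#'
#' @param track An `aoi_center_track`.
#' @param path Path to a CSV file.
#' @return `read_center_track()` returns an `aoi_center_track` data frame
#'   with attribute `frame_rate`.
#' @export
write_center_track <- function(track, path) {
  out <- track[, center_track_cols(), drop = FALSE]
  out$valid <- as.integer(track$valid)
  out$carried <- as.integer(track$carried %||% rep(FALSE, nrow(track)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   na = "NaN")  # missing-center sentinel is the token NaN
  invisible(path)
}

#' @rdname write_center_track
#' @param frame_rate Frame rate in Hz; estimated from timestamps when `NULL`.
#' @export
read_center_track <- function(path, frame_rate = NULL) {
  df <- read_table_checked(path)
  require_cols(df, center_track_cols(), path)
  check_monotonic(df$timestamp)
  out <- data.frame(frame = as.integer(df$frame),
                    timestamp = as.numeric(df$timestamp),
                    valid = as.logical(df$valid))
  for (col in center_cols()) out[[col]] <- as.numeric(df[[col]])
  out$carried <- if ("carried" %in% names(df)) as.logical(df$carried)
                 else rep(FALSE, nrow(df))
  new_center_track(out, frame_rate %||% estimate_rate(out$timestamp))
}

new_center_track <- function(df, frame_rate) {
  structure(df, frame_rate = frame_rate,
            class = c("aoi_center_track", "data.frame"))
}

#' Read and write AOI label streams
#'
#' Per-gaze-sample AOI labels: CSV columns `time` (seconds), `frame` (the
#' video frame the sample was aligned to) and `label`, one of
#' `r paste(stream_labels(), collapse = ", ")`.
#'
#' @param stream An `aoi_label_stream`.
#' @param path Path to a CSV file.
#' @param sampling_rate Sampling rate in Hz; estimated when `NULL`.
#' @export
write_label_stream <- function(stream, path) {
  utils::write.csv(
    data.frame(time = stream$time, frame = stream$frame,
               label = stream$label),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_label_stream
#' @export
read_label_stream <- function(path, sampling_rate = NULL) {
  df <- read_table_checked(path)
  require_cols(df, c("time", "frame", "label"), path)
  check_monotonic(df$time, "time")
  bad <- setdiff(unique(df$label), STREAM_LABELS)
  if (length(bad)) {
    aoi_error("malformed_header",
              sprintf("%s: unknown label(s) %s", path,
                      paste(bad, collapse = ", ")))
  }
  new_label_stream(time = as.numeric(df$time), frame = as.integer(df$frame),
                   label = as.character(df$label),
                   sampling_rate = sampling_rate %||% estimate_rate(df$time))
}

new_label_stream <- function(time, frame, label, sampling_rate) {
  structure(data.frame(time = time, frame = frame, label = label),
            sampling_rate = sampling_rate,
            class = c("aoi_label_stream", "data.frame"))
}

#' Read and write summary tables
#'
#' Thin wrappers fixing the CSV dialect (comma, period decimal, header row)
#' for dwell, paired-gaze and validation summary tables.
#'
#' @param df A data frame.
#' @param path Path to a CSV file.
#' @export
write_summary_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  read_table_checked(path)
}
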