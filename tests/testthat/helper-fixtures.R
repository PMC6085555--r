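# Shared fixture builders. Everything is constructed in code; no files on
# disk beyond tempfiles created per test.

# Label stream at a fixed rate starting at t = 0.
make_label_stream <- function(labels, rate = 10) {
  n <- length(labels)
  faceAOI:::new_label_stream(time = (seq_len(n) - 1) / rate,
                             frame = seq_len(n) - 1L,
                             label = labels, sampling_rate = rate)
}

# Center track with per-frame coordinates supplied as a named list of
# 2-column matrices (or single c(x, y) recycled over frames).
make_center_track <- function(n, centers, rate = 25,
                              valid = rep(TRUE, n)) {
  df <- data.frame(frame = seq_len(n) - 1L,
                   timestamp = (seq_len(n) - 1) / rate, valid = valid)
  for (aoi in names(centers)) {
    m <- centers[[aoi]]
    if (is.null(dim(m))) m <- matrix(m, n, 2, byrow = TRUE)
    df[[paste0(aoi, "_x")]] <- m[, 1]
    df[[paste0(aoi, "_y")]] <- m[, 2]
  }
  df$carried <- FALSE
  faceAOI:::new_center_track(df, rate)
}

# The four well-separated reference centers used across LRVT tests.
demo_centers <- function() {
  list(left_eye = c(100, 100), right_eye = c(200, 100),
       nose = c(150, 160), mouth = c(150, 220))
}

# Gaze recording from explicit coordinates.
make_gaze <- function(x, y, rate = 100, valid = rep(TRUE, length(x))) {
  n <- length(x)
  faceAOI:::new_gaze_recording((seq_len(n) - 1) / rate, x, y, valid, rate)
}

# Small landmark-track data frame (in-memory, 1-based columns) with all 68
# landmarks at simple deterministic positions.
make_landmark_df <- function(n = 3, rate = 25, success = rep(TRUE, n)) {
  df <- data.frame(frame = seq_len(n) - 1L,
                   timestamp = (seq_len(n) - 1) / rate,
                   confidence = rep(0.9, n), success = success)
  for (k in 1:68) {
    df[[paste0("x_", k)]] <- 100 + k + (seq_len(n) - 1)
    df[[paste0("y_", k)]] <- 200 + 2 * k + (seq_len(n) - 1)
  }
  df
}

make_landmark_track <- function(n = 3, rate = 25,
                                success = rep(TRUE, n)) {
  faceAOI:::new_landmark_track(make_landmark_df(n, rate, success),
                               frame_rate = rate, source_id = "fixture")
}

# Reference screen: 22-inch 1680x1050, 47.38x29.61 cm, width 32.61 deg.
ref_geometry <- function() {
  screen_geometry(1680, 1050, 47.38, 29.61, width_deg = 32.61)
}
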