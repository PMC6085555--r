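# Synthetic landmark tracks, gaze recordings and dyads with known ground
# truth, so the whole pipeline can be tested end to end without any video.

#' Template 68-point face layout
#'
#' A hard-coded, anatomically plausible 68-landmark layout (standard
#' numbering: jaw 1-17, eyebrows 18-27, nose 28-36, eyes 37-48, outer lip
#' 49-60, inner lip 61-68) spanning roughly 310 x 390 px, anchored by the
#' nose tip (landmark 31) at `center`. Image coordinates: x rightward,
#' y downward. The derived AOI centers sit at the eyes (+-98, -128), nose
#' (0, 0) and mouth (0, +106) relative to the nose tip (before scaling).
#'
#' @param center `c(x, y)` position of the nose tip in pixels.
#' @param scale Isotropic scale factor (1 = default face size; larger
#'   values emulate a closer camera).
#' @return A 68 x 2 matrix with columns `x`, `y`.
#' @export
face_template <- function(center = c(840, 525), scale = 1) {
  sx <- 1.4 * scale
  sy <- 1.6 * scale
  t_jaw <- seq(pi, 0, length.out = 17)
  jaw <- cbind(110 * cos(t_jaw), -40 + 170 * sin(t_jaw))
  brow_x <- seq(-85, -35, length.out = 5)
  brow_y <- -105 - c(0, 6, 9, 6, 0)
  l_brow <- cbind(brow_x, brow_y)
  r_brow <- cbind(-rev(brow_x), rev(brow_y))
  bridge <- cbind(rep(0, 4), c(-80, -55, -28, 0))
  nostrils <- cbind(c(-22, -11, 0, 11, 22), rep(12, 5))
  l_eye <- cbind(c(-88, -77, -63, -52, -63, -77),
                 c(-80, -87, -87, -80, -73, -73))
  r_eye <- cbind(-rev(l_eye[, 1]), rev(l_eye[, 2]))
  r_eye <- r_eye[c(4, 3, 2, 1, 6, 5), ]  # restore 43..48 ordering
  outer_lip <- cbind(c(-45, -30, -12, 0, 12, 30, 45, 30, 12, 0, -12, -30),
                     c(65, 55, 50, 48, 50, 55, 65, 78, 83, 85, 83, 78))
  inner_lip <- cbind(c(-35, -12, 0, 12, 35, 12, 0, -12),
                     c(65, 60, 58, 60, 65, 72, 74, 72))
  pts <- rbind(jaw, l_brow, r_brow, bridge, nostrils, l_eye, r_eye,
               outer_lip, inner_lip)
  pts[, 1] <- pts[, 1] * sx + center[1]
  pts[, 2] <- pts[, 2] * sy + center[2]
  colnames(pts) <- c("x", "y")
  pts
}

#' Configuration for simulated landmark tracks
#'
#' The simulated face translates rigidly along a per-axis sinusoid (smooth
#' head motion), each landmark receives i.i.d. Gaussian jitter (detector
#' noise), and scheduled blinks displace the eye landmarks (37-48)
#' downward and inward — toward the face midline — by `blink_offset` for
#' the duration of the blink.
#'
#' @param n_frames Number of video frames.
#' @param frame_rate Frame rate in Hz.
#' @param base_landmarks 68 x 2 matrix, e.g. [face_template()].
#' @param motion_amp_px Sinusoid amplitude in px, `c(x, y)`.
#' @param motion_period_s Sinusoid period in s, `c(x, y)`.
#' @param jitter_sd Per-landmark Gaussian jitter SD in px.
#' @param blink_schedule List of `c(start_frame, duration_frames)`
#'   (0-based start), each window fully inside the track.
#' @param blink_offset `c(dx, dy)`: dx px toward the face midline, dy px
#'   downward.
#' @param seed Integer seed; equal seeds give bit-identical tracks.
#' @return A `face_sim_config` list.
#' @export
face_sim_config <- function(n_frames = 250L, frame_rate = 25,
                            base_landmarks = face_template(),
                            motion_amp_px = c(20, 10),
                            motion_period_s = c(4, 3),
                            jitter_sd = 0.5,
                            blink_schedule = list(),
                            blink_offset = c(4, 10),
                            seed = 1L) {
  if (n_frames < 1L || frame_rate <= 0 ||
      any(motion_amp_px < 0) || jitter_sd < 0 ||
      !all(dim(base_landmarks) == c(68L, 2L))) {
    aoi_error("invalid_config", "invalid face simulation config")
  }
  for (b in blink_schedule) {
    if (b[1] < 0 || b[2] < 1 || b[1] + b[2] > n_frames) {
      aoi_error("invalid_config", "blink window outside the track")
    }
  }
  structure(list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 base_landmarks = base_landmarks,
                 motion_amp_px = motion_amp_px,
                 motion_period_s = motion_period_s,
                 jitter_sd = jitter_sd, blink_schedule = blink_schedule,
                 blink_offset = blink_offset, seed = as.integer(seed)),
            class = "face_sim_config")
}

#' Simulate a landmark track with known ground-truth AOI centers
#'
#' @param cfg A [face_sim_config()].
#' @param definition An [aoi_definition()] used for the ground truth.
#' @return A list: `track` (a `landmark_track`, all frames successful) and
#'   `truth` (an `aoi_center_track` computed from the noiseless,
#'   blink-free trajectory).
#' @export
generate_landmark_track <- function(cfg, definition = aoi_definition()) {
  n <- cfg$n_frames
  t <- (seq_len(n) - 1L) / cfg$frame_rate
  shift_x <- cfg$motion_amp_px[1] * sin(2 * pi * t / cfg$motion_period_s[1])
  shift_y <- cfg$motion_amp_px[2] * sin(2 * pi * t / cfg$motion_period_s[2])

  base <- cfg$base_landmarks
  xs <- outer(shift_x, base[, 1], `+`)  # n x 68
  ys <- outer(shift_y, base[, 2], `+`)

  withr::with_seed(cfg$seed, {
    xs <- xs + matrix(stats::rnorm(n * 68L, sd = cfg$jitter_sd), n, 68L)
    ys <- ys + matrix(stats::rnorm(n * 68L, sd = cfg$jitter_sd), n, 68L)
  })

  midline_x <- mean(base[c(37:48), 1])  # face midline between the eyes
  for (b in cfg$blink_schedule) {
    rows <- (b[1] + 1L):(b[1] + b[2])
    for (k in 37:48) {
      toward <- sign(midline_x - base[k, 1])  # inward: toward the midline
      xs[rows, k] <- xs[rows, k] + toward * cfg$blink_offset[1]
      ys[rows, k] <- ys[rows, k] + cfg$blink_offset[2]  # downward: +y
    }
  }

  df <- data.frame(frame = seq_len(n) - 1L, timestamp = t,
                   confidence = rep(0.98, n), success = rep(TRUE, n))
  df[paste0("x_", 1:68)] <- as.data.frame(xs)
  df[paste0("y_", 1:68)] <- as.data.frame(ys)
  track <- new_landmark_track(df, frame_rate = cfg$frame_rate,
                              source_id = "simulated")

  truth <- data.frame(frame = df$frame, timestamp = t,
                      valid = rep(TRUE, n))
  for (aoi in names(definition)) {
    pts <- definition[[aoi]]
    truth[[paste0(aoi, "_x")]] <- mean(base[pts, 1]) + shift_x
    truth[[paste0(aoi, "_y")]] <- mean(base[pts, 2]) + shift_y
  }
  truth$carried <- FALSE
  list(track = track,
       truth = new_center_track(truth, cfg$frame_rate))
}

#' Configuration for simulated gaze recordings
#'
#' Gaze follows a dwell schedule: for each entry the simulated observer
#' fixates the named AOI's current (per-frame) cell center — or, for the
#' entry `"non"`, a fixed off-face point — for the stated duration, plus
#' isotropic Gaussian noise. Samples are dropped (marked invalid)
#' independently with probability `p_missing`.
#'
#' @param schedule Data frame with columns `label` (an AOI label or
#'   `"non"`) and `duration_s` (> 0).
#' @param noise_sd Gaze noise SD in px.
#' @param sampling_rate Gaze sampling rate in Hz.
#' @param p_missing Per-sample missingness probability in `[0, 1)`.
#' @param off_face_point `c(x, y)` target for `"non"` entries; must lie
#'   farther than the LRVT radius from every center for the truth labels
#'   to be recoverable. The default, the screen's top-left region, is far
#'   from any screen-centred face.
#' @param seed Integer seed.
#' @return A `gaze_sim_config` list.
#' @export
gaze_sim_config <- function(schedule, noise_sd = 0, sampling_rate = 100,
                            p_missing = 0, off_face_point = c(50, 50),
                            seed = 1L) {
  if (!all(c("label", "duration_s") %in% names(schedule)) ||
      any(schedule$duration_s <= 0) ||
      !all(schedule$label %in% c(AOI_LABELS, NON_LABEL)) ||
      noise_sd < 0 || sampling_rate <= 0 ||
      p_missing < 0 || p_missing >= 1) {
    aoi_error("invalid_config", "invalid gaze simulation config")
  }
  structure(list(schedule = schedule, noise_sd = noise_sd,
                 sampling_rate = sampling_rate, p_missing = p_missing,
                 off_face_point = off_face_point, seed = as.integer(seed)),
            class = "gaze_sim_config")
}

#' Simulate a gaze recording targeting a center track
#'
#' @param cfg A [gaze_sim_config()].
#' @param centers An `aoi_center_track` to target.
#' @param frame_rate Video frame rate; defaults to the center track's.
#' @param offset Gaze-to-video clock offset in seconds.
#' @return A list: `gaze` (a `gaze_recording`) and `truth` (an
#'   `aoi_label_stream` of the scheduled labels; injected-missing samples
#'   are labelled `"missing"`).
#' @export
generate_gaze <- function(cfg, centers, frame_rate = NULL, offset = 0) {
  frame_rate <- frame_rate %||% attr(centers, "frame_rate")
  total_s <- sum(cfg$schedule$duration_s)
  track_s <- nrow(centers) / frame_rate
  if (total_s > track_s + 1e-9) {
    aoi_error("schedule_overflow",
              sprintf("schedule (%.3f s) exceeds the track (%.3f s)",
                      total_s, track_s))
  }
  dt <- 1 / cfg$sampling_rate
  # per-segment sample counts (exact when durations are multiples of dt)
  n_per <- round(cfg$schedule$duration_s * cfg$sampling_rate)
  n <- sum(n_per)
  t <- (seq_len(n) - 1L) * dt
  truth_label <- rep(cfg$schedule$label, n_per)

  al <- align_to_frames(t, frame_rate, offset, n_frames = nrow(centers))
  idx <- al$frame + 1L
  tx <- numeric(n)
  ty <- numeric(n)
  off <- truth_label == NON_LABEL
  tx[off] <- cfg$off_face_point[1]
  ty[off] <- cfg$off_face_point[2]
  for (aoi in AOI_LABELS) {
    sel <- truth_label == aoi
    tx[sel] <- centers[[paste0(aoi, "_x")]][idx[sel]]
    ty[sel] <- centers[[paste0(aoi, "_y")]][idx[sel]]
  }

  withr::with_seed(cfg$seed, {
    gx <- tx + stats::rnorm(n, sd = cfg$noise_sd)
    gy <- ty + stats::rnorm(n, sd = cfg$noise_sd)
    valid <- stats::runif(n) >= cfg$p_missing
  })
  truth_label[!valid] <- MISSING_LABEL

  list(gaze = new_gaze_recording(t, gx, gy, valid, cfg$sampling_rate),
       truth = new_label_stream(t, al$frame, truth_label,
                                cfg$sampling_rate))
}

#' Simulate a dyad with a shared paired-gaze schedule
#'
#' Builds two participants' faces and gaze from one schedule of paired
#' states: during `two_way` both participants fixate their partner's left
#' eye; during `one_way` participant A fixates the eyes while B fixates
#' the nose; during `no_eye_gaze` A fixates the nose and B the mouth.
#'
#' @param mutual_schedule Data frame with columns `state` (one of
#'   `two_way`, `one_way`, `no_eye_gaze`) and `duration_s`.
#' @param face_a,face_b [face_sim_config()]s for the two faces.
#' @param noise_sd,sampling_rate,p_missing,seed Passed to the two
#'   [gaze_sim_config()]s (participant seeds are derived as `seed + 1` and
#'   `seed + 2`).
#' @return A list with `gaze_a`, `gaze_b` (`gaze_recording`s), `centers_a`,
#'   `centers_b` (`aoi_center_track`s, ground truth), `truth_labels_a/b`
#'   and `truth_paired` (a `paired_gaze_stream` of the scheduled states;
#'   samples where either participant is missing are `undefined`).
#' @export
generate_dyad <- function(mutual_schedule,
                          face_a = face_sim_config(seed = 11L),
                          face_b = face_sim_config(seed = 12L),
                          noise_sd = 0, sampling_rate = 100,
                          p_missing = 0, seed = 1L) {
  if (!all(mutual_schedule$state %in%
           c("two_way", "one_way", "no_eye_gaze"))) {
    aoi_error("schedule_mismatch", "unknown paired state in schedule")
  }
  tgt <- list(two_way = c(a = "left_eye", b = "left_eye"),
              one_way = c(a = "left_eye", b = "nose"),
              no_eye_gaze = c(a = "nose", b = "mouth"))
  sched <- function(who) {
    data.frame(
      label = vapply(mutual_schedule$state, function(s) tgt[[s]][[who]], ""),
      duration_s = mutual_schedule$duration_s
    )
  }
  sim_a <- generate_landmark_track(face_a)
  sim_b <- generate_landmark_track(face_b)
  ga <- generate_gaze(
    gaze_sim_config(sched("a"), noise_sd, sampling_rate, p_missing,
                    seed = seed + 1L),
    sim_b$truth)  # A looks at B's face and vice versa
  gb <- generate_gaze(
    gaze_sim_config(sched("b"), noise_sd, sampling_rate, p_missing,
                    seed = seed + 2L),
    sim_a$truth)

  state <- classify_state(ga$truth$label, gb$truth$label)
  truth_paired <- structure(
    data.frame(time = ga$truth$time, state = state),
    sampling_rate = sampling_rate,
    class = c("paired_gaze_stream", "data.frame"))

  list(gaze_a = ga$gaze, gaze_b = gb$gaze,
       centers_a = sim_a$truth, centers_b = sim_b$truth,
       landmarks_a = sim_a$track, landmarks_b = sim_b$track,
       truth_labels_a = ga$truth, truth_labels_b = gb$truth,
       truth_paired = truth_paired)
}
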