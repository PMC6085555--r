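test_that("equal seeds give bit-identical simulated tracks", {
  cfg <- face_sim_config(n_frames = 40, seed = 99,
                         blink_schedule = list(c(10, 2)))
  s1 <- generate_landmark_track(cfg)
  s2 <- generate_landmark_track(cfg)
  expect_identical(as.data.frame(s1$track), as.data.frame(s2$track))
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  s3 <- generate_landmark_track(face_sim_config(n_frames = 40, seed = 100))
  expect_false(identical(as.data.frame(s1$track), as.data.frame(s3$track)))
})

test_that("a motionless, noiseless, blink-free face has constant true centers", {
  sim <- generate_landmark_track(face_sim_config(
    n_frames = 20, motion_amp_px = c(0, 0), jitter_sd = 0))
  ct <- derive_center_track(sim$track)
  for (col in faceAOI:::center_cols()) {
    expect_equal(diff(range(ct[[col]])), 0)
    expect_equal(ct[[col]], sim$truth[[col]], tolerance = 1e-12)
  }
  # template-derived: nose center equals landmark 31 of the template
  tmpl <- face_template()
  expect_equal(ct$nose_x[1], unname(tmpl[31, "x"]))
  expect_equal(ct$nose_y[1], unname(tmpl[31, "y"]))
})

test_that("blinks displace eye centers by exactly the configured offset", {
  sim <- generate_landmark_track(face_sim_config(
    n_frames = 30, motion_amp_px = c(0, 0), jitter_sd = 0,
    blink_schedule = list(c(10, 3)), blink_offset = c(4, 10)))
  ct <- derive_center_track(sim$track)
  blink <- 11:13  # frames 10..12, 1-based rows
  # downward (+y) on both eyes
  expect_equal(ct$left_eye_y[blink] - sim$truth$left_eye_y[blink],
               rep(10, 3))
  expect_equal(ct$right_eye_y[blink] - sim$truth$right_eye_y[blink],
               rep(10, 3))
  # inward: the image-left eye moves right, the image-right eye moves left
  expect_equal(ct$left_eye_x[blink] - sim$truth$left_eye_x[blink],
               rep(4, 3))
  expect_equal(ct$right_eye_x[blink] - sim$truth$right_eye_x[blink],
               rep(-4, 3))
  # nose and mouth are untouched
  expect_equal(ct$nose_y, sim$truth$nose_y, tolerance = 1e-12)
  expect_equal(ct$mouth_y, sim$truth$mouth_y, tolerance = 1e-12)
})

test_that("invalid simulation configs are rejected", {
  expect_error(face_sim_config(n_frames = 0),
               class = "faceAOI_invalid_config")
  expect_error(face_sim_config(n_frames = 10,
                               blink_schedule = list(c(8, 5))),
               class = "faceAOI_invalid_config")
  expect_error(gaze_sim_config(data.frame(label = "eyebrow",
                                          duration_s = 1)),
               class = "faceAOI_invalid_config")
  expect_error(gaze_sim_config(data.frame(label = "nose",
                                          duration_s = 1),
                               p_missing = 1),
               class = "faceAOI_invalid_config")
})

test_that("noiseless scheduled gaze is recovered exactly by assignment", {
  geom <- ref_geometry()
  sim <- generate_landmark_track(face_sim_config(n_frames = 200,
                                                 jitter_sd = 0))
  sched <- data.frame(label = c("left_eye", "nose", "non", "mouth",
                                "right_eye"),
                      duration_s = c(2, 1.5, 1, 2, 1.5))
  g <- generate_gaze(gaze_sim_config(sched), sim$truth)
  ls <- assign_stream(g$gaze, sim$truth, lrvt_config(), geom)
  expect_identical(ls$label, g$truth$label)
})

test_that("labels stay accurate when gaze noise is small versus the radius", {
  geom <- ref_geometry()
  radius_px <- deg_to_px(4, geom)
  # close-up face: Voronoi boundaries sit far from the targets in noise SDs
  face <- face_sim_config(n_frames = 300,
                          base_landmarks = face_template(scale = 1.6),
                          jitter_sd = 0)
  sim <- generate_landmark_track(face)
  sched <- data.frame(label = c("left_eye", "nose", "mouth", "right_eye"),
                      duration_s = c(3, 3, 3, 3))
  g <- generate_gaze(gaze_sim_config(sched, noise_sd = radius_px / 10,
                                     seed = 7),
                     sim$truth)
  ls <- assign_stream(g$gaze, sim$truth, lrvt_config(), geom)
  expect_gte(mean(ls$label == g$truth$label), 0.99)
})

test_that("missingness is injected at close to the requested rate", {
  sim <- generate_landmark_track(face_sim_config(n_frames = 300,
                                                 jitter_sd = 0))
  sched <- data.frame(label = "nose", duration_s = 10)
  g <- generate_gaze(gaze_sim_config(sched, p_missing = 0.1, seed = 3),
                     sim$truth)
  n <- nrow(g$gaze)
  frac <- mean(!g$gaze$valid)
  sd3 <- 3 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), sd3)
  expect_true(all(g$truth$label[!g$gaze$valid] == "missing"))
})

test_that("a schedule longer than the track raises schedule_overflow", {
  sim <- generate_landmark_track(face_sim_config(n_frames = 25))
  expect_error(
    generate_gaze(gaze_sim_config(data.frame(label = "nose",
                                             duration_s = 100)),
                  sim$truth),
    class = "faceAOI_schedule_overflow")
})

test_that("a zero-noise dyad reproduces its paired-state schedule exactly", {
  sched <- data.frame(state = c("two_way", "one_way", "no_eye_gaze"),
                      duration_s = c(2, 1, 1))
  dy <- generate_dyad(sched,
                      face_a = face_sim_config(n_frames = 120, seed = 1),
                      face_b = face_sim_config(n_frames = 120, seed = 2))
  sm <- summarize_states(dy$truth_paired)
  tot <- function(s) sm$total_time_s[sm$state == s]
  expect_equal(tot("two_way"), 2)
  expect_equal(tot("one_way"), 1)
  expect_equal(tot("no_eye_gaze"), 1)
  # an all-two_way schedule is a single episode
  dy2 <- generate_dyad(data.frame(state = "two_way", duration_s = 3),
                       face_a = face_sim_config(n_frames = 120, seed = 1),
                       face_b = face_sim_config(n_frames = 120, seed = 2))
  sm2 <- summarize_states(dy2$truth_paired)
  expect_equal(sm2$n_episodes[sm2$state == "two_way"], 1L)
  expect_equal(sm2$mean_episode_s[sm2$state == "two_way"],
               sm2$total_time_s[sm2$state == "two_way"])
  # swapping the participants' label streams leaves the totals unchanged
  swapped <- classify_state(dy$truth_labels_b$label,
                            dy$truth_labels_a$label)
  expect_identical(swapped, dy$truth_paired$state)
  expect_error(generate_dyad(data.frame(state = "mutual", duration_s = 1)),
               class = "faceAOI_schedule_mismatch")
})
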