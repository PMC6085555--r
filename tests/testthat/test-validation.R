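two_tracks <- function(n = 20, shift = 0) {
  a <- make_center_track(n, demo_centers())
  b <- a
  if (shift != 0) {
    for (col in faceAOI:::center_cols()) b[[col]] <- b[[col]] + shift
  }
  list(a = a, b = b)
}

test_that("identical tracks have zero mean and max absolute difference", {
  tr <- two_tracks()
  expect_true(all(mean_abs_diff(tr$a, tr$b)$value == 0))
  expect_true(all(max_abs_diff(tr$a, tr$b)$value == 0))
})

test_that("mean and max absolute differences match hand-computed values", {
  a <- make_center_track(2, demo_centers())
  b <- a
  a$nose_x <- c(0, 2)
  b$nose_x <- c(1, 1)
  m <- mean_abs_diff(a, b)
  expect_equal(m$value[m$aoi == "nose" & m$axis == "x"], 1)  # (1 + 1)/2

  a4 <- make_center_track(4, demo_centers())
  b4 <- a4
  a4$left_eye_x <- b4$left_eye_x + c(0, 0, 7, 1)
  mx <- max_abs_diff(a4, b4)
  expect_equal(mx$value[mx$aoi == "left_eye" & mx$axis == "x"], 7)
})

test_that("difference statistics are symmetric and translation-invariant", {
  withr::with_seed(51, {
    a <- make_center_track(30, demo_centers())
    b <- a
    for (col in faceAOI:::center_cols()) {
      b[[col]] <- b[[col]] + rnorm(30, sd = 3)
    }
  })
  expect_equal(mean_abs_diff(a, b), mean_abs_diff(b, a))
  expect_equal(max_abs_diff(a, b), max_abs_diff(b, a))
  # max >= mean on every AOI/axis
  expect_true(all(max_abs_diff(a, b)$value >= mean_abs_diff(a, b)$value))
  # joint translation changes nothing
  a2 <- a; b2 <- b
  for (col in faceAOI:::center_cols()) {
    a2[[col]] <- a2[[col]] + 55
    b2[[col]] <- b2[[col]] + 55
  }
  expect_equal(mean_abs_diff(a2, b2), mean_abs_diff(a, b))
})

test_that("frames invalid in either track are excluded pairwise", {
  a <- make_center_track(4, demo_centers())
  b <- a
  a$nose_x <- c(0, 100, 0, 2)
  b$nose_x <- c(1, 0, 0, 1)
  a$valid[2] <- FALSE  # the 100-px outlier frame is ignored
  m <- mean_abs_diff(a, b)
  expect_equal(m$value[m$aoi == "nose" & m$axis == "x"], 2 / 3)
  expect_error(mean_abs_diff(a, make_center_track(3, demo_centers())),
               class = "faceAOI_length_mismatch")
  b$valid <- !a$valid
  expect_error(mean_abs_diff(a, b),
               class = "faceAOI_no_overlapping_valid_frames")
})

test_that("sample-to-sample RMS matches hand-computed sequences", {
  ct <- make_center_track(5, demo_centers())
  expect_true(all(rms_s2s(ct)$value == 0))  # constant track
  ct$nose_x <- c(0, 1, 0, 1, 0)
  r <- rms_s2s(ct)
  expect_equal(r$value[r$aoi == "nose" & r$axis == "x"], 1)
  ct3 <- make_center_track(3, demo_centers())
  ct3$nose_x <- c(0, 2, 0)
  r3 <- rms_s2s(ct3)
  expect_equal(r3$value[r3$aoi == "nose" & r3$axis == "x"], 2)  # sqrt(8/2)
  # about-mean variant measures spread, not jitter
  rm3 <- rms_s2s(ct3, method = "about_mean")
  expect_equal(rm3$value[rm3$aoi == "nose" & rm3$axis == "x"],
               sqrt(mean((c(0, 2, 0) - 2 / 3)^2)))
  expect_error(rms_s2s(make_center_track(3, demo_centers(),
                                         valid = c(TRUE, FALSE, TRUE))),
               class = "faceAOI_insufficient_data")
})

test_that("the Hampel detector flags isolated excursions and nothing else", {
  ct <- make_center_track(30, demo_centers())
  expect_false(any(detect_spikes(ct)))  # constant track
  ct$left_eye_y[12] <- ct$left_eye_y[12] + 15
  flags <- detect_spikes(ct, window = 7, n_mad = 3)
  expect_identical(which(flags), 12L)
  # slow linear drift stays below threshold
  drift <- make_center_track(50, demo_centers())
  for (col in faceAOI:::center_cols()) {
    drift[[col]] <- drift[[col]] + seq(0, 10, length.out = 50)
  }
  expect_false(any(detect_spikes(drift, window = 7, n_mad = 3)))
  # nose/mouth are not monitored by default
  ct2 <- make_center_track(30, demo_centers())
  ct2$nose_y[10] <- ct2$nose_y[10] + 50
  expect_false(any(detect_spikes(ct2)))
  expect_error(detect_spikes(ct, window = 4),
               class = "faceAOI_domain_error")
  expect_error(detect_spikes(make_center_track(3, demo_centers()),
                             window = 5),
               class = "faceAOI_window_too_large")
})

test_that("spike filtering restores the baseline and leaves the rest alone", {
  ct <- make_center_track(30, demo_centers())
  truth <- ct
  ct$left_eye_y[12] <- ct$left_eye_y[12] + 15
  ct$right_eye_x[20] <- ct$right_eye_x[20] - 9
  flags <- detect_spikes(ct)
  for (method in c("interpolate", "median_replace")) {
    fixed <- filter_spikes(ct, flags, method = method)
    expect_equal(as.data.frame(fixed), as.data.frame(truth))
  }
  # no flags -> identity
  expect_identical(as.data.frame(filter_spikes(ct, rep(FALSE, 30))),
                   as.data.frame(ct))
  # spikes at both ends extend from the nearest unflagged frame
  ct_end <- make_center_track(10, demo_centers())
  truth_end <- ct_end
  ct_end$left_eye_x[c(1, 10)] <- ct_end$left_eye_x[c(1, 10)] + 20
  fixed_end <- filter_spikes(ct_end, detect_spikes(ct_end, window = 5))
  expect_equal(as.data.frame(fixed_end), as.data.frame(truth_end))
  expect_error(filter_spikes(ct, rep(TRUE, 30)),
               class = "faceAOI_all_frames_flagged")
})

test_that("filtering injected blinks cannot increase sample-to-sample RMS", {
  sim <- generate_landmark_track(face_sim_config(
    n_frames = 100, jitter_sd = 0, motion_amp_px = c(0, 0),
    blink_schedule = list(c(20, 2), c(60, 3)), blink_offset = c(4, 10),
    seed = 5))
  ct <- derive_center_track(sim$track)
  flags <- detect_spikes(ct)
  fixed <- filter_spikes(ct, flags)
  r0 <- rms_s2s(ct)$value
  r1 <- rms_s2s(fixed)$value
  expect_true(all(r1 <= r0 + 1e-12))
})

test_that("the comparison report maps pixels through the screen geometry", {
  geom <- ref_geometry()
  withr::with_seed(61, {
    a <- make_center_track(20, demo_centers())
    b <- a
    for (col in faceAOI:::center_cols()) b[[col]] <- b[[col]] + rnorm(20)
  })
  rep_ <- track_comparison(a, b, geom)
  expect_equal(nrow(rep_), 8)
  i <- which(rep_$aoi == "nose" & rep_$axis == "y")
  expect_equal(rep_$mean_abs_diff_deg[i],
               px_to_deg(rep_$mean_abs_diff_px[i], geom, "vertical"))
  j <- which(rep_$aoi == "nose" & rep_$axis == "x")
  expect_equal(rep_$max_abs_diff_deg[j],
               px_to_deg(rep_$max_abs_diff_px[j], geom, "horizontal"))
})
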