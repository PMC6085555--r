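---
title: "Automatic face AOIs: method, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic face AOIs: method, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceAOI)
```

## The problem

Relating gaze behaviour to a *moving* face — a video stimulus, or the live
feed of a conversation partner — normally requires drawing Areas of
Interest (AOIs) on every video frame, a prohibitively slow manual task.
faceAOI automates the whole chain: a 68-point facial-landmark detector is
run on the video once (outside this package), and everything downstream —
per-frame AOI construction, gaze-to-AOI mapping, dwell and dyadic measures,
and quality statistics — is computed here, with no researcher input.

## From landmarks to AOI cell centers

Each facial AOI is represented by a single *cell center*: the arithmetic
mean of a fixed subset of the 68 standard landmarks.

| AOI       | landmarks | note                                   |
|-----------|-----------|----------------------------------------|
| left eye  | 37–42     | eye on the left of the *image*         |
| right eye | 43–48     |                                        |
| nose      | 31        | nose tip; center equals the landmark   |
| mouth     | 63, 67    | inner-lip midpoints; center of the mouth opening |

The coordinate convention is image-based: origin top-left, x rightward,
y downward, in pixels. "Left eye" is viewer perspective throughout — the
mirror-image of the anatomical left.

Frames where the detector reports failure get no centers of their own. The
default gap policy carries the last valid centers forward for up to
`max_gap_frames = 12` frames (about half a second at 25 fps), on the
grounds that landmark tracking usually recovers quickly and brief dropouts
should not destroy otherwise continuous dwells; longer dropouts become
missing. Detector confidence is *not* thresholded by default
(`min_confidence = 0`): only the success flag is honoured. Both choices are
exposed because neither is forced by the method itself.

## Limited-Radius Voronoi Tessellation (LRVT)

A gaze sample \((g_x, g_y)\) is assigned to the AOI whose cell center
\(c_i\) minimises the Euclidean distance \(\lVert g - c_i \rVert\),
*provided* that distance does not exceed a radius \(r\); otherwise the
sample belongs to the catch-all `non` AOI. Defaults:

* `radius_deg = 4` degrees of visual angle, converted to pixels once on
  the horizontal axis at screen center (the two axes' pixel pitches differ
  by well under a percent on typical screens, so no per-sample or per-axis
  correction is applied);
* the boundary is inclusive (distance exactly \(r\) is inside);
* exact distance ties — a measure-zero event — break deterministically in
  the order left eye, right eye, nose, mouth.

Invalid gaze samples, and samples whose video frame has missing centers,
are labelled `missing` and never touch any metric. Gaze on screen but off
the face is `non`, not missing: the distinction between "looked away" and
"no data" is preserved all the way into the dyadic measures.

Gaze-to-video alignment is `floor((t - offset) * frame_rate)` with a
configurable clock offset (default 0), since the synchronisation between
an eye tracker and a video feed is a property of the recording setup, not
of the method.

## Dwells and their measures

A *dwell* is a maximal run of identical non-missing labels. Durations use
the convention that each sample occupies one sample interval
(`1/sampling_rate`), so a one-sample dwell lasts one interval and total
dwell time over all labels plus missing time equals the recording duration
exactly — a conservation law the test suite checks. Per AOI the package
reports total dwell time (TDT), mean dwell time, and number of dwells,
plus a combined `eyes` AOI aggregating both eye AOIs (adjacent left/right
dwells merge into one `eyes` dwell, so combined TDT is additive while the
combined dwell count need not be).

Two robustness knobs exist but default to off, reflecting the reference
analysis: `gap_tolerance_s = 0` (no bridging of missing gaps inside a
dwell) and `min_dwell_s = 0` (no minimum dwell duration). The exact
onset/offset rules around missing data are not dictated by the method, so
they are documented here and kept configurable.

## Dyadic paired-gaze states

For two participants watching live video of each other, the two label
streams are joined by nearest timestamp onto the coarser stream's timeline
(tolerance: half the coarser sample interval) and classified per sample:

* `two_way` — both labels are an eye AOI;
* `one_way` — exactly one is;
* `no_eye_gaze` — neither is, both observed;
* `undefined` — either label is missing.

Missing data maps to `undefined` rather than `no_eye_gaze` because absence
of data is not evidence of looking away; it also keeps the conservation
law (state totals + undefined = session duration) exact. Episode counts
are reported both as raw counts and as episodes per minute, since
"frequency" is used both ways in the literature.

## Track validation statistics

To compare two center tracks of the same video (e.g. automatic vs an
independent reference), the package computes per AOI and axis the mean and
maximum absolute coordinate difference (the maximum corresponds to a
single frame), each in pixels and degrees. Temporal stability is the RMS
of *sample-to-sample* differences. An about-mean RMS is also implemented
(`method = "about_mean"`), but sample-to-sample is the default: the
statistic is meant to measure frame-to-frame jitter of the landmark
solution, and an about-mean RMS would be dominated by genuine head motion.

Pixel–degree conversion is tangent-exact,
\( \theta = 2\,\mathrm{atan}\!\left(\frac{\text{size}}{2d}\right) \),
not the small-angle approximation; the viewing distance can be inferred in
closed form from any known physical/angular extent pair of the screen.
For the reference screen used in the examples (22-inch, 1680×1050 px,
47.38×29.61 cm, 32.61° wide) this gives d ≈ 81 cm — an inference from the
printed extents, not a measured distance — and reproduces the screen's
20.72° vertical extent.

### Blink spikes

Eyelid closure drags the eye-landmark centroids downward and toward the
face midline for a few frames. The detector is a Hampel filter: a frame is
flagged when a monitored coordinate deviates from its rolling-window
median by more than `n_mad = 3` scaled MADs of that window
(`window = 7` frames). Only the eye AOIs are monitored by default — blinks
do not displace the nose or mouth. The window median resists a spike only
while the spike occupies under half the window, so the window should
exceed twice the longest expected blink; at 25 fps, window 7 covers blinks
up to ~120 ms, and longer windows can be configured for slower videos.
Repair is linear interpolation from the nearest unflagged frames (ends
extend), or a windowed median. The spike filter is **off by default** in
the pipeline: the blink excursion is part of the true landmark solution,
filtering it is an analysis choice, and the validation statistics are more
honest with it left in.

## The synthetic-data generator

Real interaction videos cannot be bundled, so every stage is exercised
against simulated data with known ground truth:

* a hard-coded, anatomically plausible 68-point template face
  (≈310×390 px; AOI centers at the eyes (±98, −128), nose (0, 0) and
  mouth (0, +106) relative to the nose tip), rigidly translated by a
  per-axis sinusoid (default ±20 px over 4 s horizontally, ±10 px over 3 s
  vertically — gentle conversational head motion at 25 fps) with i.i.d.
  per-landmark Gaussian jitter (default SD 0.5 px, the order of a good
  detector's frame-to-frame noise);
* blinks as rectangular displacement pulses on the eye landmarks (default
  4 px inward, 10 px downward) — enough to exercise spike detection,
  with no pretence of modelling eyelid kinematics;
* gaze that fixates a scheduled sequence of AOI centers (or an off-face
  point) at 100 Hz with isotropic Gaussian noise and i.i.d. missing
  samples; dyads are driven by a shared schedule of paired states.

All generators are deterministic under a fixed seed. What the simulation
does **not** emulate: facial deformation (expressions, talking), rotation
and scale changes of the head, correlated detector error, eye-tracker
drift and fixation dynamics. Passing the synthetic suites therefore shows
the *pipeline logic* is correct — assignment, segmentation, bookkeeping,
spike handling — not that any landmark detector is accurate on real video;
that question is one the validation module is designed to answer per
dataset, against a second track.

Two deliberate fixture choices: the zero-noise recovery checks use
schedules whose durations are multiples of the sample interval, so exact
equality is well-defined; and the label-accuracy check under noise uses a
1.6× close-up of the template so that every Voronoi boundary lies several
noise SDs (≥4 at noise = radius/10) from the fixated centers, making the
expected accuracy bound comfortably loose by construction. Problem sizes
throughout (hundreds of frames, 10⁴ samples or random configurations) were
chosen as the smallest at which the stochastic bounds are
sampling-error-proof.

## Worked example

```{r example, eval = FALSE}
geom <- screen_geometry(1680, 1050, 47.38, 29.61, width_deg = 32.61)
sim <- generate_landmark_track(face_sim_config(n_frames = 250, seed = 1))
sched <- data.frame(label = c("left_eye", "nose", "mouth", "non"),
                    duration_s = c(3, 2, 2, 1))
g <- generate_gaze(gaze_sim_config(sched, noise_sd = 5, seed = 2),
                   sim$truth)
centers <- derive_center_track(sim$track)
labels <- assign_stream(g$gaze, centers, lrvt_config(), geom)
summarize_dwells(segment_dwells(labels))
```

## Known limitations

* One face per video; frontal recordings assumed (no pose correction).
* The angular size of off-center extents uses the centered formula;
  eccentricity is ignored, consistent with single deg↔px equivalences.
* Dwell/paired-state timing is only as good as the gaze–video clock
  offset supplied; the package estimates nothing about synchronisation.
* The landmark detector itself is out of scope: the package starts at its
  CSV output.
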