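Package: faceAOI
Title: Automatic Areas of Interest for Videos of a Face in Eye-Tracking Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic Area-of-Interest (AOI) analysis for eye-tracking
    experiments that use videos of a face as the stimulus. Reads per-frame
    68-point facial-landmark tracks produced by landmark detectors, derives
    AOI cell centers for the left eye, right eye, nose and mouth by averaging
    fixed landmark subsets, assigns gaze samples to AOIs with the
    Limited-Radius Voronoi Tessellation (LRVT) rule, and computes dwell-based
    measures per AOI as well as dyadic paired-gaze states (two-way, one-way
    and no eye gaze) for two interacting participants. Also provides the
    validation statistics used to compare two AOI-center tracks (mean and
    maximum absolute difference, sample-to-sample RMS deviation), a Hampel
    detector and filter for blink-induced coordinate spikes, exact
    pixel/centimetre/degree screen-geometry conversions, and a synthetic-data
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
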