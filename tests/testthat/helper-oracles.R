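# Independent brute-force oracle for the LRVT rule: explicit distance loop
# over labels in tie order, kept deliberately separate from the package's
# vectorised implementation.
lrvt_oracle <- function(point, centers, radius_px,
                        tie_order = aoi_labels(), inclusive = TRUE) {
  best_lab <- "non"
  best_d <- Inf
  for (lab in tie_order) {
    d <- sqrt(sum((centers[[lab]] - point)^2))
    if (d < best_d) {  # strict: earlier tie_order entry wins exact ties
      best_d <- d
      best_lab <- lab
    }
  }
  ok <- if (inclusive) best_d <= radius_px else best_d < radius_px
  if (ok) best_lab else "non"
}
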