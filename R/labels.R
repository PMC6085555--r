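AOI_LABELS <- c("left_eye", "right_eye", "nose", "mouth")
NON_LABEL <- "non"
MISSING_LABEL <- "missing"
STREAM_LABELS <- c(AOI_LABELS, NON_LABEL, MISSING_LABEL)
PAIRED_STATES <- c("two_way", "one_way", "no_eye_gaze", "undefined")
EYE_LABELS <- c("left_eye", "right_eye")

#' AOI label alphabets
#'
#' @description
#' `aoi_labels()` returns the four facial AOI labels in canonical order;
#' `stream_labels()` additionally includes `"non"` (gaze on screen but on no
#' facial AOI) and `"missing"` (invalid gaze sample or missing AOI centers);
#' `paired_states()` returns the four dyadic gaze states.
#'
#' @return A character vector.
#' @export
aoi_labels <- function() AOI_LABELS

#' @rdname aoi_labels
#' @export
stream_labels <- function() STREAM_LABELS

#' @rdname aoi_labels
#' @export
paired_states <- function() PAIRED_STATES

center_cols <- function(aois = AOI_LABELS) {
  as.vector(t(outer(aois, c("x", "y"), function(a, ax) paste0(a, "_", ax))))
}
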