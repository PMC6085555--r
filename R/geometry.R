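#' Screen geometry for pixel/degree conversion
#'
#' Describes a flat screen viewed frontally: resolution in pixels, physical
#' size in centimetres, and viewing distance in centimetres. The viewing
#' distance may instead be inferred from a known angular extent of the screen
#' via [infer_distance()] by supplying `width_deg` or `height_deg`.
#'
#' @param width_px,height_px Screen resolution in pixels (> 0).
#' @param width_cm,height_cm Physical screen size in cm (> 0).
#' @param distance_cm Viewing distance in cm (> 0), or `NULL` to infer it.
#' @param width_deg,height_deg Optional angular extent of the screen in
#'   degrees of visual angle; used to infer `distance_cm` when it is `NULL`
#'   (width takes precedence if both are given).
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(1680, 1050, 47.38, 29.61, width_deg = 32.61)
#' px_to_deg(6.5, geom)
#' @export
screen_geometry <- function(width_px, height_px, width_cm, height_cm,
                            distance_cm = NULL, width_deg = NULL,
                            height_deg = NULL) {
  vals <- c(width_px, height_px, width_cm, height_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    aoi_error("domain_error", "screen dimensions must be positive and finite")
  }
  if (is.null(distance_cm)) {
    if (!is.null(width_deg)) {
      distance_cm <- infer_distance(width_cm, width_deg)
    } else if (!is.null(height_deg)) {
      distance_cm <- infer_distance(height_cm, height_deg)
    } else {
      aoi_error("domain_error",
                "supply distance_cm, or width_deg/height_deg to infer it")
    }
  }
  if (!is.finite(distance_cm) || distance_cm <= 0) {
    aoi_error("domain_error", "distance_cm must be positive and finite")
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         width_cm = width_cm, height_cm = height_cm,
         distance_cm = distance_cm),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px, %.2f x %.2f cm, viewed at %.2f cm\n",
    x$width_px, x$height_px, x$width_cm, x$height_cm, x$distance_cm))
  cat(sprintf("  extent: %.2f x %.2f deg of visual angle\n",
              px_to_deg(x$width_px, x, "horizontal"),
              px_to_deg(x$height_px, x, "vertical")))
  invisible(x)
}

#' Infer viewing distance from a physical and an angular extent
#'
#' Solves `2 * atan(extent_cm / (2 * d)) = extent_deg` for the viewing
#' distance `d` in closed form: `d = (extent_cm / 2) / tan(extent_deg / 2)`.
#'
#' @param extent_cm Physical extent in cm (> 0).
#' @param extent_deg Angular extent in degrees (0 < extent_deg < 180).
#' @return Viewing distance in cm.
#' @export
infer_distance <- function(extent_cm, extent_deg) {
  if (!is.finite(extent_cm) || extent_cm <= 0 ||
      !is.finite(extent_deg) || extent_deg <= 0 || extent_deg >= 180) {
    aoi_error("domain_error",
              "need extent_cm > 0 and 0 < extent_deg < 180")
  }
  (extent_cm / 2) / tan(extent_deg * pi / 360)
}

pixel_pitch <- function(geom, axis) {
  switch(axis,
         horizontal = geom$width_cm / geom$width_px,
         vertical   = geom$height_cm / geom$height_px)
}

#' Convert between pixels and degrees of visual angle
#'
#' Tangent-exact conversion for an extent centred on the line of sight:
#' `deg = 2 * atan(n_px * pitch / (2 * distance))` where `pitch` is the
#' physical size of one pixel along the chosen axis. `deg_to_px()` is the
#' exact inverse. Both are odd functions and vectorised over the first
#' argument. The angular size of an off-centre extent is approximated by the
#' centred formula (eccentricity is ignored).
#'
#' @param n_px Extent in pixels (may be negative).
#' @param geom A [screen_geometry()].
#' @param axis `"horizontal"` or `"vertical"` (pixel pitch may differ).
#' @return Degrees of visual angle (`px_to_deg`) or pixels (`deg_to_px`).
#' @export
px_to_deg <- function(n_px, geom, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  pitch <- pixel_pitch(geom, axis)
  2 * atan(n_px * pitch / (2 * geom$distance_cm)) * 180 / pi
}

#' @rdname px_to_deg
#' @param angle_deg Extent in degrees of visual angle, `|angle_deg| < 180`.
#' @export
deg_to_px <- function(angle_deg, geom, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (any(!is.finite(angle_deg)) || any(abs(angle_deg) >= 180)) {
    aoi_error("domain_error", "|angle_deg| must be < 180")
  }
  pitch <- pixel_pitch(geom, axis)
  2 * geom$distance_cm * tan(angle_deg * pi / 360) / pitch
}
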