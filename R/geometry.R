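#' Screen geometry of the recording setup
#'
#' Display geometry used to convert pixel gaze coordinates into degrees of
#' visual angle. Defaults describe a 1024 x 768 CRT subtending an angular
#' radius of 14.7 degrees horizontally and 11.2 degrees vertically, viewed
#' from 71.5 cm, sampled at 1000 Hz.
#'
#' Conversion is linear per axis (small-angle convention): one horizontal
#' pixel is `half_width_deg / (width_px / 2)` degrees. At 14.7 degrees the
#' discrepancy with exact tangent geometry is below 2% and is not modelled.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param half_width_deg,half_height_deg Angular radii of the display in
#'   degrees of visual angle.
#' @param viewing_distance_cm Eye-to-screen distance in centimetres
#'   (informational; the linear conversion uses only the angular radii).
#' @param sample_rate_hz Gaze sampling rate in Hz.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(1024, 384, geom) # right screen edge, vertical midline
#' @export
screen_geometry <- function(width_px = 1024, height_px = 768,
                            half_width_deg = 14.7, half_height_deg = 11.2,
                            viewing_distance_cm = 71.5,
                            sample_rate_hz = 1000) {
  vals <- c(width_px, height_px, half_width_deg, half_height_deg,
            viewing_distance_cm, sample_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be strictly positive", call. = FALSE)
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         half_width_deg = half_width_deg, half_height_deg = half_height_deg,
         viewing_distance_cm = viewing_distance_cm,
         sample_rate_hz = sample_rate_hz),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, +/-%.1f x +/-%.1f deg, %g Hz\n",
              x$width_px, x$height_px, x$half_width_deg, x$half_height_deg,
              x$sample_rate_hz))
  invisible(x)
}

#' Convert pixel coordinates to degrees from screen centre
#'
#' @param x_px,y_px Numeric vectors of screen pixel coordinates.
#' @param geometry A [screen_geometry()].
#' @return A list with numeric vectors `x_deg`, `y_deg`: angular offsets
#'   from the screen centre. Off-screen coordinates map linearly beyond
#'   the screen radii. The mapping is invertible via [deg_to_px()].
#' @export
px_to_deg <- function(x_px, y_px, geometry = screen_geometry()) {
  hw <- geometry$width_px / 2
  hh <- geometry$height_px / 2
  list(x_deg = (x_px - hw) * geometry$half_width_deg / hw,
       y_deg = (y_px - hh) * geometry$half_height_deg / hh)
}

#' Convert degree offsets back to pixel coordinates
#'
#' Inverse of [px_to_deg()].
#' @param x_deg,y_deg Angular offsets from screen centre, degrees.
#' @inheritParams px_to_deg
#' @return A list with numeric vectors `x_px`, `y_px`.
#' @export
deg_to_px <- function(x_deg, y_deg, geometry = screen_geometry()) {
  hw <- geometry$width_px / 2
  hh <- geometry$height_px / 2
  list(x_px = x_deg * hw / geometry$half_width_deg + hw,
       y_px = y_deg * hh / geometry$half_height_deg + hh)
}

#' Angular distance between two gaze positions
#'
#' Euclidean distance in the flattened degree plane (small-angle
#' convention, consistent with the linear pixel-to-degree mapping).
#'
#' @param x1_deg,y1_deg,x2_deg,y2_deg Angular offsets in degrees
#'   (vectorised).
#' @return Numeric vector of distances in degrees.
#' @examples
#' angular_distance(0, 0, 3, 4) # 5
#' @export
angular_distance <- function(x1_deg, y1_deg, x2_deg, y2_deg) {
  sqrt((x2_deg - x1_deg)^2 + (y2_deg - y1_deg)^2)
}

#' Gaze-contingent mask specification
#'
#' Describes the display manipulation of a trial: `"window"` shows only
#' the region within `radius_deg` of gaze (central-vision condition),
#' `"scotoma"` hides that region (peripheral-vision condition), `"none"`
#' leaves the scene unmasked (control).
#'
#' @param mode One of `"window"`, `"scotoma"`, `"none"`.
#' @param radius_deg Mask radius in degrees of eccentricity; the default
#'   5 degrees corresponds to the foveal + parafoveal extent.
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(mode = c("none", "window", "scotoma"),
                      radius_deg = 5.0) {
  mode <- match.arg(mode)
  if (mode != "none" && (!is.finite(radius_deg) || radius_deg <= 0)) {
    stop("radius_deg must be > 0 when mode != 'none'", call. = FALSE)
  }
  structure(list(mode = mode, radius_deg = radius_deg), class = "mask_spec")
}

#' Is a scene point visible under a gaze-contingent mask?
#'
#' @param mask A [mask_spec()].
#' @param gaze_x_deg,gaze_y_deg Current gaze position, degrees.
#' @param x_deg,y_deg Scene point(s) to test, degrees.
#' @return Logical vector: `TRUE` where the point is visible. A window
#'   shows points at eccentricity `<= radius_deg`; a scotoma shows points
#'   strictly beyond it.
#' @export
visible <- function(mask, gaze_x_deg, gaze_y_deg, x_deg, y_deg) {
  if (mask$mode == "none") {
    return(rep(TRUE, length(x_deg)))
  }
  d <- angular_distance(gaze_x_deg, gaze_y_deg, x_deg, y_deg)
  if (mask$mode == "window") d <= mask$radius_deg else d > mask$radius_deg
}

#' Mask specification for a named visual condition
#'
#' Maps the experiment's condition labels onto masks: `central` is a
#' 5-degree gaze-contingent window, `peripheral` a 5-degree scotoma,
#' `control` no mask.
#'
#' @param condition `"central"`, `"peripheral"` or `"control"`.
#' @param radius_deg Mask radius in degrees.
#' @return A [mask_spec()].
#' @export
condition_mask <- function(condition, radius_deg = 5.0) {
  switch(match.arg(condition, c("central", "peripheral", "control")),
         central = mask_spec("window", radius_deg),
         peripheral = mask_spec("scotoma", radius_deg),
         control = mask_spec("none"))
}
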