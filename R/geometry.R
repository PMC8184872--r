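#' Screen and viewing geometry
#'
#' Recording geometry for converting between screen pixels and visual
#' degrees. Defaults describe a 23-inch 1920 x 1080 panel viewed at 670 mm
#' with the head stabilised on a chin rest. The conversion uses the exact
#' per-axis tangent about the screen center rather than a small-angle
#' approximation, because the 12-degree targets make the linearisation error
#' non-negligible; set `linear = TRUE` to restore it.
#'
#' Conventions: pixel coordinates are 0-based with y increasing downward;
#' degrees are measured from the screen center with right and up positive.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_mm,height_mm Physical panel size in millimeters.
#' @param distance_mm Eye-to-screen distance in millimeters.
#' @param linear Use the small-angle (linear) approximation instead of the
#'   tangent conversion.
#' @return A list of class `screen_geometry`.
#' @examples
#' g <- screen_geometry()
#' px_to_deg(960, 540, g)  # screen center -> (0, 0) degrees
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            width_mm = 509.2, height_mm = 286.4,
                            distance_mm = 670, linear = FALSE) {
  g <- list(width_px = width_px, height_px = height_px,
            width_mm = width_mm, height_mm = height_mm,
            distance_mm = distance_mm, linear = isTRUE(linear))
  if (any(unlist(g[1:5]) <= 0)) {
    stop_config("all screen geometry dimensions must be positive")
  }
  class(g) <- "screen_geometry"
  g
}

#' Convert screen pixels to visual degrees (and back)
#'
#' Per-axis conversion `deg = atan(((p - center) * mm_per_px) / distance)`,
#' odd-symmetric about the screen center; `deg_to_px()` is its exact inverse.
#'
#' @param x_px,y_px Pixel coordinates (0-based, y downward).
#' @param x_deg,y_deg Degrees from center (right/up positive).
#' @param geometry A [screen_geometry()] object.
#' @return A tibble with converted `x`/`y` columns.
#' @export
px_to_deg <- function(x_px, y_px, geometry = screen_geometry()) {
  mmx <- geometry$width_mm / geometry$width_px
  mmy <- geometry$height_mm / geometry$height_px
  cx <- (geometry$width_px - 1) / 2
  cy <- (geometry$height_px - 1) / 2
  dx <- (x_px - cx) * mmx / geometry$distance_mm
  dy <- -(y_px - cy) * mmy / geometry$distance_mm  # y flips: screen y is down
  if (geometry$linear) {
    tibble::tibble(x_deg = dx * 180 / pi, y_deg = dy * 180 / pi)
  } else {
    tibble::tibble(x_deg = atan(dx) * 180 / pi, y_deg = atan(dy) * 180 / pi)
  }
}

#' @rdname px_to_deg
#' @export
deg_to_px <- function(x_deg, y_deg, geometry = screen_geometry()) {
  mmx <- geometry$width_mm / geometry$width_px
  mmy <- geometry$height_mm / geometry$height_px
  cx <- (geometry$width_px - 1) / 2
  cy <- (geometry$height_px - 1) / 2
  if (geometry$linear) {
    tx <- x_deg * pi / 180
    ty <- y_deg * pi / 180
  } else {
    tx <- tan(x_deg * pi / 180)
    ty <- tan(y_deg * pi / 180)
  }
  tibble::tibble(
    x_px = tx * geometry$distance_mm / mmx + cx,
    y_px = -ty * geometry$distance_mm / mmy + cy
  )
}
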