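#' Cage geometry
#'
#' Pixel-space description of one home cage: the cage bounds, the 2x2
#' quadrant partition of the floor, the social window (a circular hole in
#' the lower inside-facing wall through which a partner mouse is
#' visible), the shelter hut region, and the pixel-to-centimetre scale.
#'
#' The coordinate system follows image conventions: origin at the
#' top-left of the cage crop, x rightward, y downward, pixel units.
#'
#' @param width_px,height_px Cage bounds in pixels. Defaults 320 x 240
#'   (one cage crop of a 640 x 960 two-camera frame covering 8 cages).
#' @param px_per_cm Pixels per centimetre (default 6).
#' @param window_center `c(x, y)` of the window centre; must lie on a
#'   cage wall. Default: on the right (inside-facing) wall near the lower
#'   corner.
#' @param window_radius_px Window radius in px. Default: a 2.5-inch
#'   diameter hole converted via `px_per_cm`.
#' @param hut Named vector `c(x0, x1, y0, y1)` of the hut rectangle;
#'   must lie within the cage. Default: upper-left third of the cage.
#' @return An object of class `cage_geometry`.
#' @export
cage_geometry <- function(width_px = 320, height_px = 240, px_per_cm = 6,
                          window_center = NULL, window_radius_px = NULL,
                          hut = NULL) {
  stopifnot(width_px > 0, height_px > 0, px_per_cm > 0)
  if (is.null(window_center))
    window_center <- c(width_px, height_px * 0.85)
  if (is.null(window_radius_px))
    window_radius_px <- (2.5 * 2.54 / 2) * px_per_cm
  if (is.null(hut))
    hut <- c(x0 = 0, x1 = width_px / 3, y0 = 0, y1 = height_px / 3)
  hut <- hut[c("x0", "x1", "y0", "y1")]
  on_wall <- isTRUE(all.equal(window_center[1], 0)) ||
    isTRUE(all.equal(window_center[1], width_px)) ||
    isTRUE(all.equal(window_center[2], 0)) ||
    isTRUE(all.equal(window_center[2], height_px))
  if (!on_wall) stop("window_center must lie on a cage wall")
  if (any(is.na(hut)) || hut["x0"] < 0 || hut["x1"] > width_px ||
      hut["y0"] < 0 || hut["y1"] > height_px ||
      hut["x1"] <= hut["x0"] || hut["y1"] <= hut["y0"])
    stop("hut region must be a non-empty rectangle inside the cage bounds")
  structure(
    list(width_px = width_px, height_px = height_px, px_per_cm = px_per_cm,
         window_center = unname(window_center),
         window_radius_px = window_radius_px, hut = hut),
    class = "cage_geometry"
  )
}

#' @export
print.cage_geometry <- function(x, ...) {
  cat("<cage_geometry> ", x$width_px, "x", x$height_px, " px @ ",
      x$px_per_cm, " px/cm\n", sep = "")
  cat("  window: centre (", paste(signif(x$window_center, 4), collapse = ", "),
      "), radius ", signif(x$window_radius_px, 4), " px\n", sep = "")
  cat("  hut: [", x$hut["x0"], ",", x$hut["x1"], "] x [", x$hut["y0"], ",",
      x$hut["y1"], "] px\n", sep = "")
  invisible(x)
}

#' Quadrant containing each point
#'
#' The cage floor is split into a 2x2 grid. Quadrants are numbered 1 =
#' top-left, 2 = top-right, 3 = bottom-left, 4 = bottom-right (image
#' coordinates; "top" is small y). Points on a midline belong to the
#' right/bottom quadrant (half-open convention).
#'
#' @param x,y Coordinates in px.
#' @param geometry A [cage_geometry()].
#' @return Integer vector in 1..4.
#' @export
quadrant_of <- function(x, y, geometry) {
  mx <- geometry$width_px / 2
  my <- geometry$height_px / 2
  1L + (x >= mx) + 2L * (y >= my)
}

# minimum distance (px) from each point to the four cage walls
wall_distance_px <- function(x, y, geometry) {
  pmin(x, geometry$width_px - x, y, geometry$height_px - y)
}

# is each point inside the hut rectangle (closed)
in_hut <- function(x, y, geometry) {
  h <- geometry$hut
  x >= h["x0"] & x <= h["x1"] & y >= h["y0"] & y <= h["y1"]
}

# is each point within the window radius
near_window <- function(x, y, geometry) {
  wc <- geometry$window_center
  sqrt((x - wc[1])^2 + (y - wc[2])^2) <= geometry$window_radius_px
}
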