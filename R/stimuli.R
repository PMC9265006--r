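#' Screen specification
#'
#' Describes the touch surface as a pixel raster with origin at the top-left
#' corner, x increasing rightward and y increasing downward. The default
#' 1024 x 768 geometry corresponds to a typical 4:3 panel and comfortably
#' admits the largest (550 px) training dot.
#'
#' @param width_px,height_px Screen dimensions in pixels (positive integers).
#' @return An object of class `dot_screen`.
#' @examples
#' scr <- screen_spec()
#' scr$width_px
#' @export
screen_spec <- function(width_px = 1024L, height_px = 768L) {
  width_px  <- check_count(width_px, "width_px", min = 1L)
  height_px <- check_count(height_px, "height_px", min = 1L)
  structure(list(width_px = width_px, height_px = height_px),
            class = "dot_screen")
}

#' Dot stimulus
#'
#' A circular target on the screen, optionally carrying a numeral label
#' ("1" or "2") used by the sequencing task. The dot must lie fully on
#' screen: `radius <= center <= dimension - radius` on both axes.
#'
#' @param dot_id Identifier (character or integer, stored as character).
#' @param center_x_px,center_y_px Center coordinates in pixels (origin
#'   top-left, y downward).
#' @param diameter_px Dot diameter in pixels (> 0).
#' @param label One of `"none"`, `"1"`, `"2"`.
#' @param visible Logical; newly presented dots are visible.
#' @param screen Optional [screen_spec()]; when given, the on-screen
#'   invariant is enforced.
#' @return An object of class `dot_stimulus`.
#' @export
dot_stimulus <- function(dot_id, center_x_px, center_y_px, diameter_px,
                         label = "none", visible = TRUE, screen = NULL) {
  diameter_px <- check_number(diameter_px, "diameter_px", min = 0, strict_min = TRUE)
  check_number(center_x_px, "center_x_px")
  check_number(center_y_px, "center_y_px")
  if (!label %in% c("none", "1", "2"))
    dt_spec_error('`label` must be one of "none", "1", "2"')
  if (!is.null(screen)) {
    r <- diameter_px / 2
    if (center_x_px < r || center_x_px > screen$width_px - r ||
        center_y_px < r || center_y_px > screen$height_px - r)
      dt_spec_error(sprintf("dot %s does not lie fully on screen", dot_id))
  }
  structure(list(dot_id = as.character(dot_id),
                 center_x_px = center_x_px, center_y_px = center_y_px,
                 diameter_px = diameter_px, label = label,
                 visible = isTRUE(visible)),
            class = "dot_stimulus")
}

#' Touch event
#'
#' A single touch at a pixel coordinate, timestamped on the session clock
#' (seconds since session start).
#'
#' @param time_s Seconds on the session clock (>= 0).
#' @param x_px,y_px Touch coordinates in pixels.
#' @param screen Optional [screen_spec()] for bounds checking
#'   (`0 <= x < width`, `0 <= y < height`).
#' @return An object of class `dot_touch`.
#' @export
touch_event <- function(time_s, x_px, y_px, screen = NULL) {
  check_number(time_s, "time_s", min = 0)
  check_number(x_px, "x_px")
  check_number(y_px, "y_px")
  if (!is.null(screen)) {
    if (x_px < 0 || x_px >= screen$width_px || y_px < 0 || y_px >= screen$height_px)
      dt_spec_error("touch coordinates out of screen bounds")
  }
  structure(list(time_s = time_s, x_px = x_px, y_px = y_px),
            class = "dot_touch")
}

#' Place dots at random non-overlapping locations
#'
#' Samples dot centers uniformly (rejection sampling) over the feasible
#' integer lattice so that every dot lies fully on screen and, for any pair,
#' the Euclidean center distance strictly exceeds the sum of radii plus
#' `min_gap_px`. Uses the R global random number generator; seed the session
#' for reproducibility.
#'
#' @param screen A [screen_spec()].
#' @param diameters Numeric vector of 1 or 2 dot diameters in pixels.
#' @param min_gap_px Minimum extra clearance between dot rims (default 0,
#'   i.e. plain non-overlap).
#' @param labels Optional character vector of labels, recycled to the dots
#'   (default `"none"`).
#' @param max_attempts Rejection-sampling budget before a placement error
#'   is raised (default 10000).
#' @return List of [dot_stimulus()] objects (dot ids `"d1"`, `"d2"`).
#' @examples
#' set.seed(1)
#' sample_dot_placement(screen_spec(), c(100, 100))
#' @export
sample_dot_placement <- function(screen, diameters, min_gap_px = 0,
                                 labels = NULL, max_attempts = 10000L) {
  n <- length(diameters)
  if (n < 1L || n > 2L)
    dt_spec_error("`diameters` must have length 1 or 2")
  check_number(min_gap_px, "min_gap_px", min = 0)
  lim <- min(screen$width_px, screen$height_px)
  for (d in diameters) {
    check_number(d, "diameter", min = 0, strict_min = TRUE)
    if (d > lim)
      dt_config_error(sprintf("dot diameter %g exceeds smallest screen dimension %d", d, lim))
  }
  if (is.null(labels)) labels <- rep("none", n)
  labels <- rep_len(labels, n)

  # feasible center lattice per dot: integers in [ceil(r), floor(dim - r)]
  r  <- diameters / 2
  xlo <- ceiling(r); xhi <- floor(screen$width_px - r)
  ylo <- ceiling(r); yhi <- floor(screen$height_px - r)

  for (attempt in seq_len(max_attempts)) {
    cx <- xlo + floor(stats::runif(n) * (xhi - xlo + 1))
    cy <- ylo + floor(stats::runif(n) * (yhi - ylo + 1))
    # guard against the measure-zero runif(..) == 1 edge
    cx <- pmin(cx, xhi); cy <- pmin(cy, yhi)
    ok <- TRUE
    if (n == 2L) {
      dist <- sqrt((cx[1] - cx[2])^2 + (cy[1] - cy[2])^2)
      ok <- dist > sum(r) + min_gap_px
    }
    if (ok) {
      return(lapply(seq_len(n), function(i)
        dot_stimulus(paste0("d", i), cx[i], cy[i], diameters[i],
                     label = labels[i])))
    }
  }
  dt_placement_error(sprintf(
    "could not place %d dots after %d attempts (screen %dx%d, min_gap %g)",
    n, max_attempts, screen$width_px, screen$height_px, min_gap_px))
}

#' Hit-test a touch against a dot
#'
#' A touch hits a dot iff its Euclidean distance to the dot center is at
#' most the radius (inclusive boundary). The numeral label plays no role.
#'
#' @param dot A visible [dot_stimulus()].
#' @param touch A [touch_event()].
#' @return `TRUE` if the touch lands on the dot.
#' @export
hit_test <- function(dot, touch) {
  if (!isTRUE(dot$visible))
    dt_spec_error("hit_test requires a visible dot")
  dx <- touch$x_px - dot$center_x_px
  dy <- touch$y_px - dot$center_y_px
  sqrt(dx * dx + dy * dy) <= dot$diameter_px / 2
}
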