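#' Elliptical agent footprint
#'
#' Constructs the planar elliptical footprint of an agent. Coordinates are
#' global 2D Cartesian in meters with y increasing toward the exit; the
#' orientation is the angle of the major axis against the global x axis,
#' normalized to `[0, pi)` (an ellipse is symmetric under rotation by pi).
#'
#' @param center numeric length 2, center position (m).
#' @param orientation major-axis angle (rad), any value; stored mod pi.
#' @param a semi-major axis (m), `a >= b`.
#' @param b semi-minor axis (m), `> 0`.
#' @return An object of class `ellipse_shape`.
#' @examples
#' ellipse_shape(c(0, 0), 0, a = 0.03, b = 0.015)
#' @export
ellipse_shape <- function(center, orientation = 0, a, b) {
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  if (!is.finite(a) || !is.finite(b) || b <= 0 || a < b)
    stop("invalid ellipse axes: need a >= b > 0")
  phi <- orientation %% pi
  structure(list(center = as.numeric(center), orientation = phi,
                 a = a, b = b),
            class = "ellipse_shape")
}

#' Wall segment
#'
#' A straight wall segment with a unit inward normal (the side agents
#' occupy). If `inward_normal` is omitted the left-hand perpendicular of
#' `p2 - p1` is used.
#'
#' @param p1,p2 numeric length 2 endpoints (m); must be distinct.
#' @param inward_normal optional unit normal, perpendicular to the segment.
#' @return An object of class `wall_segment`.
#' @export
wall_segment <- function(p1, p2, inward_normal = NULL) {
  stopifnot(is.numeric(p1), is.numeric(p2), length(p1) == 2, length(p2) == 2)
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("invalid geometry: zero-length wall segment")
  if (is.null(inward_normal)) {
    inward_normal <- c(-d[2], d[1]) / len
  } else {
    nn <- sqrt(sum(inward_normal^2))
    if (abs(nn - 1) > 1e-8 || abs(sum(inward_normal * d)) > 1e-8 * len)
      stop("inward_normal must be a unit vector perpendicular to the segment")
  }
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                 inward_normal = as.numeric(inward_normal)),
            class = "wall_segment")
}

contact_info <- function(delta, normal, point) {
  structure(list(delta = delta, normal = as.numeric(normal),
                 point = as.numeric(point)),
            class = "contact_info")
}

as_cpp_shape <- function(s) {
  c(s$center[1], s$center[2], s$orientation, s$a, s$b)
}

#' Overlap of two elliptical footprints
#'
#' Detects contact between two ellipses and returns the penetration depth,
#' the unit contact normal pointing from `shape_j` toward `shape_i`, and a
#' contact point inside the intersection lens. The depth is measured along
#' the mid-normal of the chord joining the boundary intersection points
#' (the extent of the overlap lens along that line); for two circles this
#' reduces to `2 r - d`. When one center lies inside the other ellipse the
#' center-to-center direction is used instead.
#'
#' @param shape_i,shape_j [ellipse_shape()] objects.
#' @return A `contact_info` (fields `delta`, `normal`, `point`) or `NULL`
#'   when the boundaries do not intersect. Swapping the arguments preserves
#'   `delta` and flips the normal. Coincident centers raise a
#'   "degenerate contact" error (the normal is undefined).
#' @examples
#' a <- ellipse_shape(c(0, 0), 0, 0.03, 0.03)
#' b <- ellipse_shape(c(0.05, 0), 0, 0.03, 0.03)
#' ellipse_overlap(a, b)$delta  # 0.01
#' @export
ellipse_overlap <- function(shape_i, shape_j) {
  stopifnot(inherits(shape_i, "ellipse_shape"),
            inherits(shape_j, "ellipse_shape"))
  res <- ellipse_contact_cpp(as_cpp_shape(shape_i), as_cpp_shape(shape_j))
  if (!res$found) return(NULL)
  contact_info(res$delta, res$normal, res$point)
}

#' Contact of an ellipse with a wall segment
#'
#' Reports contact when the ellipse boundary crosses the wall's supporting
#' line within the segment extent. The depth is the maximal penetration of
#' the ellipse past the wall line (support function minus center distance);
#' the normal points from the wall toward the agent, i.e. equals the inward
#' normal for an agent on the inward side.
#'
#' @param shape an [ellipse_shape()].
#' @param wall a [wall_segment()].
#' @return A `contact_info` or `NULL`.
#' @export
segment_contact <- function(shape, wall) {
  stopifnot(inherits(shape, "ellipse_shape"), inherits(wall, "wall_segment"))
  res <- wall_face_contact_cpp(as_cpp_shape(shape), wall$p1, wall$p2,
                               wall$inward_normal)
  if (!res$found) return(NULL)
  contact_info(res$delta, res$normal, res$point)
}

#' Contact of an ellipse with a point obstacle (wall corner)
#'
#' Wall junctions such as the exit-gap edges are treated as point obstacles
#' with the normal along the corner-to-center direction and the depth the
#' radial penetration of the point into the ellipse.
#'
#' @param shape an [ellipse_shape()].
#' @param point numeric length 2 obstacle position (m).
#' @return A `contact_info` or `NULL`.
#' @export
corner_contact <- function(shape, point) {
  stopifnot(inherits(shape, "ellipse_shape"),
            is.numeric(point), length(point) == 2)
  res <- point_contact_cpp(as_cpp_shape(shape), point)
  if (!res$found) return(NULL)
  contact_info(res$delta, res$normal, res$point)
}
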