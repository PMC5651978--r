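#' Build the guide-wall arena
#'
#' A rectangular room of the given width (x) and length (y, increasing
#' toward the exit) with a single exit gap centered in the far wall. Two
#' guide walls are hinged at the exit-gap edges and rotated by `theta_deg`
#' from the exit-wall plane toward the room interior, spanning to the side
#' walls so the boundary is closed with no gap except the exit (this
#' mirrors an apparatus in which the guide walls connect the exit to the
#' corridor sides; at `theta = 0` they are collinear with the exit wall and
#' reproduce a flat wall with a plain opening). The waiting area is the
#' strip of the given depth at the near end of the room.
#'
#' @param theta_deg guide-wall angle (degrees), in `[0, 90)`.
#' @param width room width (m).
#' @param length room length (m); the exit line lies at `y = length`.
#' @param exit_width width of the exit gap (m); must exceed
#'   `min_agent_diameter`.
#' @param waiting_depth depth of the initial waiting strip (m).
#' @param min_agent_diameter smallest admissible exit width (m), the minor
#'   diameter of the agents (default a 1.5 cm semi-minor-axis mouse).
#' @return An object of class `evac_arena` with the wall segments (matrix
#'   columns p1x, p1y, p2x, p2y, nx, ny with inward unit normals), the
#'   exit-gap corner points, the exit line and the exit target point (gap
#'   midpoint).
#' @examples
#' build_arena(75)
#' @export
build_arena <- function(theta_deg, width = 0.25, length = 0.85,
                        exit_width = 0.06, waiting_depth = 0.30,
                        min_agent_diameter = 0.03) {
  if (!is.finite(theta_deg) || theta_deg < 0 || theta_deg >= 90)
    stop("guide-wall angle must be in [0, 90) degrees")
  if (width <= 0 || length <= 0 || exit_width <= 0 || waiting_depth <= 0)
    stop("arena dimensions must be positive")
  if (exit_width <= min_agent_diameter)
    stop("exit narrower than the agent minor diameter")
  if (exit_width >= width) stop("exit_width must be smaller than width")
  th <- theta_deg * pi / 180
  half_span <- (width - exit_width) / 2
  depth <- tan(th) * half_span
  if (depth >= length - waiting_depth)
    stop("guide walls reach into the waiting area; increase length")
  gx0 <- width / 2 - exit_width / 2
  gx1 <- width / 2 + exit_width / 2
  y_side <- length - depth
  seg <- function(p1, p2, n) c(p1, p2, n)
  walls <- rbind(
    seg(c(0, 0), c(width, 0), c(0, 1)),                # near wall
    seg(c(0, 0), c(0, y_side), c(1, 0)),               # left side
    seg(c(width, 0), c(width, y_side), c(-1, 0)),      # right side
    seg(c(0, y_side), c(gx0, length), c(NA, NA)),      # left guide wall
    seg(c(width, y_side), c(gx1, length), c(NA, NA))   # right guide wall
  )
  # inward normals of the guide walls point down into the room
  for (w in 4:5) {
    d <- walls[w, 3:4] - walls[w, 1:2]
    d <- d / sqrt(sum(d^2))
    n <- if (w == 4) c(d[2], -d[1]) else c(-d[2], d[1])
    walls[w, 5:6] <- n
  }
  colnames(walls) <- c("p1x", "p1y", "p2x", "p2y", "nx", "ny")
  structure(list(theta_deg = theta_deg, width = width, length = length,
                 exit_width = exit_width, waiting_depth = waiting_depth,
                 walls = walls,
                 corners = rbind(c(gx0, length), c(gx1, length)),
                 exit_y = length, exit_x0 = gx0, exit_x1 = gx1,
                 exit_target = c(width / 2, length)),
            class = "evac_arena")
}

#' @export
print.evac_arena <- function(x, ...) {
  cat(sprintf(
    "<evac_arena> %.2f x %.2f m, exit %.3f m, guide walls %g deg (depth %.3f m)\n",
    x$width, x$length, x$exit_width, x$theta_deg,
    x$length - min(x$walls[4:5, "p1y"])))
  invisible(x)
}

#' Wall segments of an arena
#'
#' @param arena an `evac_arena`.
#' @return List of [wall_segment()] objects.
#' @export
arena_walls <- function(arena) {
  stopifnot(inherits(arena, "evac_arena"))
  apply(arena$walls, 1, function(w)
    wall_segment(w[1:2], w[3:4], w[5:6]), simplify = FALSE)
}
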