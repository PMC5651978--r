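#' Panic-behaviour configuration
#'
#' Parameters of the panic-state decision rules. The critical density is
#' the sector occupancy above which an agent declines to steer into that
#' sector. The default 77 agents/m^2 is the mouse-scale value obtained by
#' preserving the occupancy fraction of the human-scale rule
#' (0.78 agents/m^2 for human-sized bodies) relative to the body footprint
#' of a 6 cm x 3 cm mouse. Sector radius defaults to four semi-major axes
#' (0.12 m); the wall-avoidance range to two semi-minor axes (0.03 m).
#'
#' @param critical_density sector density threshold (agents/m^2), `> 0`.
#' @param sector_radius radius of the decision sectors (m), `> 0`.
#' @param wall_avoid_distance range of the wall-avoidance steering (m).
#' @param right_first_fraction fraction of agents that check the right
#'   side first, in `[0, 1]`; 0.9 mirrors the right-handed share of a
#'   population.
#' @param sector_offset angular offset of the side sectors (rad); also the
#'   sector half-width.
#' @return An object of class `behavior_config`.
#' @export
behavior_config <- function(critical_density = 77, sector_radius = 0.12,
                            wall_avoid_distance = 0.03,
                            right_first_fraction = 0.9,
                            sector_offset = pi / 6) {
  if (critical_density <= 0) stop("critical_density must be positive")
  if (sector_radius <= 0) stop("sector_radius must be positive")
  if (right_first_fraction < 0 || right_first_fraction > 1)
    stop("right_first_fraction must be in [0, 1]")
  structure(list(critical_density = critical_density,
                 sector_radius = sector_radius,
                 wall_avoid_distance = wall_avoid_distance,
                 right_first_fraction = right_first_fraction,
                 sector_offset = sector_offset),
            class = "behavior_config")
}

#' Assign handedness to agents
#'
#' Exactly `round(fraction_right * n)` agents check their right side first
#' when overtaking; the rest check the left first. The assignment order is
#' shuffled with a seeded RNG.
#'
#' @param n number of agents, `>= 0`.
#' @param fraction_right fraction of right-first agents, in `[0, 1]`.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return Logical vector of length `n`; `TRUE` = right-first.
#' @examples
#' table(assign_handedness(50, 0.9, seed = 1))
#' @export
assign_handedness <- function(n, fraction_right = 0.9, seed = NULL) {
  if (fraction_right < 0 || fraction_right > 1)
    stop("fraction_right must be in [0, 1]")
  if (n < 0) stop("n must be non-negative")
  if (n == 0) return(logical(0))
  n_right <- round(fraction_right * n)
  h <- c(rep(TRUE, n_right), rep(FALSE, n - n_right))
  with_seed(seed, h[sample.int(n)])
}

#' Agent density in a decision sector
#'
#' Counts the other agents whose centers fall in the circular sector of
#' angular half-width pi/6 and radius `sector_radius`, centered on the
#' heading rotated by 0 (front), -pi/6 (right) or +pi/6 (left), and divides
#' by the sector area `(pi/3) R^2 / 2`.
#'
#' @param position agent center (m), length 2.
#' @param heading heading angle (rad, counterclockwise from +x).
#' @param side one of `"front"`, `"right"`, `"left"`.
#' @param others matrix of other agents' centers (rows of x, y), or NULL.
#' @param config a [behavior_config()].
#' @return Density in agents/m^2.
#' @export
sector_density <- function(position, heading, side = c("front", "right", "left"),
                           others, config = behavior_config()) {
  side <- match.arg(side)
  off <- switch(side, front = 0, right = -config$sector_offset,
                left = config$sector_offset)
  R <- config$sector_radius
  area <- pi * R^2 / 6
  if (is.null(others) || NROW(others) == 0) return(0)
  others <- matrix(as.numeric(others), ncol = 2)
  rel <- sweep(others, 2, position)
  d <- sqrt(rowSums(rel^2))
  ax <- c(cos(heading + off), sin(heading + off))
  keep <- d > 1e-12 & d <= R
  if (!any(keep)) return(0)
  cosang <- (rel[keep, 1] * ax[1] + rel[keep, 2] * ax[2]) / d[keep]
  sum(cosang >= cos(config$sector_offset)) / area
}

#' Desired velocities from the panic-behaviour rules
#'
#' For every active agent: (i) the base desired direction points to the
#' nearest point of the exit opening (inset by one semi-minor axis from
#' the doorposts), which far from the exit is the gap midpoint and close
#' up is straight through the opening; (ii) if the nearest agent in the
#' front sector is slower
#' than the agent, it attempts to overtake by steering +-pi/6 into the
#' first side sector (preferred side first) whose density is strictly
#' below the critical density (the front target itself does not count
#' toward the side-sector occupancy: the side sectors overlap the front
#' wedge, and the agent being passed must not veto its own overtake);
#' (iii) if both side sectors are at or above
#' the critical density the agent slows to the front target's current
#' speed and follows it. Only a target walking in the same direction at a
#' non-negligible speed (> 0.01 m/s) is overtaken or followed; a jammed or
#' opposing crowd is pushed against under rule (i). (iv) A lateral
#' steering adjustment (perpendicular to the desired direction) pushes
#' away from the nearest wall face closer than the wall-avoidance range,
#' weighted by `1 - d / wall_avoid_distance`; the perpendicular face
#' distance is used, so the exit-gap doorposts do not deflect an agent
#' already in the opening. The magnitude equals the desired speed except
#' in follow mode.
#'
#' @param state an `evac_state` (see [new_state()]).
#' @param arena an `evac_arena` from [build_arena()], or NULL for open
#'   space (no walls; the exit target must then be supplied).
#' @param config a [behavior_config()].
#' @param exit_target optional length-2 override of the exit target point.
#' @return Matrix `n x 2` of desired velocities (m/s); zero rows for
#'   exited agents.
#' @export
desired_velocities <- function(state, arena, config = behavior_config(),
                               exit_target = NULL) {
  stopifnot(inherits(state, "evac_state"))
  if (!is.null(exit_target)) {
    exit_spec <- c(exit_target[1], exit_target[1], exit_target[2], 0)
  } else {
    if (is.null(arena)) stop("need an arena or an explicit exit_target")
    exit_spec <- c(arena$exit_x0, arena$exit_x1, arena$exit_y,
                   min(state$b))
  }
  walls <- if (is.null(arena)) matrix(0, 0, 6) else arena$walls
  desired_velocities_cpp(state$pos, state$vel, state$desired_speed,
                         state$right_first, state$active, walls,
                         exit_spec, config$critical_density,
                         config$sector_radius, config$wall_avoid_distance)
}

#' Desired velocity of a single agent
#'
#' Convenience wrapper around [desired_velocities()] for one agent among
#' others; errors if the agent lies outside the arena bounds.
#'
#' @param i index of the agent in `state`.
#' @inheritParams desired_velocities
#' @return Numeric length 2 desired velocity (m/s).
#' @export
desired_velocity <- function(i, state, arena, config = behavior_config(),
                             exit_target = NULL) {
  if (!is.null(arena)) {
    p <- state$pos[i, ]
    if (p[1] < 0 || p[1] > arena$width || p[2] < 0 || p[2] > arena$length)
      stop("agent lies outside the arena")
  }
  desired_velocities(state, arena, config, exit_target)[i, ]
}
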