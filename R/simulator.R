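#' Simulation configuration
#'
#' Collects every tunable of a single evacuation run: agent geometry and
#' mass (mouse-scale defaults: 3 cm semi-major axis, 1.5 cm semi-minor
#' axis, 30 g), the desired-speed distribution, contact and behaviour
#' parameters, the integration time step and the arena geometry.
#'
#' @param n_agents number of agents.
#' @param theta_deg guide-wall angle (degrees).
#' @param dt integration time step (s). The default 1e-4 s keeps the
#'   explicit dashpot update stable at mouse scale, where the damping
#'   derived from restitution 0.1 gives `eta * dt / m_eff` above the
#'   stability bound 2 at a 1e-3 s step (see the methods vignette).
#' @param max_time maximum simulated time (s).
#' @param record_stride trajectory output stride in steps; default
#'   emulates a ~30 fps tracking export at the chosen dt.
#' @param behavior_stride steps between desired-velocity updates.
#' @param speed_mean,speed_sd mean and standard deviation (m/s) of the
#'   desired-speed distribution (normal, redrawn while at or below
#'   `speed_min`).
#' @param speed_min floor of the desired-speed draws (m/s).
#' @param agent_a,agent_b,agent_mass semi-axes (m) and mass (kg).
#' @param dt_res response time of the psychological force (s).
#' @param orient_rate maximum angular rate (rad/s) at which the body axis
#'   relaxes toward the heading; default a quarter turn per response time.
#'   Bounding the turn rate prevents contact-driven velocity swings from
#'   spinning the ellipse in place and pumping spring energy.
#' @param block_time seconds of near-standstill (speed below 0.01 m/s)
#'   after which a blocked agent repositions; the deterministic rules
#'   alone can reach exact static arch equilibria that a real blocked
#'   animal breaks by shifting its footing. 0 disables repositioning.
#' @param reposition_time duration (s) of the repositioning sidestep
#'   (desired direction rotated a quarter turn toward the handed side).
#' @param contact a [contact_params()].
#' @param behavior a [behavior_config()].
#' @param width,length,exit_width,waiting_depth arena dimensions (m),
#'   passed to [build_arena()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_agents = 20, theta_deg = 0, dt = 1e-4,
                       max_time = 120, record_stride = NULL,
                       behavior_stride = 1L, speed_mean = 0.4,
                       speed_sd = 0.1, speed_min = 0.05,
                       agent_a = 0.03, agent_b = 0.015,
                       agent_mass = 0.030, dt_res = 0.1,
                       orient_rate = pi / (2 * 0.1),
                       block_time = 1, reposition_time = 0.5,
                       contact = contact_params(),
                       behavior = behavior_config(), width = 0.25,
                       length = 0.85, exit_width = 0.06,
                       waiting_depth = 0.30) {
  if (dt <= 0) stop("dt must be positive")
  if (n_agents < 1) stop("n_agents must be positive")
  if (speed_sd < 0) stop("speed_sd must be non-negative")
  if (is.null(record_stride)) record_stride <- max(1, round(1 / (30 * dt)))
  structure(list(n_agents = as.integer(n_agents), theta_deg = theta_deg,
                 dt = dt, max_time = max_time,
                 record_stride = as.integer(record_stride),
                 behavior_stride = as.integer(behavior_stride),
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 speed_min = speed_min,
                 agent_a = agent_a, agent_b = agent_b,
                 agent_mass = agent_mass, dt_res = dt_res,
                 orient_rate = orient_rate, block_time = block_time,
                 reposition_time = reposition_time,
                 contact = contact, behavior = behavior, width = width,
                 length = length, exit_width = exit_width,
                 waiting_depth = waiting_depth),
            class = "sim_config")
}

#' Agent state container
#'
#' Kinematics, shape, traits and evacuation status of all agents in a run.
#' Scalar shape/trait arguments are recycled across agents.
#'
#' @param pos `n x 2` matrix of center positions (m).
#' @param vel `n x 2` matrix of velocities (m/s); default at rest.
#' @param phi orientations (rad); default major axis along +y.
#' @param a,b semi-axes (m); `a >= b > 0`.
#' @param mass agent masses (kg), `> 0`.
#' @param desired_speed desired speed magnitudes (m/s).
#' @param right_first logical, right-first handedness per agent.
#' @param active logical; `FALSE` marks exited agents.
#' @param exit_time exit times (s), `NA` while not exited.
#' @param t simulation clock (s).
#' @return An object of class `evac_state`.
#' @export
new_state <- function(pos, vel = NULL, phi = NULL, a = 0.03, b = 0.015,
                      mass = 0.030, desired_speed = 0.4,
                      right_first = TRUE, active = TRUE, exit_time = NA_real_,
                      t = 0) {
  pos <- matrix(as.numeric(pos), ncol = 2)
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 2) else vel <- matrix(as.numeric(vel), ncol = 2)
  if (is.null(phi)) phi <- rep(pi / 2, n)
  rec <- function(x) rep_len(x, n)
  if (any(rec(mass) <= 0)) stop("mass must be positive")
  if (any(rec(b) <= 0) || any(rec(a) < rec(b)))
    stop("invalid ellipse axes: need a >= b > 0")
  structure(list(pos = pos, vel = vel, phi = rec(phi), a = rec(a),
                 b = rec(b), mass = rec(mass),
                 desired_speed = rec(desired_speed),
                 right_first = rec(right_first), active = rec(active),
                 exit_time = rec(exit_time), t = t),
            class = "evac_state")
}

#' Sample desired speeds
#'
#' Draws from a normal distribution with the given mean and standard
#' deviation, redrawing any non-positive values (agents always intend to
#' move toward the exit). In the angle-specific dispersion mode the sd is
#' the per-angle value; in the uniform mode it is the across-angle mean.
#'
#' @param n number of draws.
#' @param mean mean desired speed (m/s), `> 0`.
#' @param sd standard deviation (m/s), `>= 0`.
#' @param seed optional integer seed (caller's RNG state is restored).
#' @param min lower floor (m/s): draws at or below it are redrawn. The
#'   default 0 redraws only non-positive values; simulation runs use
#'   `sim_config()$speed_min` (0.05 m/s), a realism bound on how slowly a
#'   panicked animal escapes.
#' @return Numeric vector of `n` speeds above `min`.
#' @export
sample_desired_speeds <- function(n, mean, sd, seed = NULL, min = 0) {
  if (mean <= 0) stop("mean must be positive")
  if (sd < 0) stop("sd must be non-negative")
  if (min >= mean) stop("min must be below the mean")
  with_seed(seed, {
    s <- rnorm(n, mean, sd)
    while (any(s <= min)) s[s <= min] <- rnorm(sum(s <= min), mean, sd)
    s
  })
}

# non-overlapping placement of axis-aligned (major axis along +y) ellipses
# in the waiting strip by seeded rejection sampling
place_agents <- function(arena, n, a, b, margin = 1e-3, max_tries = 5000) {
  xlo <- b + margin
  xhi <- arena$width - b - margin
  ylo <- a + margin
  yhi <- arena$waiting_depth - a
  if (xhi <= xlo || yhi <= ylo)
    stop("waiting area too small for the agent size")
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (tr in seq_len(max_tries)) {
      p <- c(runif(1, xlo, xhi), runif(1, ylo, yhi))
      ok <- if (i == 1) TRUE else {
        dx <- (pos[seq_len(i - 1), 1] - p[1]) / b
        dy <- (pos[seq_len(i - 1), 2] - p[2]) / a
        all(dx^2 + dy^2 >= 4 * (1 + 1e-6))
      }
      if (ok) {
        pos[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("cannot place ", n, " non-overlapping agents in the waiting ",
           "area; enlarge waiting_depth or width")
  }
  pos
}

#' Initialize agents for a run
#'
#' Places `n_agents` without overlaps in the waiting strip (seeded
#' rejection sampling), samples desired speeds and assigns handedness.
#'
#' @param arena an `evac_arena`.
#' @param config a [sim_config()].
#' @param seed integer seed; the run is fully reproducible from it.
#' @return An `evac_state`.
#' @export
init_state <- function(arena, config, seed = 1) {
  with_seed(seed, {
    pos <- place_agents(arena, config$n_agents, config$agent_a,
                        config$agent_b)
    speeds <- sample_desired_speeds(config$n_agents, config$speed_mean,
                                    config$speed_sd,
                                    min = config$speed_min)
    hand <- assign_handedness(config$n_agents,
                              config$behavior$right_first_fraction)
    new_state(pos, a = config$agent_a, b = config$agent_b,
              mass = config$agent_mass, desired_speed = speeds,
              right_first = hand)
  })
}

cpp_par <- function(config, arena, n_steps, record, behavior, psych,
                    vdes_fixed, t0, active0) {
  par <- list(dt = config$dt, n_steps = as.integer(n_steps),
              record_stride = config$record_stride, record = record,
              k_normal = config$contact$k_normal,
              k_tangential = config$contact$k_tangential,
              mu = config$contact$friction,
              restitution = config$contact$restitution,
              dt_res = config$dt_res, orient_rate = config$orient_rate,
              block_time = config$block_time,
              reposition_time = config$reposition_time,
              psych_on = psych,
              behavior_on = behavior,
              behavior_stride = config$behavior_stride,
              critical_density = config$behavior$critical_density,
              sector_radius = config$behavior$sector_radius,
              wall_avoid_distance = config$behavior$wall_avoid_distance,
              exit_on = !is.null(arena), t0 = t0)
  if (!is.null(arena)) {
    par$exit_y <- arena$exit_y
    par$exit_x0 <- arena$exit_x0
    par$exit_x1 <- arena$exit_x1
    par$exit_spec <- c(arena$exit_x0, arena$exit_x1, arena$exit_y,
                       config$agent_b)
  } else if (behavior) {
    stop("behaviour update needs an arena (exit target)")
  }
  if (!behavior) {
    if (is.null(vdes_fixed)) vdes_fixed <- matrix(0, 0, 2)
    par$vdes_fixed <- vdes_fixed
  }
  par$active0 <- active0
  par
}

state_from_cpp <- function(state, res) {
  state$pos <- res$pos
  state$vel <- res$vel
  state$phi <- res$phi
  newly <- state$active & !res$active
  state$exit_time[newly] <- res$exit_time[newly]
  state$active <- res$active
  state$t <- res$t_end
  state
}

#' Advance the simulation by one or more time steps
#'
#' Semi-implicit Euler integration of Newton's second law with the summed
#' contact forces (agent pairs, wall faces, wall corners) and the
#' psychological force. Agents whose center crosses the exit line are
#' marked exited with a linearly interpolated exit time and excluded from
#' further dynamics. Tangential contact springs persist within one call;
#' [sim_run()] integrates a whole run in a single call so they persist
#' throughout.
#'
#' @param state an `evac_state`.
#' @param arena an `evac_arena`, or NULL for free space without walls or
#'   exit.
#' @param config a [sim_config()].
#' @param n_steps number of steps of size `config$dt` to take.
#' @param behavior recompute desired velocities from the behaviour rules
#'   every `behavior_stride` steps; if `FALSE`, `vdes_fixed` is used.
#' @param psych apply the psychological force.
#' @param vdes_fixed `n x 2` matrix of fixed desired velocities when
#'   `behavior = FALSE`.
#' @return The advanced `evac_state`.
#' @export
sim_step <- function(state, arena, config, n_steps = 1, behavior = TRUE,
                     psych = TRUE, vdes_fixed = NULL) {
  stopifnot(inherits(state, "evac_state"))
  par <- cpp_par(config, arena, n_steps, record = FALSE,
                 behavior = behavior, psych = psych,
                 vdes_fixed = vdes_fixed, t0 = state$t,
                 active0 = state$active)
  walls <- if (is.null(arena)) matrix(0, 0, 6) else arena$walls
  corners <- if (is.null(arena)) matrix(0, 0, 2) else arena$corners
  res <- run_sim_cpp(state$pos, state$vel, state$phi, state$a, state$b,
                     state$mass, state$desired_speed, state$right_first,
                     walls, corners, par)
  state_from_cpp(state, res)
}

#' Run one evacuation trial
#'
#' Initializes agents in the waiting area, then integrates the full model
#' until all agents have exited or `max_time` is reached, recording the
#' trajectory at the configured output stride. Fully reproducible from the
#' seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param trial_id identifier written into the output tables.
#' @return A list of class `evac_run`: `tracks` (data frame with columns
#'   trial_id, frame, time_s, agent_id, x_m, y_m, orientation_rad,
#'   vx_mps, vy_mps, status), `events` (trial_id, agent_id, exit_time_s,
#'   in exit order), the final `state`, the `arena`, `config` and `seed`.
#' @examples
#' run <- sim_run(sim_config(n_agents = 3, max_time = 20), seed = 1)
#' head(run$events)
#' @export
sim_run <- function(config, seed = 1, trial_id = 1L) {
  arena <- build_arena(config$theta_deg, config$width, config$length,
                       config$exit_width, config$waiting_depth,
                       min_agent_diameter = 2 * config$agent_b)
  state <- init_state(arena, config, seed)
  n_steps <- ceiling(config$max_time / config$dt)
  par <- cpp_par(config, arena, n_steps, record = TRUE, behavior = TRUE,
                 psych = TRUE, vdes_fixed = NULL, t0 = 0,
                 active0 = state$active)
  res <- run_sim_cpp(state$pos, state$vel, state$phi, state$a, state$b,
                     state$mass, state$desired_speed, state$right_first,
                     arena$walls, arena$corners, par)
  state <- state_from_cpp(state, res)
  tr <- as.data.frame(res$track)
  tracks <- data.frame(trial_id = as.integer(trial_id),
                       frame = as.integer(tr$frame),
                       time_s = tr$time_s,
                       agent_id = as.integer(tr$agent_id),
                       x_m = tr$x_m, y_m = tr$y_m,
                       orientation_rad = tr$orientation_rad,
                       vx_mps = tr$vx_mps, vy_mps = tr$vy_mps,
                       status = ifelse(tr$status > 0.5, "exited",
                                       "evacuating"))
  exited <- which(!is.na(state$exit_time))
  events <- data.frame(trial_id = as.integer(trial_id),
                       agent_id = as.integer(exited),
                       exit_time_s = state$exit_time[exited])
  events <- events[order(events$exit_time_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(tracks = tracks, events = events, state = state,
                 arena = arena, config = config, seed = seed),
            class = "evac_run")
}
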