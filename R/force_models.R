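#' Contact parameters
#'
#' Linear spring-dashpot contact parameters. Defaults are the mouse-scale
#' simulation values: normal and tangential spring constants 5.0e4 N/m,
#' coefficient of restitution 0.1, coefficient of friction 0.1. The dashpot
#' damping is not a free parameter; it is derived from the restitution via
#' [damping_coefficient()].
#'
#' @param k_normal normal spring constant (N/m), `> 0`.
#' @param k_tangential tangential spring constant (N/m), `>= 0`.
#' @param restitution coefficient of restitution, in `(0, 1]`.
#' @param friction Coulomb friction coefficient, `>= 0`.
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(k_normal = 5.0e4, k_tangential = 5.0e4,
                           restitution = 0.1, friction = 0.1) {
  if (k_normal <= 0) stop("k_normal must be positive")
  if (k_tangential < 0) stop("k_tangential must be non-negative")
  if (restitution <= 0 || restitution > 1)
    stop("restitution must be in (0, 1]")
  if (friction < 0) stop("friction must be non-negative")
  structure(list(k_normal = k_normal, k_tangential = k_tangential,
                 restitution = restitution, friction = friction),
            class = "contact_params")
}

#' Dashpot damping from the coefficient of restitution
#'
#' For the linear spring-dashpot contact the restitution of a binary
#' collision is `exp(-gamma * pi / omega_d)` with `gamma = eta / (2 m_eff)`
#' and `omega_d = sqrt(k / m_eff - gamma^2)`. Inverting gives
#' `eta = 2 (-ln e) sqrt(m_eff k) / sqrt(pi^2 + ln(e)^2)`.
#'
#' @param restitution coefficient of restitution `e`, in `(0, 1]`; the
#'   linear dashpot cannot realize `e = 0` (perfect plasticity).
#' @param m_eff effective mass (kg): `m_i m_j / (m_i + m_j)` for a pair,
#'   the agent mass for an immobile wall.
#' @param k normal spring constant (N/m).
#' @return Damping coefficient eta (N s/m); 0 in the elastic limit `e = 1`.
#' @examples
#' damping_coefficient(1, 0.015, 5e4)    # 0: elastic
#' damping_coefficient(0.1, 0.015, 5e4)  # heavily damped mouse-scale pair
#' @export
damping_coefficient <- function(restitution, m_eff, k) {
  if (restitution <= 0)
    stop("restitution must be > 0: a linear dashpot cannot realize e = 0")
  if (restitution > 1) stop("restitution must be <= 1")
  if (m_eff <= 0 || k <= 0) stop("m_eff and k must be positive")
  if (restitution == 1) return(0)
  le <- log(restitution)
  2 * (-le) * sqrt(m_eff * k) / sqrt(pi^2 + le^2)
}

#' Spring-dashpot contact force
#'
#' Normal component `(k delta - eta * (v_rel . n)) n` (repulsive along the
#' contact normal, which points from the other body toward the subject;
#' `v_rel` is subject velocity minus other velocity). The tangential
#' component is a spring on the accumulated tangential stretch, capped by
#' Coulomb friction at `mu * |F_normal|`; with zero stretch (the default,
#' appropriate at first touch) it vanishes.
#'
#' @param contact a `contact_info` from [ellipse_overlap()] or
#'   [segment_contact()]; `delta` must be positive.
#' @param v_rel relative velocity of the subject against the other body
#'   (m/s), length 2.
#' @param params a [contact_params()].
#' @param m_eff effective mass (kg) used to derive the damping.
#' @param tangential_stretch accumulated tangential spring stretch (m),
#'   length 2; maintained across a persisting contact by the simulator.
#' @return Numeric length 2, total contact force on the subject (N), with
#'   attributes `normal` and `tangential` holding the two components.
#' @export
contact_force <- function(contact, v_rel, params, m_eff,
                          tangential_stretch = c(0, 0)) {
  stopifnot(inherits(contact, "contact_info"),
            inherits(params, "contact_params"))
  if (!is.numeric(contact$delta) || contact$delta <= 0)
    stop("contact_force requires a positive overlap delta")
  n <- contact$normal
  eta <- damping_coefficient(params$restitution, m_eff, params$k_normal)
  vn <- sum(v_rel * n)
  fn_scalar <- params$k_normal * contact$delta - eta * vn
  f_n <- fn_scalar * n
  xi <- tangential_stretch - sum(tangential_stretch * n) * n
  f_t <- -params$k_tangential * xi
  cap <- params$friction * abs(fn_scalar)
  ftm <- sqrt(sum(f_t^2))
  if (ftm > cap) f_t <- if (ftm > 0) f_t * (cap / ftm) else c(0, 0)
  structure(f_n + f_t, normal = f_n, tangential = f_t)
}

#' Psychological driving force
#'
#' The force with which an agent relaxes its current velocity toward its
#' desired velocity: `F = (m / dt_res) (v_desired - v_current)`. The gain
#' `c = m / dt_res` is derived from the agent mass and the response time
#' (0.1 s by default), so a free agent approaches its desired speed
#' exponentially with time constant `dt_res`. Evaluating the same force in
#' a frame rotated to the desired direction (with the cross component of
#' the desired velocity zero) composes to the identical global vector.
#'
#' @param v_current current velocity (m/s), length 2.
#' @param v_desired desired velocity (m/s), length 2.
#' @param mass agent mass (kg).
#' @param dt_res response time (s), `> 0`.
#' @return Numeric length 2 force (N).
#' @examples
#' psychological_force(c(0, 0), c(0.2, 0), mass = 0.03, dt_res = 0.1)
#' @export
psychological_force <- function(v_current, v_desired, mass, dt_res = 0.1) {
  if (dt_res <= 0) stop("dt_res must be positive")
  stopifnot(length(v_current) == 2, length(v_desired) == 2)
  (mass / dt_res) * (v_desired - v_current)
}
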