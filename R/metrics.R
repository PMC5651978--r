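#' Mean speed of one tracked agent
#'
#' Instantaneous speeds are finite differences of position over the frame
#' interval: central differences at interior frames, one-sided at the
#' ends (tracking exports carry positions, not velocities). The mean of
#' these `n` measurements from the agent's start to its exit is the
#' agent's mean speed.
#'
#' @param track data frame with columns `time_s`, `x_m`, `y_m` for a
#'   single agent in a single trial, ordered or orderable by time; at
#'   least two samples.
#' @return Mean speed (m/s).
#' @examples
#' tr <- data.frame(time_s = 0:4 / 30, x_m = 0.2 * (0:4) / 30, y_m = 0)
#' agent_mean_speed(tr)  # 0.2
#' @export
agent_mean_speed <- function(track) {
  o <- order(track$time_s)
  t <- track$time_s[o]
  x <- track$x_m[o]
  y <- track$y_m[o]
  n <- length(t)
  if (n < 2) stop("mean speed undefined: need at least two samples")
  mean(track_speeds(t, x, y))
}

# finite-difference speeds: central interior, one-sided ends
track_speeds <- function(t, x, y) {
  n <- length(t)
  sp <- numeric(n)
  sp[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) / (t[2] - t[1])
  sp[n] <- sqrt((x[n] - x[n - 1])^2 + (y[n] - y[n - 1])^2) /
    (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    sp[i] <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2) /
      (t[i + 1] - t[i - 1])
  }
  sp
}

#' Evacuation metrics from trajectories and exit events
#'
#' Computes the full measurement layer: per-agent mean speeds, their
#' per-trial mean, the per-angle mean over cases (the total average
#' velocity), the per-trial evacuation span `T_evc` (last exit minus first
#' start), the per-trial mean individual evacuation time `t_evc`, their
#' per-angle means, the per-angle velocity dispersion and its across-angle
#' mean. An agent's start time is its first tracked frame (partition
#' removal at t = 0 in simulation); its exit time comes from the event
#' list. Only frames up to the exit are used for the mean speed.
#'
#' @param tracks trajectory data frame (columns trial_id, time_s,
#'   agent_id, x_m, y_m, ...), e.g. from [sim_run()], [sim_sweep()] or
#'   [read_tracks()].
#' @param events exit events (trial_id, agent_id, exit_time_s).
#' @param trials data frame mapping `trial_id` to `angle`; if NULL all
#'   trials form one unnamed condition.
#' @param population logical; divide the dispersion by N (population
#'   convention, the default) rather than N - 1.
#' @return A list of class `evac_metrics` with data frames `per_agent`
#'   (trial_id, agent_id, start_s, exit_s, v_mean), `per_trial` (trial_id,
#'   angle, n_agents, v_mean_trial, T_evc, t_evc, s_v), `per_angle`
#'   (angle, V_total, T_evc, t_evc, S_mice) and the scalar `S_uni`
#'   (mean of S_mice across angles).
#' @export
evac_metrics <- function(tracks, events, trials = NULL, population = TRUE) {
  if (nrow(tracks) == 0 || nrow(events) == 0)
    stop("empty trial: no trajectory or exit data")
  if (is.null(trials))
    trials <- data.frame(trial_id = unique(tracks$trial_id), angle = NA_real_)
  key <- interaction(tracks$trial_id, tracks$agent_id, drop = TRUE)
  exit_of <- stats::setNames(events$exit_time_s,
                             paste(events$trial_id, events$agent_id))
  groups <- split(seq_len(nrow(tracks)), key)
  per_agent <- do.call(rbind, lapply(groups, function(idx) {
    tr <- tracks[idx, ]
    tr <- tr[order(tr$time_s), ]
    ex <- unname(exit_of[paste(tr$trial_id[1], tr$agent_id[1])])
    if (is.null(ex)) ex <- NA_real_
    use <- if (is.na(ex)) tr else tr[tr$time_s <= ex + 1e-12, ]
    data.frame(trial_id = tr$trial_id[1], agent_id = tr$agent_id[1],
               start_s = tr$time_s[1], exit_s = ex,
               v_mean = agent_mean_speed(use))
  }))
  rownames(per_agent) <- NULL
  per_agent <- per_agent[order(per_agent$trial_id, per_agent$agent_id), ]

  per_trial <- do.call(rbind, lapply(split(per_agent, per_agent$trial_id),
                                     function(pa) {
    ex <- pa$exit_s[!is.na(pa$exit_s)]
    if (length(ex) == 0)
      stop("empty trial: no exit events for trial ", pa$trial_id[1])
    n <- nrow(pa)
    dur <- pa$exit_s[!is.na(pa$exit_s)] - pa$start_s[!is.na(pa$exit_s)]
    sv <- if (n >= 2) pop_sd(pa$v_mean, population) else NA_real_
    data.frame(trial_id = pa$trial_id[1], n_agents = n,
               v_mean_trial = mean(pa$v_mean),
               T_evc = max(ex) - min(pa$start_s), t_evc = mean(dur),
               s_v = sv)
  }))
  rownames(per_trial) <- NULL
  per_trial$angle <- trials$angle[match(per_trial$trial_id, trials$trial_id)]
  per_trial <- per_trial[, c("trial_id", "angle", "n_agents", "v_mean_trial",
                             "T_evc", "t_evc", "s_v")]

  angle_f <- factor(per_trial$angle, exclude = NULL)  # keep unnamed group
  per_angle <- do.call(rbind, lapply(split(per_trial, angle_f),
                                     function(pt) {
    data.frame(angle = pt$angle[1], n_cases = nrow(pt),
               V_total = mean(pt$v_mean_trial), T_evc = mean(pt$T_evc),
               t_evc = mean(pt$t_evc), S_mice = mean(pt$s_v))
  }))
  rownames(per_angle) <- NULL
  structure(list(per_agent = per_agent, per_trial = per_trial,
                 per_angle = per_angle, S_uni = mean(per_angle$S_mice)),
            class = "evac_metrics")
}

pop_sd <- function(x, population = TRUE) {
  n <- length(x)
  if (population) sqrt(sum((x - mean(x))^2) / n) else sd(x)
}

#' Velocity dispersion across trials and angles
#'
#' Per trial, the standard deviation (population convention by default:
#' divisor N) of the per-agent mean speeds about the trial mean; per
#' angle, the mean of that value over the cases (a double average over
#' agents and cases); and the across-angle mean of the per-angle values
#' (the uniform dispersion).
#'
#' @param per_agent data frame with columns `trial_id`, `angle`, `v_mean`
#'   (one row per agent); every trial needs at least two agents.
#' @param population divisor N (`TRUE`, default) or N - 1.
#' @return List with `S_trial` (trial_id, angle, s_v), `S_mice` (angle,
#'   S_mice) and scalar `S_uni = mean(S_mice)`.
#' @export
velocity_dispersion <- function(per_agent, population = TRUE) {
  stopifnot(all(c("trial_id", "angle", "v_mean") %in% names(per_agent)))
  s_trial <- do.call(rbind, lapply(split(per_agent, per_agent$trial_id),
                                   function(pa) {
    if (nrow(pa) < 2)
      stop("velocity dispersion undefined for a single-agent trial")
    data.frame(trial_id = pa$trial_id[1], angle = pa$angle[1],
               s_v = pop_sd(pa$v_mean, population))
  }))
  rownames(s_trial) <- NULL
  s_mice <- do.call(rbind, lapply(split(s_trial, s_trial$angle),
                                  function(st) {
    data.frame(angle = st$angle[1], S_mice = mean(st$s_v))
  }))
  rownames(s_mice) <- NULL
  list(S_trial = s_trial, S_mice = s_mice, S_uni = mean(s_mice$S_mice))
}
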