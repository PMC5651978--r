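#' Specify a synthetic tracking-export fixture
#'
#' Describes straight-line trajectories with known speeds and exit times,
#' emulating the structure of a tracking-software export (frames at a
#' fixed video-rate interval, one row per agent per frame) so the metrics
#' and burst layers can be exercised against closed-form expectations
#' without any experimental data.
#'
#' @param cases list of cases; each case is a list with `trial_id`,
#'   `angle`, `speeds` (per-agent constant speeds, or a list of
#'   per-frame-interval piecewise-constant speed vectors) and
#'   `exit_times` (s, positive and finite, one per agent).
#' @param frame_dt frame interval (s); default 1/30 s (video rate).
#' @param seed integer seed for the (arbitrary) headings and start points.
#' @return An object of class `synthetic_track_spec`.
#' @export
synthetic_track_spec <- function(cases, frame_dt = 1 / 30, seed = 1) {
  if (frame_dt <= 0) stop("frame_dt must be positive")
  for (cs in cases) {
    if (any(!is.finite(cs$exit_times)) || any(cs$exit_times <= 0))
      stop("exit times must be positive and finite")
  }
  structure(list(cases = cases, frame_dt = frame_dt, seed = seed),
            class = "synthetic_track_spec")
}

# closed-form mean of the finite-difference speed estimates (central at
# interior frames, one-sided at the ends) for a straight-line trajectory
# with per-interval speeds s[1..K], sampled at K + 1 frames
fd_mean_speed <- function(s) {
  K <- length(s)
  if (K == 1) return(s[1])
  (s[1] + s[K] + sum((s[-K] + s[-1]) / 2)) / (K + 1)
}

#' Generate synthetic tracks with closed-form expected metrics
#'
#' Straight-line trajectories at the specified speeds, sampled at the
#' frame interval and truncated at each agent's exit time, together with
#' the exactly computable expected metrics (per-agent mean speeds, trial
#' and angle aggregates, evacuation times, dispersion). The expectations
#' are computed directly from the speed values, independently of the
#' trajectory construction, which makes the generator an oracle for the
#' metrics pipeline.
#'
#' @param spec a [synthetic_track_spec()].
#' @return List with `tracks`, `events` (the CSV dialects of
#'   [write_tracks()] / [write_events()]), `trials` (trial_id, angle) and
#'   `expected` (data frames `per_agent`, `per_trial`, `per_angle`, scalar
#'   `S_uni`; population-sd convention).
#' @export
generate_tracks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_track_spec"))
  dtf <- spec$frame_dt
  tracks <- list()
  events <- list()
  pa <- list()
  with_seed(spec$seed, {
    for (cs in spec$cases) {
      n <- length(cs$exit_times)
      headings <- runif(n, 0, 2 * pi)
      starts <- cbind(runif(n, 0, 1), runif(n, 0, 1))
      for (i in seq_len(n)) {
        K <- floor(cs$exit_times[i] / dtf + 1e-9)
        if (K < 1)
          stop("exit time shorter than one frame for agent ", i,
               " in trial ", cs$trial_id)
        s <- if (is.list(cs$speeds)) {
          if (length(cs$speeds[[i]]) < K)
            stop("piecewise speed profile shorter than the track")
          cs$speeds[[i]][seq_len(K)]
        } else rep(cs$speeds[i], K)
        u <- c(cos(headings[i]), sin(headings[i]))
        dist <- c(0, cumsum(s * dtf))
        tracks[[length(tracks) + 1]] <- data.frame(
          trial_id = cs$trial_id, frame = 0:K, time_s = (0:K) * dtf,
          agent_id = i, x_m = starts[i, 1] + dist * u[1],
          y_m = starts[i, 2] + dist * u[2],
          orientation_rad = headings[i] %% pi, vx_mps = NA_real_,
          vy_mps = NA_real_, status = "evacuating")
        pa[[length(pa) + 1]] <- data.frame(
          trial_id = cs$trial_id, angle = cs$angle, agent_id = i,
          v_mean = fd_mean_speed(s))
      }
      events[[length(events) + 1]] <- data.frame(
        trial_id = cs$trial_id, agent_id = seq_len(n),
        exit_time_s = cs$exit_times)
    }
  })
  per_agent <- do.call(rbind, pa)
  per_trial <- do.call(rbind, lapply(split(per_agent, per_agent$trial_id),
                                     function(p) {
    ev <- events[[which(vapply(events, function(e) e$trial_id[1],
                               0) == p$trial_id[1])]]
    data.frame(trial_id = p$trial_id[1], angle = p$angle[1],
               v_mean_trial = mean(p$v_mean),
               T_evc = max(ev$exit_time_s), t_evc = mean(ev$exit_time_s),
               s_v = pop_sd(p$v_mean))
  }))
  rownames(per_trial) <- NULL
  per_angle <- do.call(rbind, lapply(split(per_trial, per_trial$angle),
                                     function(p) {
    data.frame(angle = p$angle[1], V_total = mean(p$v_mean_trial),
               T_evc = mean(p$T_evc), t_evc = mean(p$t_evc),
               S_mice = mean(p$s_v))
  }))
  rownames(per_angle) <- NULL
  list(tracks = do.call(rbind, tracks), events = do.call(rbind, events),
       trials = unique(per_agent[, c("trial_id", "angle")]),
       expected = list(per_agent = per_agent, per_trial = per_trial,
                       per_angle = per_angle,
                       S_uni = mean(per_angle$S_mice)))
}

#' Bundled trend-shaped fixture preset
#'
#' A synthetic fixture emulating the experiment's structure (50 agents, 3
#' cases per angle, 6 guide-wall angles) with per-angle mean speeds and
#' speed dispersions decreasing with angle and evacuation spans shrinking
#' with angle, so the whole analysis path can be demonstrated end to end
#' without running the simulator.
#'
#' @param n_agents agents per case.
#' @param cases cases per angle.
#' @param angles guide-wall angles (degrees).
#' @param frame_dt frame interval (s).
#' @param seed integer seed.
#' @return A [synthetic_track_spec()].
#' @export
fis_track_preset <- function(n_agents = 50, cases = 3,
                             angles = seq(0, 75, by = 15),
                             frame_dt = 1 / 30, seed = 1) {
  cs <- list()
  with_seed(seed, {
    tid <- 0
    for (ang in angles) {
      mean_v <- 0.45 - ang / 300      # 0.45 -> 0.20 m/s
      sd_v <- 0.10 - 0.001 * ang      # 0.10 -> 0.025 m/s
      t_max <- 30 - 0.24 * ang        # 30 -> 12 s evacuation span
      for (k in seq_len(cases)) {
        tid <- tid + 1
        cs[[tid]] <- list(
          trial_id = tid, angle = ang,
          speeds = sample_desired_speeds(n_agents, mean_v, sd_v),
          exit_times = sort(runif(n_agents, 2 * frame_dt, t_max)))
      }
    }
  })
  synthetic_track_spec(cs, frame_dt = frame_dt, seed = seed + 1)
}
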