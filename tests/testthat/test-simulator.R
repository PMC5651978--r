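test_that("arena construction closes the boundary and honors the angle", {
  ar <- build_arena(0)
  # theta = 0: guide walls collinear with the exit wall (plain opening)
  expect_equal(unname(ar$walls[4, c("p1y", "p2y")]),
               c(ar$length, ar$length))
  expect_equal(unname(ar$walls[5, c("p1y", "p2y")]),
               c(ar$length, ar$length))
  # wall endpoints chain into a closed boundary with only the exit open
  ar75 <- build_arena(75)
  expect_equal(unname(ar75$walls[2, c("p2x", "p2y")]),
               unname(ar75$walls[4, c("p1x", "p1y")]))
  expect_equal(unname(ar75$walls[3, c("p2x", "p2y")]),
               unname(ar75$walls[5, c("p1x", "p1y")]))
  # guide-wall direction is the theta = 0 direction rotated by theta
  # about the gap edge
  d75 <- ar75$walls[5, c("p2x", "p2y")] - ar75$walls[5, c("p1x", "p1y")]
  d75 <- d75 / sqrt(sum(d75^2))
  th <- 75 * pi / 180
  expect_equal(unname(d75), c(-cos(th), sin(th)), tolerance = 1e-12)
  # funnel depth from plane trigonometry
  expect_equal(unname(ar75$walls[5, "p1y"]),
               ar75$length - tan(th) * (ar75$width - ar75$exit_width) / 2,
               tolerance = 1e-12)
})

test_that("invalid arenas are rejected", {
  expect_error(build_arena(95), "\\[0, 90\\)")
  expect_error(build_arena(-5), "\\[0, 90\\)")
  expect_error(build_arena(0, exit_width = 0.02), "narrower")
  expect_error(build_arena(89, length = 0.85), "waiting area")
})

test_that("desired-speed sampling honors mean, sd and positivity", {
  expect_equal(sample_desired_speeds(5, 0.4, 0, seed = 1), rep(0.4, 5))
  s <- sample_desired_speeds(10000, 0.4, 0.15, seed = 2)
  expect_true(all(s > 0))
  expect_equal(sd(s), 0.15, tolerance = 0.03)
  # heavy truncation keeps positivity but shrinks the spread
  expect_true(all(sample_desired_speeds(2000, 0.1, 0.2, seed = 7) > 0))
  s2 <- sample_desired_speeds(1000, 0.4, 0.2, seed = 3, min = 0.05)
  expect_true(all(s2 > 0.05))
  expect_error(sample_desired_speeds(5, -1, 0.1), "mean")
})

test_that("force-free motion is uniform and straight", {
  cfg <- sim_config(n_agents = 1, dt = 1e-3)
  st <- new_state(matrix(c(0.1, 0.2), 1), vel = matrix(c(0.3, -0.1), 1))
  out <- sim_step(st, NULL, cfg, n_steps = 100, behavior = FALSE,
                  psych = FALSE, vdes_fixed = matrix(0, 1, 2))
  expect_equal(out$pos[1, ], c(0.1, 0.2) + 0.1 * c(0.3, -0.1),
               tolerance = 1e-12)
  expect_equal(out$vel[1, ], c(0.3, -0.1), tolerance = 1e-15)
})

test_that("momentum is conserved exactly in pure pair contacts", {
  cfg <- sim_config(n_agents = 2, dt = 1e-6)
  st <- new_state(rbind(c(-0.025, -0.004), c(0.025, 0.006)),
                  vel = rbind(c(0.3, 0.05), c(-0.2, -0.02)),
                  phi = c(0.4, 2.0), mass = c(0.03, 0.05))
  p0 <- colSums(st$mass * st$vel)
  out <- sim_step(st, NULL, cfg, n_steps = 20000, behavior = FALSE,
                  psych = FALSE, vdes_fixed = matrix(0, 2, 2))
  expect_equal(colSums(out$mass * out$vel), p0, tolerance = 1e-12)
})

test_that("a single agent produces exactly one exit event", {
  run <- sim_run(sim_config(n_agents = 1, max_time = 30), seed = 4)
  expect_equal(nrow(run$events), 1)
  expect_false(run$state$active[1])
  expect_equal(run$events$exit_time_s, run$state$exit_time[1])
})

test_that("agent count is conserved at every recorded frame and exited
           agents never re-enter", {
  run <- sim_run(sim_config(n_agents = 5, max_time = 60), seed = 5)
  tr <- run$tracks
  counts <- tapply(tr$agent_id, tr$frame, function(x) length(unique(x)))
  expect_true(all(counts == 5))
  for (id in unique(tr$agent_id)) {
    s <- tr$status[tr$agent_id == id][order(tr$frame[tr$agent_id == id])]
    ex <- which(s == "exited")
    if (length(ex) > 0) expect_true(all(s[seq(min(ex), length(s))] == "exited"))
  }
})

test_that("identical seeds reproduce bit-identical runs", {
  r1 <- sim_run(sim_config(n_agents = 6, max_time = 60), seed = 9)
  r2 <- sim_run(sim_config(n_agents = 6, max_time = 60), seed = 9)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$tracks, r2$tracks)
  r3 <- sim_run(sim_config(n_agents = 6, max_time = 60), seed = 10)
  expect_false(identical(r1$events, r3$events))
})

test_that("agents stay inside the arena up to transient overlap", {
  run <- sim_run(sim_config(n_agents = 10, max_time = 60), seed = 6)
  tr <- run$tracks[run$tracks$status == "evacuating", ]
  b <- run$config$agent_b
  expect_true(all(tr$x_m > -b / 2 & tr$x_m < run$arena$width + b / 2))
  expect_true(all(tr$y_m > -b / 2 & tr$y_m < run$arena$length + b / 2))
})

test_that("initialization rejects an overfull waiting area", {
  cfg <- sim_config(n_agents = 200)
  arena <- build_arena(0)
  expect_error(init_state(arena, cfg, seed = 1), "waiting area")
})

test_that("sweep trials carry the per-angle conditions and seeds", {
  prof <- fis_speed_profile()
  expect_equal(prof$angle, seq(0, 75, by = 15))
  expect_true(all(diff(prof$mean) < 0) && all(diff(prof$sd) < 0))
  cfg <- sim_config(n_agents = 2, max_time = 30)
  sw <- sim_sweep(cfg, angles = c(0, 75), cases = 2, mode = "smice",
                  seed = 3)
  expect_equal(nrow(sw$trials), 4)
  expect_equal(sort(unique(sw$trials$angle)), c(0, 75))
  expect_equal(length(unique(sw$trials$seed)), 4)
  expect_true(all(sw$tracks$trial_id %in% sw$trials$trial_id))
})
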