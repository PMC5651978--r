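# small helper: a state with one focal agent at the origin heading +y
# toward an exit target, plus explicitly placed others
beh_state <- function(focal_vel, others_pos, others_vel, desired_speed = 0.4,
                      right_first = TRUE, others_speed_des = 0.4) {
  n <- 1 + NROW(others_pos)
  pos <- rbind(c(0, 0), others_pos)
  vel <- rbind(focal_vel, others_vel)
  new_state(pos, vel, desired_speed = c(desired_speed,
                                        rep(others_speed_des, n - 1)),
            right_first = c(right_first, rep(TRUE, n - 1)))
}

exit_up <- c(0, 10)  # far exit straight ahead: base direction (0, 1)

test_that("handedness counts are exact and order is shuffled", {
  h <- assign_handedness(50, 0.9, seed = 1)
  expect_length(h, 50)
  expect_equal(sum(h), 45)
  expect_equal(sum(assign_handedness(10, 0.9, seed = 2)), 9)
  expect_identical(assign_handedness(0, 0.9), logical(0))
  expect_error(assign_handedness(10, 1.2), "fraction")
  # seeded: reproducible, and not simply all-right block first
  expect_identical(assign_handedness(20, 0.5, seed = 3),
                   assign_handedness(20, 0.5, seed = 3))
})

test_that("sector density counts centers in the wedge and divides by area", {
  cfg <- behavior_config(sector_radius = 1)
  expect_identical(sector_density(c(0, 0), pi / 2, "front", NULL, cfg), 0)
  # one agent strictly inside the right sector (heading +y, axis at
  # -pi/6 off heading; 55 degrees is right-only since the wedges overlap)
  ang <- 55 * pi / 180
  p <- 0.5 * c(cos(ang), sin(ang))
  expect_equal(sector_density(c(0, 0), pi / 2, "right", rbind(p), cfg),
               6 / pi, tolerance = 1e-12)
  expect_equal(sector_density(c(0, 0), pi / 2, "left", rbind(p), cfg), 0)
  expect_equal(sector_density(c(0, 0), pi / 2, "front", rbind(p), cfg), 0)
  # outside the radius
  expect_equal(sector_density(c(0, 0), pi / 2, "right", rbind(2.2 * p), cfg),
               0)
})

test_that("alone, the desired velocity points at the exit at full speed", {
  st <- new_state(matrix(c(0.1, 0), 1), desired_speed = 0.37)
  dv <- desired_velocities(st, arena = NULL, exit_target = c(0.1, 5))
  expect_equal(dv[1, ], c(0, 0.37), tolerance = 1e-12)
})

test_that("a right-first agent overtakes a slower leader into an empty
           right sector", {
  st <- beh_state(focal_vel = c(0, 0.4),
                  others_pos = rbind(c(0, 0.05)),
                  others_vel = rbind(c(0, 0.1)))
  dv <- desired_velocities(st, NULL, exit_target = exit_up)
  ang <- atan2(dv[1, 2], dv[1, 1])
  expect_equal(ang, pi / 2 - pi / 6, tolerance = 1e-9)  # rotated right
  expect_equal(sqrt(sum(dv[1, ]^2)), 0.4, tolerance = 1e-12)
  # left-first mirror
  st$right_first[1] <- FALSE
  dv2 <- desired_velocities(st, NULL, exit_target = exit_up)
  expect_equal(atan2(dv2[1, 2], dv2[1, 1]), pi / 2 + pi / 6,
               tolerance = 1e-9)
})

test_that("the preferred side is skipped when at or above the critical
           density, strictly below passes", {
  # sector area at R = 0.12 is pi R^2/6 = 7.54e-3 m^2; one agent gives
  # 132.6 agents/m^2
  one_right <- 0.06 * c(cos(pi / 2 - pi / 6), sin(pi / 2 - pi / 6))
  st <- beh_state(c(0, 0.4),
                  others_pos = rbind(c(0, 0.05), one_right),
                  others_vel = rbind(c(0, 0.1), c(0, 0.1)))
  dens_one <- 1 / (pi * 0.12^2 / 6)
  # threshold just above the occupied-sector density: right admissible
  cfg_hi <- behavior_config(critical_density = dens_one + 1e-6)
  dv <- desired_velocities(st, NULL, cfg_hi, exit_target = exit_up)
  expect_equal(atan2(dv[1, 2], dv[1, 1]), pi / 2 - pi / 6, tolerance = 1e-9)
  # threshold just below the density: "lower than" fails, go left
  cfg_eq <- behavior_config(critical_density = dens_one - 1e-6)
  dv2 <- desired_velocities(st, NULL, cfg_eq, exit_target = exit_up)
  expect_equal(atan2(dv2[1, 2], dv2[1, 1]), pi / 2 + pi / 6,
               tolerance = 1e-9)
})

test_that("with both side sectors crowded the agent slows and follows", {
  ang_r <- pi / 2 - pi / 6
  ang_l <- pi / 2 + pi / 6
  others <- rbind(c(0.01, 0.05),                       # slower leader ahead
                  0.06 * c(cos(ang_r), sin(ang_r)),
                  0.06 * c(cos(ang_l), sin(ang_l)))
  st <- beh_state(c(0, 0.4), others,
                  others_vel = rbind(c(0, 0.12), c(0, 0.1), c(0, 0.1)))
  cfg <- behavior_config(critical_density = 50)  # one agent (133/m^2) blocks
  dv <- desired_velocities(st, NULL, cfg, exit_target = exit_up)
  spd <- sqrt(sum(dv[1, ]^2))
  expect_equal(spd, 0.12, tolerance = 1e-9)     # leader's current speed
  dir <- dv[1, ] / spd
  expect_equal(dir, c(0.01, 0.05) / sqrt(0.01^2 + 0.05^2), tolerance = 1e-9)
})

test_that("agents never overtake a faster leader or an empty front", {
  # faster leader: base direction kept
  st <- beh_state(c(0, 0.2), rbind(c(0, 0.05)), rbind(c(0, 0.5)))
  dv <- desired_velocities(st, NULL, exit_target = exit_up)
  expect_equal(dv[1, ] / sqrt(sum(dv[1, ]^2)), c(0, 1), tolerance = 1e-12)
  # agent behind (not in the front sector): base direction kept
  st2 <- beh_state(c(0, 0.4), rbind(c(0, -0.05)), rbind(c(0, 0.1)))
  dv2 <- desired_velocities(st2, NULL, exit_target = exit_up)
  expect_equal(dv2[1, ] / sqrt(sum(dv2[1, ]^2)), c(0, 1), tolerance = 1e-12)
})

test_that("desired speed never exceeds the agent's own desired speed", {
  set.seed(5)
  for (k in 1:30) {
    n <- 6
    st <- new_state(cbind(runif(n, 0, 0.25), runif(n, 0, 0.5)),
                    vel = matrix(rnorm(2 * n, 0, 0.3), n),
                    desired_speed = runif(n, 0.2, 0.6),
                    right_first = runif(n) < 0.9)
    dv <- desired_velocities(st, NULL, exit_target = c(0.125, 0.85))
    expect_true(all(sqrt(rowSums(dv^2)) <= st$desired_speed + 1e-9))
  }
})

test_that("reflecting the scene across the midline mirrors the decisions", {
  set.seed(11)
  arena <- build_arena(45)
  W <- arena$width
  for (k in 1:10) {
    n <- 8
    st <- new_state(cbind(runif(n, 0.03, W - 0.03), runif(n, 0.05, 0.45)),
                    vel = matrix(rnorm(2 * n, 0, 0.2), n),
                    desired_speed = runif(n, 0.2, 0.6),
                    right_first = runif(n) < 0.9)
    dv <- desired_velocities(st, arena)
    st_m <- st
    st_m$pos[, 1] <- W - st$pos[, 1]
    st_m$vel[, 1] <- -st$vel[, 1]
    st_m$right_first <- !st$right_first
    dv_m <- desired_velocities(st_m, arena)
    expect_equal(dv_m[, 1], -dv[, 1], tolerance = 1e-9)
    expect_equal(dv_m[, 2], dv[, 2], tolerance = 1e-9)
  }
})

test_that("identical state yields identical decisions", {
  set.seed(21)
  arena <- build_arena(30)
  n <- 10
  st <- new_state(cbind(runif(n, 0.03, 0.22), runif(n, 0.05, 0.4)),
                  vel = matrix(rnorm(2 * n, 0, 0.2), n),
                  desired_speed = runif(n, 0.2, 0.6),
                  right_first = runif(n) < 0.9)
  expect_identical(desired_velocities(st, arena),
                   desired_velocities(st, arena))
})

test_that("the desired direction steers away from a close wall", {
  arena <- build_arena(0)
  # agent hugging the left wall, exit target up and to the right
  st <- new_state(matrix(c(0.005, 0.4), 1), desired_speed = 0.4)
  dv <- desired_velocities(st, arena)
  base <- (arena$exit_target - c(0.005, 0.4))
  base <- base / sqrt(sum(base^2))
  # steered further from the wall than the plain exit direction
  expect_gt(dv[1, 1] / sqrt(sum(dv[1, ]^2)), base[1])
  # far from any wall: unchanged
  st2 <- new_state(matrix(c(0.125, 0.4), 1), desired_speed = 0.4)
  dv2 <- desired_velocities(st2, arena)
  base2 <- arena$exit_target - c(0.125, 0.4)
  expect_equal(dv2[1, ] / sqrt(sum(dv2[1, ]^2)),
               base2 / sqrt(sum(base2^2)), tolerance = 1e-9)
})

test_that("desired_velocity checks the arena bounds", {
  arena <- build_arena(0)
  st <- new_state(matrix(c(-0.1, 0.2), 1))
  expect_error(desired_velocity(1, st, arena), "outside the arena")
})
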