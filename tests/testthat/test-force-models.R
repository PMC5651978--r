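test_that("static normal force is k * delta, repulsive along the normal", {
  ct <- structure(list(delta = 1e-3, normal = c(0, 1), point = c(0, 0)),
                  class = "contact_info")
  f <- contact_force(ct, v_rel = c(0, 0), params = contact_params(),
                     m_eff = 0.015)
  expect_equal(as.numeric(f), c(0, 50), tolerance = 1e-12)
  expect_equal(attr(f, "tangential"), c(0, 0))
})

test_that("frictionless contact has no tangential component", {
  ct <- structure(list(delta = 5e-4, normal = c(1, 0), point = c(0, 0)),
                  class = "contact_info")
  f <- contact_force(ct, v_rel = c(0, 0.3), params = contact_params(friction = 0),
                     m_eff = 0.015, tangential_stretch = c(0, 1e-3))
  expect_equal(attr(f, "tangential"), c(0, 0))
})

test_that("tangential force is Coulomb-capped by mu |F_normal|", {
  ct <- structure(list(delta = 1e-3, normal = c(0, 1), point = c(0, 0)),
                  class = "contact_info")
  p <- contact_params()  # mu = 0.1, Fn = 50 N, cap 5 N
  f <- contact_force(ct, v_rel = c(0, 0), params = p, m_eff = 0.015,
                     tangential_stretch = c(1e-3, 0))  # spring force 50 N
  expect_equal(sqrt(sum(attr(f, "tangential")^2)), 5, tolerance = 1e-9)
})

test_that("non-positive overlap violates the contact-force contract", {
  ct <- structure(list(delta = 0, normal = c(0, 1), point = c(0, 0)),
                  class = "contact_info")
  expect_error(contact_force(ct, c(0, 0), contact_params(), 0.015),
               "positive overlap")
})

test_that("damping vanishes in the elastic limit and grows as e drops", {
  expect_identical(damping_coefficient(1, 0.015, 5e4), 0)
  es <- c(0.9, 0.7, 0.5, 0.3, 0.1, 0.01)
  etas <- vapply(es, damping_coefficient, 0, m_eff = 0.015, k = 5e4)
  expect_true(all(diff(etas) > 0))
  expect_error(damping_coefficient(0, 0.015, 5e4), "e = 0")
})

test_that("derived damping reproduces the restitution in an independent
           RK4 two-body integration", {
  for (e in c(0.1, 0.5, 0.9)) {
    expect_equal(oracle_restitution(e), e, tolerance = 0.02)
  }
})

test_that("a simulated head-on collision rebounds at the tabulated
           restitution", {
  cfg <- sim_config(n_agents = 2, dt = 1e-6)
  st <- new_state(rbind(c(-0.031, 0), c(0.031, 0)),
                  vel = rbind(c(0.2, 0), c(-0.2, 0)),
                  phi = c(0, 0), a = 0.03, b = 0.03)
  out <- sim_step(st, arena = NULL, config = cfg, n_steps = 40000,
                  behavior = FALSE, psych = FALSE,
                  vdes_fixed = matrix(0, 2, 2))
  ratio <- abs(out$vel[2, 1] - out$vel[1, 1]) / 0.4
  expect_equal(ratio, 0.1, tolerance = 0.02)
})

test_that("psychological force is the mass-scaled velocity gap", {
  expect_equal(psychological_force(c(0.2, 0.1), c(0.2, 0.1), 0.03), c(0, 0))
  expect_equal(psychological_force(c(0, 0), c(0.2, 0), 0.03, 0.1),
               c(0.06, 0), tolerance = 1e-15)
  expect_error(psychological_force(c(0, 0), c(1, 0), 0.03, dt_res = 0),
               "dt_res")
})

test_that("rotated-frame evaluation composes to the same global vector", {
  # frame with y-bar along the desired direction (angle theta vs x): the
  # cross component of the desired velocity vanishes and the rotated
  # components recompose to c * (v* - v0)
  set.seed(7)
  for (k in 1:100) {
    v0 <- rnorm(2, 0, 0.5)
    spd <- runif(1, 0.1, 1)
    theta <- runif(1, -pi, pi)
    vstar <- spd * c(cos(theta), sin(theta))
    m <- 0.03; dtr <- 0.1; cc <- m / dtr
    R <- cbind(c(sin(theta), -cos(theta)), c(cos(theta), sin(theta)))
    v0_bar <- drop(t(R) %*% v0)
    vstar_bar <- c(0, spd)
    f_rot <- cc * drop(R %*% (vstar_bar - v0_bar))
    expect_equal(f_rot, psychological_force(v0, vstar, m, dtr),
                 tolerance = 1e-12)
  }
})

test_that("pair forces obey Newton's third law", {
  set.seed(13)
  for (k in 1:20) {
    p <- random_ellipse_pair()
    ci <- ellipse_overlap(p[[1]], p[[2]])
    if (is.null(ci)) next
    cj <- ellipse_overlap(p[[2]], p[[1]])
    vrel <- rnorm(2, 0, 0.3)
    xi <- rnorm(2, 0, 1e-4)
    fi <- contact_force(ci, vrel, contact_params(), 0.015, xi)
    fj <- contact_force(cj, -vrel, contact_params(), 0.015, -xi)
    expect_equal(as.numeric(fi), -as.numeric(fj), tolerance = 1e-8)
  }
})

test_that("binary collisions with e < 1 dissipate kinetic energy", {
  cfg <- sim_config(n_agents = 2, dt = 1e-6)
  st <- new_state(rbind(c(-0.028, -0.003), c(0.028, 0.003)),
                  vel = rbind(c(0.25, 0.02), c(-0.2, 0)),
                  phi = c(0.2, 1.1))
  ke <- function(s) sum(0.5 * s$mass * rowSums(s$vel^2))
  out <- sim_step(st, NULL, cfg, n_steps = 30000, behavior = FALSE,
                  psych = FALSE, vdes_fixed = matrix(0, 2, 2))
  expect_lt(ke(out), ke(st))
})

test_that("a free agent relaxes exponentially at the response time", {
  cfg <- sim_config(n_agents = 1, dt = 1e-3)
  st <- new_state(matrix(c(0, 0), 1), desired_speed = 0.4)
  vd <- matrix(c(0.4, 0), 1)
  # closed form v(t) = v*(1 - exp(-t / dt_res)) at sampled times
  for (nst in c(50, 100, 200)) {
    out <- sim_step(st, NULL, cfg, n_steps = nst, behavior = FALSE,
                    psych = TRUE, vdes_fixed = vd)
    t <- nst * 1e-3
    expect_equal(out$vel[1, 1], 0.4 * (1 - exp(-t / 0.1)),
                 tolerance = 6e-3)
  }
})
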