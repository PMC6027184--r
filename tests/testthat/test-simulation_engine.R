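# local helpers (independent of package internals)
quat_from_axis_angle_test2 <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * a)
}
extract_flexion <- function(tr) {
  q <- tr$poses$ulna[, 4:7]
  2 * atan2(q[, 2L], q[, 1L]) * 180 / pi
}

# rigid-body integration primitives, the two-phase protocol, conservation

static_trial <- function(bodies, n = 3L, dt = 0.01, poses = NULL) {
  if (is.null(poses))
    poses <- stats::setNames(rep(list(c(0, 0, 0, 1, 0, 0, 0)), length(bodies)),
                             bodies)
  motion_trial("static", seq(0, by = dt, length.out = n),
               lapply(poses, function(p) matrix(rep(p, each = n), n, 7L)))
}

test_that("step_dynamics obeys the explicit velocity update", {
  st <- list(xc = c(0, 0, 0), vc = c(1, 2, 3), q = c(1, 0, 0, 0),
             L = c(0, 0, 0))
  # zero wrench: twist unchanged, position advances
  s2 <- step_dynamics(st, mass = 2, inertia = diag(3),
                      wrench = list(F = c(0, 0, 0), tau = c(0, 0, 0)),
                      dt = 0.01)
  expect_equal(s2$vc, st$vc)
  expect_equal(s2$L, st$L)
  expect_equal(s2$xc, st$xc + 0.01 * st$vc)
  # constant force: dv = 1000 F/m dt exactly
  s3 <- step_dynamics(st, mass = 2, inertia = diag(3),
                      wrench = list(F = c(0.5, 0, 0), tau = c(0, 0, 0)),
                      dt = 0.01)
  expect_equal(s3$vc - st$vc, c(1000 * 0.5 / 2 * 0.01, 0, 0))
  expect_error(step_dynamics(st, 2, diag(3),
                             list(F = c(NaN, 0, 0), tau = c(0, 0, 0)), 0.01),
               "non-finite")
})

test_that("torque-free symmetric top conserves angular momentum over 10 s", {
  I_body <- diag(c(400, 400, 800))      # symmetric top, kg mm^2
  st <- list(xc = c(0, 0, 0), vc = c(0, 0, 0),
             q = quat_from_axis_angle_test2(c(0, 1, 0), 0.3),
             L = c(50, 0, 900))
  L0 <- sqrt(sum(st$L^2))
  E0 <- NA
  dt <- 1e-3
  for (k in seq_len(10000L)) {
    st <- step_dynamics(st, mass = 1, inertia = I_body,
                        wrench = list(F = c(0, 0, 0), tau = c(0, 0, 0)),
                        dt = dt)
  }
  expect_lt(abs(sqrt(sum(st$L^2)) - L0) / L0, 1e-3)   # |L| within 0.1%
  expect_equal(sqrt(sum(st$q^2)), 1, tolerance = 1e-12)
})

test_that("the model audit reports 18 DOF and zero constraint equations", {
  sub <- default_subject()
  dof <- model_dof(sub$model)
  expect_equal(dof$n_bodies, 3L)
  expect_equal(dof$dof, 18L)
  expect_equal(dof$constraint_equations, 0L)
})

test_that("inverse kinematics replays poses and records muscle lengths", {
  cm <- calibrated_model()
  model <- cm$model
  # static trial: targets constant and equal to the static lengths
  tr <- static_trial(names(model$bodies), n = 5L)
  ik <- run_inverse_kinematics(model, tr)
  expect_equal(dim(ik$lengths), c(5L, 6L))
  poses0 <- list(humerus = pose(), ulna = pose(), radius = pose())
  for (j in seq_along(model$muscles))
    expect_equal(ik$lengths[, j],
                 rep(muscle_length(model$muscles[[j]], poses0), 5L),
                 ignore_attr = TRUE)

  # pure (noise-free) flexion: flexor targets shorten monotonically
  spec <- trial_spec("60deg/s", noise_pos = 0, noise_deg = 0, hold = 0)
  tr2 <- generate_trial(model, spec)
  ik2 <- run_inverse_kinematics(model, tr2)
  up <- which(diff(extract_flexion(tr2)) > 1e-6)   # flexion-increasing frames
  for (mn in c("brachialis", "biceps-long", "biceps-short"))
    expect_true(all(diff(ik2$lengths[up, mn]) < 0))
  # extensor lengthens
  expect_true(all(diff(ik2$lengths[up, "triceps-long"]) > 0))
})

test_that("free bodies in equilibrium stay put; gravity gives 1/2 g t^2", {
  ball <- rigid_body("ball", mass = 0.5, inertia = diag(c(100, 100, 100)))
  m0 <- elbow_model(list(ball = ball), gravity = c(0, 0, 0),
                    free_bodies = "ball")
  tr <- static_trial("ball", n = 3L)
  res <- run_forward_dynamics(m0, tr, dt = 1e-3, duration = 0.5)
  expect_equal(res$poses$ball[, "z"], rep(0, length(res$time)))
  expect_equal(res$poses$ball[, "qw"], rep(1, length(res$time)))

  m1 <- elbow_model(list(ball = ball), gravity = c(0, 0, -9810),
                    free_bodies = "ball")
  res1 <- run_forward_dynamics(m1, tr, dt = 1e-4, duration = 1)
  z_end <- unname(res1$poses$ball[length(res1$time), "z"])
  expect_equal(z_end, -0.5 * 9810 * 1^2, tolerance = 2e-4)

  # duration 0: empty result, clean return
  res0 <- run_forward_dynamics(m1, tr, dt = 1e-3, duration = 0)
  expect_s3_class(res0, "simulation_result")
  expect_equal(length(res0$time), 0L)
})

test_that("forward dynamics is deterministic", {
  cm <- calibrated_model()
  spec <- trial_spec("60deg/s", seed = 3L)
  tr <- generate_trial(cm$model, spec)
  r1 <- run_forward_dynamics(cm$model, tr, dt = 5e-4, duration = 0.2)
  r2 <- run_forward_dynamics(cm$model, tr, dt = 5e-4, duration = 0.2)
  expect_identical(r1$poses, r2$poses)
  expect_identical(r1$muscle_forces, r2$muscle_forces)
})

test_that("energy drifts less than 1 percent with conservative forces only", {
  # pendulum-like configuration: the ulna segment swinging on two elastic
  # bundles under gravity; no contact, no muscles, no dampers
  ulna <- rigid_body("ulna", mass = 0.7,
                     inertia = diag(c(3600, 3600, 330)), com = c(0, 0, -130))
  hum <- rigid_body("humerus", mass = 0.5, inertia = diag(c(2e3, 2e3, 300)),
                    com = c(0, 0, 80))
  lig <- ligament_complex(list(
    ligament_bundle("a-1", list(body = "humerus", point = c(10, 0, 2)),
                    list(body = "ulna", point = c(8, 0, -12)), k = 500,
                    l0 = 12),
    ligament_bundle("a-2", list(body = "humerus", point = c(-10, 0, 2)),
                    list(body = "ulna", point = c(-8, 0, -12)), k = 500,
                    l0 = 12)))
  model <- elbow_model(list(humerus = hum, ulna = ulna), ligaments = lig,
                       free_bodies = "ulna")
  tr <- static_trial(c("humerus", "ulna"))
  res <- run_forward_dynamics(model, tr, dt = 1e-4, duration = 10,
                              dt_output = 0.05, record_energy = TRUE)
  E <- res$energy
  expect_true(all(is.finite(E)))
  scale <- max(abs(E - E[1L]))  # guard degenerate zero-range
  expect_lt(max(abs(E - E[1L])) / max(abs(E[1L]), diff(range(E)), 1e-6), 0.01)
  # drift relative to the initial total energy magnitude
  expect_lt(abs(E[length(E)] - E[1L]) / max(abs(E[1L]), 1e-6), 0.01)
})

test_that("divergent simulations fail with step provenance", {
  ball <- rigid_body("ball", mass = 1e-9, inertia = diag(3) * 1e-9)
  m <- elbow_model(list(ball = ball), gravity = c(0, 0, -9.81e20),
                   free_bodies = "ball")
  tr <- static_trial("ball")
  expect_error(run_forward_dynamics(m, tr, dt = 0.01, duration = 1),
               "solver error|divergence")
})
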