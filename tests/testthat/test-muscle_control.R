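# PCSA gain scaling, muscle paths, PID behaviour, force application

test_that("gains scale linearly with PCSA from the global values", {
  g <- scale_gains(487)
  expect_equal(unname(g), c(50, 5, 5e-4))
  g2 <- scale_gains(974)
  expect_equal(unname(g2), c(100, 10, 1e-3))
  # linearity over a sweep
  pcsa <- seq(50, 2000, by = 50)
  P <- vapply(pcsa, function(a) scale_gains(a)[["P"]], 0)
  expect_equal(P, 50 * pcsa / 487)
  expect_error(scale_gains(0), "PCSA")
  expect_error(gain_schedule(P = -1), "> 0")
})

test_that("muscle lengths follow the polyline under body motion", {
  m <- muscle_actuator("m1", list(body = "a", point = c(0, 0, 0)),
                       list(body = "b", point = c(100, 0, 0)), PCSA = 487)
  poses <- list(a = pose(), b = pose())
  expect_equal(muscle_length(m, poses), 100)

  m2 <- muscle_actuator("m2", list(body = "a", point = c(0, 0, 0)),
                        list(body = "b", point = c(10, 0, 0)), PCSA = 487,
                        via_points = list(list(body = "a",
                                               point = c(5, 5, 0))))
  expect_equal(muscle_length(m2, poses), 2 * sqrt(50))

  # rotate body b by 90 deg about z through its origin at (2,0,0):
  # insertion local (8,0,0) lands at (2,8,0)
  poses2 <- list(a = pose(),
                 b = pose(p = c(2, 0, 0),
                          q = c(cos(pi / 4), 0, 0, sin(pi / 4))))
  m3 <- muscle_actuator("m3", list(body = "a", point = c(0, 0, 0)),
                        list(body = "b", point = c(8, 0, 0)), PCSA = 487)
  expect_equal(muscle_length(m3, poses2), sqrt(4 + 64), tolerance = 1e-12)
  expect_error(muscle_length(m3, list(a = pose())), "state error")
})

test_that("discrete PID matches the hand-computed update and clamps", {
  m <- muscle_actuator("m", list(body = "a", point = c(0, 0, 0)),
                       list(body = "b", point = c(50, 0, 0)),
                       PCSA = 487, F_max = 1000)
  # first step from zeroed state, e = 1 mm, dt = 0.01:
  # u = 50*1 + 5*(1*0.01) + 0.0005*(1-0)/0.01 = 50.1
  up <- pid_update(m, l_target = 49, l_current = 50, dt = 0.01)
  expect_equal(up$force, 50 + 0.05 + 0.05)
  # second step with the same error: derivative term vanishes
  up2 <- pid_update(up$muscle, 49, 50, 0.01)
  expect_equal(up2$force, 50 + 5 * 0.02)

  # pull-only: large negative error clamps at zero
  up3 <- pid_update(m, l_target = 60, l_current = 50, dt = 0.01)
  expect_equal(up3$force, 0)
  # e = 0 throughout keeps force 0
  mz <- m
  for (i in 1:10) {
    uz <- pid_update(mz, 50, 50, 0.01)
    mz <- uz$muscle
    expect_equal(uz$force, 0)
  }
  # F_max clamp
  m4 <- muscle_actuator("m4", list(body = "a", point = c(0, 0, 0)),
                        list(body = "b", point = c(50, 0, 0)),
                        PCSA = 487, F_max = 10)
  up4 <- pid_update(m4, 40, 50, 0.01)
  expect_equal(up4$force, 10)
})

test_that("anti-windup freezes the integral while clamped", {
  m <- muscle_actuator("m", list(body = "a", point = c(0, 0, 0)),
                       list(body = "b", point = c(50, 0, 0)), PCSA = 487)
  # drive hard negative for many steps: integral must not run away
  for (i in 1:200) {
    up <- pid_update(m, 60, 50, 0.01)
    m <- up$muscle
  }
  expect_equal(m$state$integral, 0)     # never accumulated while clamped
  # recovery is immediate once the error flips
  up <- pid_update(m, 49.9, 50, 0.01)
  expect_gt(up$force, 0)
})

test_that("closed-loop tracking of a spring load converges", {
  # muscle pulling a point mass against a linear spring, simulated with the
  # same discrete controller: steady tracking error stays bounded and small
  m <- muscle_actuator("m", list(body = "a", point = c(0, 0, 0)),
                       list(body = "b", point = c(0, 0, 0)), PCSA = 487,
                       F_max = 400)
  k_spring <- 10      # N/mm
  mass <- 2           # kg
  x <- 100; vel <- 0  # muscle length = x
  dt <- 1e-3
  target <- function(t) 100 - 20 * pmin(t, 1)
  err <- numeric(3000L)
  for (i in seq_len(3000L)) {
    t <- i * dt
    up <- pid_update(m, target(t), x, dt)
    m <- up$muscle
    # spring resists displacement from 100 mm; muscle force shortens
    acc <- 1000 * (k_spring * (100 - x) - up$force) / mass
    vel <- vel + acc * dt - 5 * vel * dt   # light viscous environment
    x <- x + vel * dt
    err[i] <- x - target(t)
  }
  # the spring load needs ~200 N at steady state; the proportional bound is
  # 200/50 = 4 mm and the integral (time constant P/I = 10 s) keeps eating
  # into it, so the tail error is bounded and decreasing
  expect_lt(max(abs(err[2500:3000])), 4)
  expect_lt(mean(err[2800:3000]), mean(err[1200:1400]))
  expect_true(all(is.finite(err)))
})

test_that("muscle force application has zero net wrench", {
  sub <- default_subject()
  set.seed(21)
  for (rep_i in 1:5) {
    th <- runif(1, 0, 1.5)
    poses <- list(humerus = pose(),
                  ulna = pose(rnorm(3, sd = 0.3),
                              c(cos(th / 2), sin(th / 2), 0, 0)),
                  radius = pose(rnorm(3, sd = 0.3),
                                c(cos(th / 2), sin(th / 2), 0, 0)))
    forces <- runif(length(sub$model$muscles), 0, 100)
    ap <- apply_muscle_forces(sub$model$muscles, poses, forces)
    expect_equal(colSums(ap[, c("fx", "fy", "fz")]), c(0, 0, 0),
                 ignore_attr = TRUE, tolerance = 1e-9)
    tq <- colSums(cbind(ap$py * ap$fz - ap$pz * ap$fy,
                        ap$pz * ap$fx - ap$px * ap$fz,
                        ap$px * ap$fy - ap$py * ap$fx))
    expect_equal(tq, c(0, 0, 0), ignore_attr = TRUE, tolerance = 1e-6)
  }
  # zero forces produce no applications
  poses0 <- list(humerus = pose(), ulna = pose(), radius = pose())
  ap0 <- apply_muscle_forces(sub$model$muscles, poses0,
                             numeric(length(sub$model$muscles)))
  expect_equal(nrow(ap0), 0L)
})

test_that("fast engine paths agree with the reference force interfaces", {
  cm <- calibrated_model()
  model <- cm$model
  poses <- list(humerus = pose(),
                ulna = pose(c(0.1, -0.2, 0.05),
                            c(cos(0.4), sin(0.4), 0, 0)),
                radius = pose(c(-0.1, 0.1, 0),
                              c(cos(0.4), sin(0.4), 0, 0)))
  cache <- elbowsim:::build_engine_cache(model)
  ff <- elbowsim:::ligament_forces_fast(cache$lig, poses)
  ref <- apply_ligament_forces(model$ligaments, poses)
  expect_equal(ff$tensions, ref$tensions, tolerance = 1e-12)
  # summed world wrench of the applications matches
  sum_wrench <- function(body, P, F) {
    list(F = colSums(F), tau = colSums(cbind(P[, 2] * F[, 3] - P[, 3] * F[, 2],
                                             P[, 3] * F[, 1] - P[, 1] * F[, 3],
                                             P[, 1] * F[, 2] - P[, 2] * F[, 1])))
  }
  a1 <- sum_wrench(ff$body, ff$P, ff$F)
  a2 <- sum_wrench(ref$applications$body,
                   as.matrix(ref$applications[, c("px", "py", "pz")]),
                   as.matrix(ref$applications[, c("fx", "fy", "fz")]))
  expect_equal(unname(a1$F), unname(a2$F), tolerance = 1e-9)
  expect_equal(unname(a1$tau), unname(a2$tau), tolerance = 1e-9)

  me <- elbowsim:::muscle_eval_fast(cache$mus, poses)
  for (j in seq_along(model$muscles))
    expect_equal(me$lengths[j], muscle_length(model$muscles[[j]], poses),
                 tolerance = 1e-12)
})
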