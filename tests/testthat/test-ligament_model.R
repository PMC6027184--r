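# ligament force-strain law, wrapping, calibration, action-reaction

test_that("strain and the piecewise force law match their closed forms", {
  expect_equal(bundle_strain(50, 50), 0)
  expect_equal(bundle_strain(52.5, 50), 0.05)
  expect_equal(bundle_strain(40, 50), -0.2)
  expect_error(bundle_strain(10, 0), "l0")

  expect_equal(bundle_force(-0.01, 100), 0)
  expect_equal(bundle_force(0.03, 100, 0.03), 0.75)       # 1/4 k eps^2 / eps_l
  # at the knot eps = 2 eps_l both branches agree
  expect_equal(0.25 * 100 * 0.06^2 / 0.03, 100 * (0.06 - 0.03))
  expect_equal(bundle_force(0.06, 100, 0.03), 3)
  expect_error(bundle_force(0.1, 100, 0), "eps_l")
})

test_that("the force law is C1 at the knot and monotone", {
  k <- 740; el <- 0.03
  for (h in 10^(-3:-7)) {
    gap <- abs(bundle_force(2 * el - h, k, el) - bundle_force(2 * el + h, k, el))
    expect_lt(gap, 2 * k * h)         # C0: gap vanishes linearly
    slope_lo <- (bundle_force(2 * el, k, el) - bundle_force(2 * el - h, k, el)) / h
    slope_hi <- (bundle_force(2 * el + h, k, el) - bundle_force(2 * el, k, el)) / h
    expect_equal(slope_lo, k, tolerance = max(h / el, 1e-7))
    expect_equal(slope_hi, k, tolerance = 1e-9)           # linear branch exactly k
  }
  eps <- seq(-0.05, 0.4, by = 1e-3)
  f <- bundle_force(eps, k, el)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f[eps <= 0] == 0))
})

test_that("wrapped lengths reduce to polyline lengths without obstacles", {
  poses <- list(a = pose(), b = pose())
  b1 <- ligament_bundle("t-straight", list(body = "a", point = c(0, 0, 0)),
                        list(body = "b", point = c(3, 4, 0)), k = 100)
  expect_equal(wrapped_length(b1, poses), 5)

  b2 <- ligament_bundle("t-via", list(body = "a", point = c(0, 0, 0)),
                        list(body = "b", point = c(10, 0, 0)), k = 100,
                        via_points = list(list(body = "a", point = c(5, 5, 0))))
  expect_equal(wrapped_length(b2, poses), 2 * sqrt(50))
  expect_equal(wrapped_length(b2, poses, straight_line = TRUE), 10)
})

test_that("sphere wrap matches a brute-force geodesic oracle", {
  # straight segment blocked by a sphere: compare the analytic
  # tangent-arc-tangent length with an iteratively shortened sampled path
  # projected outside the sphere
  oracle_sphere_path <- function(p1, p2, C, r, n = 200L, iters = 60000L) {
    tseq <- seq(0, 1, length.out = n)
    path <- outer(1 - tseq, p1) + outer(tseq, p2)
    for (it in seq_len(iters)) {
      mid <- (path[-c(n - 1L, n), ] + path[-c(1L, 2L), ]) / 2
      path[2:(n - 1L), ] <- mid
      d <- sweep(path, 2L, C)
      rr <- sqrt(rowSums(d * d))
      inside <- rr < r
      path[inside, ] <- C + d[inside, , drop = FALSE] * (r / rr[inside])
      path[1L, ] <- p1; path[n, ] <- p2
    }
    sum(sqrt(rowSums(diff(path)^2)))
  }
  poses <- list(a = pose(), b = pose())
  cases <- list(
    list(p1 = c(-10, 0, 1), p2 = c(10, 0, 1), C = c(0, 0, 0), r = 4),
    list(p1 = c(-8, -3, 0), p2 = c(9, 4, 2), C = c(0, 0, 0), r = 5))
  for (cs in cases) {
    b <- ligament_bundle("t-wrap", list(body = "a", point = cs$p1),
                         list(body = "b", point = cs$p2), k = 100,
                         wrap_obstacles = list(list(type = "sphere",
                                                    body = "a",
                                                    center = cs$C,
                                                    radius = cs$r)))
    L <- wrapped_length(b, poses)
    L_oracle <- oracle_sphere_path(cs$p1, cs$p2, cs$C, cs$r)
    expect_gt(L, sqrt(sum((cs$p2 - cs$p1)^2)))  # longer than the chord
    expect_equal(L, L_oracle, tolerance = 2e-4)
  }
  # endpoint inside the obstacle is a geometry error
  b_bad <- ligament_bundle("t-bad", list(body = "a", point = c(1, 0, 0)),
                           list(body = "b", point = c(10, 0, 0)), k = 100,
                           wrap_obstacles = list(list(type = "sphere",
                                                      body = "a",
                                                      center = c(0, 0, 0),
                                                      radius = 4)))
  expect_error(wrapped_length(b_bad, poses), "geometry error")
})

test_that("cylinder wrap follows the developable unrolling", {
  poses <- list(a = pose(), b = pose())
  r <- 3
  # symmetric planar case (no axial offset): tangent-arc-tangent in 2D
  b1 <- ligament_bundle("t-cyl", list(body = "a", point = c(0, -8, 1)),
                        list(body = "b", point = c(0, 8, 1)), k = 100,
                        wrap_obstacles = list(list(type = "cylinder",
                                                   body = "a",
                                                   center = c(0, 0, 0),
                                                   axis = c(1, 0, 0),
                                                   radius = r)))
  # 2D closed form in the y-z cross-section
  d <- sqrt(8^2 + 1^2)
  alpha <- acos(sum(c(-8, 1) * c(8, 1)) / d^2)
  arc <- alpha - 2 * acos(r / d)
  L2 <- 2 * sqrt(d^2 - r^2) + r * arc
  expect_equal(wrapped_length(b1, poses), L2, tolerance = 1e-9)

  # axial offset combines with the unrolled in-plane length
  b2 <- b1
  b2$origin$point <- c(-5, -8, 1)
  b2$insertion$point <- c(5, 8, 1)
  expect_equal(wrapped_length(b2, poses), sqrt(L2^2 + 10^2),
               tolerance = 1e-9)
  # and always exceeds the straight chord
  expect_gt(wrapped_length(b2, poses), sqrt(10^2 + 16^2))
})

test_that("laxity calibration returns factor times the observed maximum", {
  cm <- calibrated_model()
  model <- cm$model
  rep_ <- attr(model$ligaments, "report")
  expect_equal(nrow(rep_), 14L)
  expect_equal(rep_$l0_mm, 0.8 * rep_$max_length_mm)

  # independent maximum: loop over frames per bundle
  for (b in c(1L, 7L, 13L)) {
    bundle <- model$ligaments$bundles[[b]]
    mx <- -Inf
    for (i in seq_along(cm$laxity$time)) {
      poses <- lapply(cm$laxity$poses, function(m)
        pose(m[i, 1:3], m[i, 4:7]))
      mx <- max(mx, wrapped_length(bundle, poses))
    }
    expect_identical(bundle$l0, 0.8 * mx)
  }

  # constant-length bundle and factor overrides
  poses0 <- list(humerus = pose(), ulna = pose(), radius = pose())
  bcst <- ligament_complex(list(
    ligament_bundle("x-c", list(body = "humerus", point = c(0, 0, 0)),
                    list(body = "humerus", point = c(0, 0, 37.2)), k = 10)))
  still <- motion_trial("laxity", seq(0, 0.1, by = 0.01),
                        lapply(poses0, function(p)
                          matrix(rep(c(p$p, p$q), each = 11L), 11L, 7L)))
  cal <- estimate_zero_load_lengths(bcst, still)
  expect_equal(cal$bundles[[1L]]$l0, 0.8 * 37.2)
  cal2 <- estimate_zero_load_lengths(bcst, still, factor = 1)
  expect_equal(cal2$bundles[[1L]]$l0, 37.2)
  expect_error(estimate_zero_load_lengths(bcst,
                                          motion_trial("laxity", numeric(0),
                                                       list())),
               "calibration error")
})

test_that("ligament forces obey action-reaction over random poses", {
  cm <- calibrated_model()
  model <- cm$model
  set.seed(11)
  for (rep_i in 1:5) {
    ang <- runif(3, -0.5, 1.5)
    poses <- list(
      humerus = pose(),
      ulna = pose(rnorm(3, sd = 0.5),
                  c(cos(ang[1L] / 2), sin(ang[1L] / 2), 0, 0)),
      radius = pose(rnorm(3, sd = 0.5),
                    c(cos(ang[1L] / 2), sin(ang[1L] / 2), 0, 0)))
    lf <- apply_ligament_forces(model$ligaments, poses)
    expect_true(all(lf$tensions >= 0))
    ap <- lf$applications
    # net force and net torque about the origin vanish
    expect_equal(colSums(ap[, c("fx", "fy", "fz")]), c(0, 0, 0),
                 ignore_attr = TRUE, tolerance = 1e-9)
    tq <- colSums(cbind(ap$py * ap$fz - ap$pz * ap$fy,
                        ap$pz * ap$fx - ap$px * ap$fz,
                        ap$px * ap$fy - ap$py * ap$fx))
    expect_equal(tq, c(0, 0, 0), ignore_attr = TRUE, tolerance = 1e-6)
  }
})

test_that("uncalibrated complexes refuse to produce forces", {
  sub <- default_subject()
  poses <- list(humerus = pose(), ulna = pose(), radius = pose())
  expect_error(apply_ligament_forces(sub$model$ligaments, poses),
               "state error")
})

test_that("slack bundles produce zero force and taut ones are collinear", {
  poses <- list(a = pose(), b = pose())
  slack <- ligament_complex(list(
    ligament_bundle("s-1", list(body = "a", point = c(0, 0, 0)),
                    list(body = "b", point = c(10, 0, 0)), k = 100, l0 = 20)))
  lf <- apply_ligament_forces(slack, poses)
  expect_equal(unname(lf$tensions), 0)
  expect_equal(nrow(lf$applications), 0L)

  taut <- ligament_complex(list(
    ligament_bundle("t-1", list(body = "a", point = c(0, 0, 0)),
                    list(body = "b", point = c(10, 0, 0)), k = 100, l0 = 8)))
  lf2 <- apply_ligament_forces(taut, poses)
  expect_gt(lf2$tensions[[1L]], 0)
  ap <- lf2$applications
  expect_equal(ap$fx[1L], -ap$fx[2L])
  expect_equal(abs(ap$fx[1L]), lf2$tensions[[1L]])  # along the +x path
  expect_equal(ap$fy, c(0, 0))
})
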