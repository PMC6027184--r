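# Deterministic synthetic subject: a parametric three-bone elbow with
# congruent analytic articular surfaces, 14 ligament bundles, 6 muscle
# elements, plus motion-trial and surrogate-EMG generators, so the whole
# pipeline is testable without subject data.
#
# Geometry convention (body-local frames coincide with the world frame at
# neutral / full extension): +x medial, +y anterior, +z proximal; elbow
# centre at the origin; humeral shaft along +z; forearm along -z; flexion
# is a rotation of ulna and radius about +x. With this orientation the
# (M-L, A-P, S-I) anatomical triad is right-handed with identity axes.

#' Parameters of the synthetic subject
#'
#' @param seed integer seed controlling every random element downstream.
#' @param trochlea_radius outer (cartilage) radius of the humeral trochlea
#'   cylinder, mm.
#' @param capitellum_radius outer radius of the capitellum sphere, mm.
#' @param cartilage_thickness nominal cartilage thickness, mm (stored on
#'   grid elements; must be below both articular radii).
#' @param element_size contact element edge length, mm (default 3, the
#'   3 x 3 mm element cross-section).
#' @param forearm_length bone shaft length of ulna/radius, mm.
#' @param laxity_amplitude varus-valgus excursion of the laxity sweep, deg.
#' @param density_bone,density_soft densities in kg/m^3 (defaults 1600 and
#'   1000); segment masses combine a bone core with a soft-tissue sleeve of
#'   the softer density.
#' @return a `subject_parameters` object.
#' @export
subject_parameters <- function(seed = 1L, trochlea_radius = 12,
                               capitellum_radius = 9,
                               cartilage_thickness = 2, element_size = 3,
                               forearm_length = 240, laxity_amplitude = 4,
                               density_bone = 1600, density_soft = 1000) {
  if (cartilage_thickness >= min(trochlea_radius, capitellum_radius))
    stop("parameter error: cartilage thicker than the articular radius")
  if (any(c(trochlea_radius, capitellum_radius, cartilage_thickness,
            element_size, forearm_length) <= 0))
    stop("parameter error: all lengths must be > 0")
  structure(list(seed = as.integer(seed), trochlea_radius = trochlea_radius,
                 capitellum_radius = capitellum_radius,
                 cartilage_thickness = cartilage_thickness,
                 element_size = element_size,
                 forearm_length = forearm_length,
                 laxity_amplitude = laxity_amplitude,
                 density_bone = density_bone, density_soft = density_soft),
            class = "subject_parameters")
}

# evaluate expr under a fixed seed without disturbing the global RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# mass and COM-frame inertia of a z-aligned solid cylinder (kg, kg mm^2)
cylinder_mass_props <- function(radius, length, density) {
  m <- density * pi * radius^2 * length * 1e-9
  list(mass = m,
       inertia = diag(c(m * (3 * radius^2 + length^2) / 12,
                        m * (3 * radius^2 + length^2) / 12,
                        m * radius^2 / 2)))
}

#' Generate the synthetic elbow subject
#'
#' Builds the three bones (bone core plus soft-tissue sleeve for mass
#' properties), congruent articular surfaces (cylindrical trochlea /
#' trochlear notch, spherical capitellum / radial-head dish, radioulnar
#' sphere-in-cup), the 14 ligament bundles (3 MCL-anterior, 3
#' MCL-posterior, 3 LUCL, 3 RCL, 2 annular), and the 6 muscle elements
#' (triceps long/lateral/medial, biceps long/short, brachialis).
#'
#' @param params a `subject_parameters` object.
#' @return list with `model` (an uncalibrated `elbow_model`), `meshes`
#'   (named list of `surface_mesh`), and `params`.
#' @export
generate_subject <- function(params = subject_parameters()) {
  Rt <- params$trochlea_radius
  Rc <- params$capitellum_radius
  Lf <- params$forearm_length
  rho_b <- params$density_bone
  rho_s <- params$density_soft

  # --- meshes -----------------------------------------------------------
  trochlea <- mesh_from_param(
    function(u, v) c(u, Rt * sin(v), -Rt * cos(v)),
    u = seq(1, 11, length.out = 6L),
    v = seq(deg2rad(-140), deg2rad(140), length.out = 41L),
    body_name = "humerus")
  trochlea <- orient_mesh_outward(trochlea, function(p)
    c(0, p[2L], p[3L]))
  # capitellum cap centred on the distal (-z) direction, polar angle u
  capitellum <- mesh_from_param(
    function(u, v) c(-9, 0, 0) +
      Rc * c(sin(u) * cos(v), sin(u) * sin(v), -cos(u)),
    u = seq(1e-3, deg2rad(105), length.out = 14L),
    v = seq(0, 2 * pi, length.out = 37L),
    body_name = "humerus")
  capitellum <- orient_mesh_outward(capitellum, function(p) p - c(-9, 0, 0))

  cyl_closed <- function(radius, z0, z1, x0 = 0, body = "") {
    side <- mesh_from_param(
      function(u, v) c(x0 + radius * cos(v), radius * sin(v), u),
      u = c(z0, z1), v = seq(0, 2 * pi, length.out = 25L), body_name = body)
    cap <- function(z, flip) {
      mesh_from_param(
        function(u, v) c(x0 + u * cos(v), u * sin(v) * (if (flip) -1 else 1), z),
        u = c(1e-6, radius), v = seq(0, 2 * pi, length.out = 25L),
        body_name = body)
    }
    m1 <- cap(z0, TRUE); m2 <- cap(z1, FALSE)
    build_indexed_mesh_from_faces(
      rbind(side$vertices, m1$vertices, m2$vertices),
      rbind(side$faces, m1$faces + nrow(side$vertices),
            m2$faces + nrow(side$vertices) + nrow(m1$vertices)), body)
  }
  humerus_bone <- cyl_closed(10, 5, 150, body = "humerus")
  ulna_bone <- cyl_closed(9, -10 - Lf, -10, body = "ulna")
  radius_bone <- cyl_closed(7, -10 - Lf, -10, x0 = -9, body = "radius")

  ulna_notch <- mesh_from_param(
    function(u, v) c(u, Rt * sin(v), -Rt * cos(v)),
    u = seq(1, 11, length.out = 6L),
    v = seq(deg2rad(-100), deg2rad(100), length.out = 31L),
    body_name = "ulna")
  radius_dish <- mesh_from_param(
    function(u, v) c(-9, 0, 0) +
      Rc * c(sin(u) * cos(v), sin(u) * sin(v), -cos(u)),
    u = seq(1e-3, deg2rad(60), length.out = 9L),
    v = seq(0, 2 * pi, length.out = 25L),
    body_name = "radius")

  meshes <- list(humerus_bone = humerus_bone,
                 humerus_trochlea = trochlea,
                 humerus_capitellum = capitellum,
                 ulna_bone = ulna_bone,
                 ulna_notch = ulna_notch,
                 radius_bone = radius_bone,
                 radius_dish = radius_dish)

  # --- bodies (bone core + soft-tissue sleeve) --------------------------
  seg_body <- function(name, r_bone, r_soft, z_lo, z_hi, x0 = 0) {
    L <- z_hi - z_lo
    zc <- (z_hi + z_lo) / 2
    bone <- cylinder_mass_props(r_bone, L, rho_b)
    soft <- cylinder_mass_props(r_soft, L, rho_s)
    soft_ann <- list(mass = soft$mass - cylinder_mass_props(r_bone, L, rho_s)$mass,
                     inertia = soft$inertia -
                       cylinder_mass_props(r_bone, L, rho_s)$inertia)
    rigid_body(name, bone$mass + soft_ann$mass,
               bone$inertia + soft_ann$inertia, com = c(x0, 0, zc))
  }
  bodies <- list(
    humerus = seg_body("humerus", 10, 35, 5, 150),
    ulna = seg_body("ulna", 9, 30, -10 - Lf, -10),
    radius = seg_body("radius", 7, 20, -10 - Lf, -10, x0 = -9))

  # --- cartilage grids and contact pairs --------------------------------
  grid_troch <- discretize_cartilage(trochlea, params$element_size,
                                     thickness = params$cartilage_thickness)
  grid_cap <- discretize_cartilage(capitellum, params$element_size,
                                   thickness = params$cartilage_thickness)
  contact_pairs <- list(
    list(name = "ulnohumeral", grid = grid_troch,
         opposing = contact_surface("cylinder_cup", body = "ulna",
                                    origin = c(0, 0, 0), axis = c(1, 0, 0),
                                    radius = Rt, axial_range = c(1, 11),
                                    d0 = c(0, 0, -1),
                                    half_angle = deg2rad(100))),
    list(name = "radiohumeral", grid = grid_cap,
         opposing = contact_surface("sphere_cup", body = "radius",
                                    center = c(-9, 0, 0), radius = Rc,
                                    d0 = c(0, 0, -1),
                                    half_angle = deg2rad(60))),
    # radial head in the radial notch: two sphere-in-cup point constraints
    # along the head axis so the articulation resists tilt as well as
    # translation
    list(name = "radioulnar-proximal", type = "point_sphere_cup",
         sphere = list(body = "radius", center = c(-9, 0, -4), radius = 8),
         cup = contact_surface("sphere_cup", body = "ulna",
                               center = c(-9, 0, -4), radius = 8.5,
                               d0 = c(-1, 0, 0), half_angle = deg2rad(90)),
         area = 15),
    list(name = "radioulnar-distal", type = "point_sphere_cup",
         sphere = list(body = "radius", center = c(-9, 0, -12), radius = 8),
         cup = contact_surface("sphere_cup", body = "ulna",
                               center = c(-9, 0, -12), radius = 8.5,
                               d0 = c(-1, 0, 0), half_angle = deg2rad(90)),
         area = 15))

  # --- ligaments ---------------------------------------------------------
  ks <- default_ligament_stiffness()
  att <- function(body, p) list(body = body, point = p)
  mk <- function(name, k, o, i, wrap = list())
    ligament_bundle(name, att("humerus", o),
                    att(if (grepl("^RCL", name)) "radius" else "ulna", i),
                    k = k, wrap_obstacles = wrap)
  # collateral origins sit on the epicondylar (flexion) axis so the bundles
  # stay near-isometric through flexion, as they do anatomically; bundle
  # fan-out is along the axis and at the insertions
  troch_wrap <- list(list(type = "sphere", body = "humerus",
                          center = c(12, 0, -2), radius = 3))
  bundles <- list(
    mk("MCL-anterior-anterior", ks[["MCL-anterior"]], c(15, 1.2, 0.5), c(9, 9, -12)),
    mk("MCL-anterior-central", ks[["MCL-anterior"]], c(15.2, 0, 0), c(9, 7, -15)),
    mk("MCL-anterior-posterior", ks[["MCL-anterior"]], c(15, -1.2, -0.5), c(9, 5, -18)),
    mk("MCL-posterior-anterior", ks[["MCL-posterior"]], c(14.8, -0.8, 0.8),
       c(9, -6, -16), troch_wrap),
    mk("MCL-posterior-central", ks[["MCL-posterior"]], c(15, -1.5, 0),
       c(9, -8, -13), troch_wrap),
    mk("MCL-posterior-posterior", ks[["MCL-posterior"]], c(14.6, -2, -0.5),
       c(9, -9, -10), troch_wrap),
    mk("LUCL-anterior", ks[["LUCL"]], c(-14, 0.8, 0.3), c(-5, -2, -20)),
    mk("LUCL-central", ks[["LUCL"]], c(-14.2, 0, 0), c(-5, 0, -22)),
    mk("LUCL-posterior", ks[["LUCL"]], c(-14, -0.8, -0.3), c(-5, 2, -24)),
    mk("RCL-anterior", ks[["RCL"]], c(-14, 1, 0.3), c(-17.5, 2, -9)),
    mk("RCL-central", ks[["RCL"]], c(-14.3, 0, 0), c(-18, 0, -9)),
    mk("RCL-posterior", ks[["RCL"]], c(-14, -1, 0.3), c(-17.5, -2, -9)),
    ligament_bundle("annular-proximal", att("ulna", c(-3, 4, -8)),
                    att("radius", c(-13, 5, -8)), k = ks[["annular"]]),
    ligament_bundle("annular-distal", att("ulna", c(-3, -4, -8)),
                    att("radius", c(-13, -5, -8)), k = ks[["annular"]]))
  ligaments <- ligament_complex(bundles)

  # --- muscles -----------------------------------------------------------
  pcsa <- default_muscle_pcsa()
  mus <- function(name, o, v, i, body_i)
    muscle_actuator(name, att("humerus", o), att(body_i, i),
                    PCSA = pcsa[[name]], via_points = list(att("humerus", v)))
  # via points sit at the soft-tissue bulge over the joint so the flexor
  # moment arms stay in the literature 20-30 mm band through the range
  muscles <- list(
    mus("triceps-long", c(0, -14, 130), c(0, -24, 25), c(0, -20, 2), "ulna"),
    mus("triceps-lateral", c(0, -14, 100), c(0, -25, 24), c(0, -21, 4), "ulna"),
    mus("triceps-medial", c(0, -14, 70), c(0, -24, 26), c(0, -19, 1), "ulna"),
    mus("biceps-long", c(0, 12, 120), c(0, 26, 24), c(-6, 8, -40), "radius"),
    mus("biceps-short", c(0, 15, 115), c(0, 25, 22), c(-6, 9, -38), "radius"),
    mus("brachialis", c(0, 14, 60), c(0, 24, 22), c(0, 6, -45), "ulna"))

  # --- anatomical frames (identity triads in each body's local frame) ---
  frames <- lapply(stats::setNames(nm = names(bodies)), function(b)
    build_anatomical_frame(list(medial = c(20, 0, 0), lateral = c(-20, 0, 0),
                                proximal = c(0, 0, 50)),
                           origin = c(0, 0, 0)))

  # passive soft-tissue joint damping: human elbows show ~0.2-0.7 N m s/rad
  # of passive viscous damping; without it the frictionless congruent
  # surfaces leave flexion-extension entirely undamped, which no real arm is
  dampers <- list(list(body_a = "humerus", body_b = "ulna", c_rot = 300),
                  list(body_a = "ulna", body_b = "radius", c_rot = 150))

  model <- elbow_model(bodies, ligaments = ligaments, muscles = muscles,
                       contact = contact_params(),
                       contact_pairs = contact_pairs, frames = frames,
                       dampers = dampers)
  list(model = model, meshes = meshes, params = params)
}

# flip face winding if triangle normals point against the outward direction
orient_mesh_outward <- function(mesh, outward_fn) {
  N <- triangle_normals(mesh)
  C <- triangle_centroids(mesh)
  dots <- vapply(seq_len(nrow(N)), function(i)
    sum(N[i, ] * vhat(outward_fn(C[i, ]))), 0)
  if (mean(dots) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

# ---- trials ------------------------------------------------------------------

#' Specification of a synthetic motion trial
#'
#' @param label `"10deg/s"`, `"60deg/s"`, `"free"` or `"laxity"`.
#' @param range_deg flexion range `(start, end)` in degrees (default
#'   5 to 95).
#' @param rate motion sample rate, Hz (default 100).
#' @param emg_rate surrogate EMG sample rate, Hz (default 1400).
#' @param noise_pos,noise_deg seeded Gaussian jitter on forearm pose
#'   channels (default 0.2 mm / 0.2 deg), emulating marker noise.
#' @param peak_velocity peak angular velocity of the `"free"` bell profile,
#'   deg/s (default 300).
#' @param hold rest hold before and after the movement, s.
#' @param vv_amplitude varus-valgus amplitude of the laxity sweep, deg.
#' @param laxity_duration duration of the laxity sweep, s.
#' @param seed trial seed.
#' @return a `trial_spec`.
#' @export
trial_spec <- function(label = c("60deg/s", "10deg/s", "free", "laxity"),
                       range_deg = c(5, 95), rate = 100, emg_rate = 1400,
                       noise_pos = 0.2, noise_deg = 0.2,
                       peak_velocity = 300, hold = 0.5, vv_amplitude = 4,
                       laxity_duration = 16, seed = 1L) {
  label <- match.arg(label)
  stopifnot(rate > 0, diff(range_deg) > 0)
  structure(list(label = label, range_deg = range_deg, rate = rate,
                 emg_rate = emg_rate, noise_pos = noise_pos,
                 noise_deg = noise_deg, peak_velocity = peak_velocity,
                 hold = hold, vv_amplitude = vv_amplitude,
                 laxity_duration = laxity_duration, seed = as.integer(seed)),
            class = "trial_spec")
}

# flexion angle profile (deg) on a uniform grid for one spec; returns
# list(time, theta, vv, ie) in degrees
trial_profile <- function(spec) {
  dt <- 1 / spec$rate
  r0 <- spec$range_deg[1L]; r1 <- spec$range_deg[2L]
  range <- r1 - r0
  if (spec$label %in% c("10deg/s", "60deg/s")) {
    v <- if (spec$label == "10deg/s") 10 else 60
    t_ramp <- 0.3
    # velocity: half-cosine rise over t_ramp, constant v, half-cosine fall;
    # ramps each cover v*t_ramp/2 of angle
    t_const <- (range - v * t_ramp) / v
    if (t_const < 0) stop("trajectory error: range too small for the ramps")
    T_up <- t_ramp + t_const + t_ramp
    total <- spec$hold + T_up + spec$hold + T_up + spec$hold
    time <- seq(0, total, by = dt)
    vprof <- function(tau) {
      ifelse(tau < 0 | tau > T_up, 0,
             ifelse(tau < t_ramp, v * 0.5 * (1 - cos(pi * tau / t_ramp)),
                    ifelse(tau <= t_ramp + t_const, v,
                           v * 0.5 * (1 - cos(pi * (T_up - tau) / t_ramp)))))
    }
    vel <- vprof(time - spec$hold) - vprof(time - spec$hold - T_up - spec$hold)
    theta <- r0 + cumsum(vel) * dt
    theta <- pmin(theta, r1)
    theta <- pmax(theta, r0)
    return(list(time = time, theta = theta, vv = numeric(length(time)),
                ie = numeric(length(time))))
  }
  if (spec$label == "free") {
    T_up <- 2 * range / spec$peak_velocity
    total <- spec$hold + T_up + spec$hold + T_up + spec$hold
    time <- seq(0, total, by = dt)
    bell <- function(tau) {
      s <- pmin(pmax(tau / T_up, 0), 1)
      range * (s - sin(2 * pi * s) / (2 * pi))
    }
    theta <- r0 + bell(time - spec$hold) -
      bell(time - spec$hold - T_up - spec$hold)
    return(list(time = time, theta = theta, vv = numeric(length(time)),
                ie = numeric(length(time))))
  }
  # laxity: slow full-range triangle sweep with VV / I-E excursions
  total <- spec$laxity_duration
  time <- seq(0, total, by = dt)
  s <- time / total
  tri <- ifelse(s <= 0.5, 2 * s, 2 * (1 - s))
  theta <- r0 + range * tri
  vv <- spec$vv_amplitude * sin(2 * pi * 0.8 * time)
  ie <- 0.5 * spec$vv_amplitude * sin(2 * pi * 0.6 * time + 1)
  list(time = time, theta = theta, vv = vv, ie = ie)
}

#' Generate a synthetic motion trial
#'
#' Produces the pose series of the three bones for one of the trial
#' protocols: isokinetic flexion-extension at 10 or 60 deg/s, a fast
#' bell-velocity ("free") movement, or the slow full-range laxity sweep
#' with varus-valgus and internal-external excursions. The humerus is held
#' static; forearm pose channels carry seeded Gaussian jitter emulating
#' marker noise.
#'
#' @param model an `elbow_model` (used for body names).
#' @param spec a `trial_spec`.
#' @return a `motion_trial`.
#' @export
generate_trial <- function(model, spec = trial_spec()) {
  prof <- trial_profile(spec)
  n <- length(prof$time)
  with_seed(spec$seed, {
    jit <- function() cbind(stats::rnorm(n, 0, spec$noise_pos),
                            stats::rnorm(n, 0, spec$noise_pos),
                            stats::rnorm(n, 0, spec$noise_pos))
    jrot <- function() stats::rnorm(n, 0, spec$noise_deg)
    pose_series <- function(jitter_pos, jitter_rot) {
      m <- matrix(0, n, 7L)
      for (i in seq_len(n)) {
        R <- rot_x(deg2rad(prof$theta[i] + jitter_rot[i, 1L])) %*%
          rot_y(deg2rad(prof$vv[i] + jitter_rot[i, 2L])) %*%
          rot_z(deg2rad(prof$ie[i] + jitter_rot[i, 3L]))
        m[i, ] <- c(jitter_pos[i, ], mat_to_quat(R))
      }
      m
    }
    ulna <- pose_series(jit(), cbind(jrot(), jrot(), jrot()))
    radius <- pose_series(jit(), cbind(jrot(), jrot(), jrot()))
    humerus <- matrix(rep(c(0, 0, 0, 1, 0, 0, 0), each = n), n, 7L)
    motion_trial(spec$label, prof$time,
                 list(humerus = humerus, ulna = ulna, radius = radius))
  })
}

#' Generate surrogate raw EMG from simulated muscle forces
#'
#' Each channel is a seeded zero-mean Gaussian broadband carrier amplitude
#' modulated by the muscle's normalized force envelope (plus a 2 percent
#' baseline), sampled at the EMG rate, so that [process_emg()] recovers the
#' driving envelope.
#'
#' @param result a `simulation_result` with muscle forces.
#' @param spec a `trial_spec` (provides `emg_rate` and `seed`).
#' @param amplitude carrier standard deviation at full activation
#'   (arbitrary volts).
#' @return data frame with `time_s` and one column per muscle.
#' @export
generate_synthetic_emg <- function(result, spec = trial_spec(),
                                   amplitude = 1) {
  if (!length(result$time)) stop("empty simulation result")
  env <- normalize_muscle_forces(result)
  t_emg <- seq(result$time[1L], result$time[length(result$time)],
               by = 1 / spec$emg_rate)
  out <- data.frame(time_s = t_emg)
  with_seed(spec$seed + 1000L, {
    for (j in seq_len(ncol(env))) {
      e <- stats::approx(result$time, env[, j], xout = t_emg, rule = 2L)$y
      carrier <- stats::rnorm(length(t_emg))
      out[[colnames(env)[j]]] <- amplitude * (0.02 + 0.98 * e) * carrier
    }
  })
  out
}
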