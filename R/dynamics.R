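# Rigid-body dynamics of the three elbow bones and the two-phase protocol.
#
# Forward dynamics integrates each free body's centre-of-mass position,
# linear velocity, orientation quaternion and *world-frame angular momentum*
# with a fixed-step semi-implicit scheme. Contact damping (up to 5 Ns/mm per
# element over ~100 elements) is far too stiff for explicit treatment at any
# practical step, so the velocity update solves a per-body 6x6 linear system
# in which the damping wrench is evaluated at the new velocity; all other
# forces (gravity, ligament and contact elasticity, muscle tensions) are
# explicit. Because angular momentum is the orientation state's conjugate
# variable, torque-free motion conserves |L| exactly.
#
# Unit bookkeeping: lengths mm, masses kg, forces N, torques N mm, inertia
# kg mm^2. Newton's law in these units is  m dv/dt = 1000 F  and
# dL/dt = 1000 tau.

#' Construct a rigid body
#'
#' @param name body label.
#' @param mass mass in kg.
#' @param inertia 3x3 inertia tensor about the centre of mass, body frame
#'   (kg mm^2); symmetric positive definite.
#' @param com centre of mass in body-local coordinates (mm).
#' @param pose initial `pose` of the body frame.
#' @return a `rigid_body`.
#' @export
rigid_body <- function(name, mass, inertia, com = c(0, 0, 0),
                       pose = pose_identity()) {
  inertia <- as.matrix(inertia)
  if (mass <= 0) stop("mass must be > 0")
  if (max(abs(inertia - t(inertia))) > 1e-9 * max(abs(inertia)) ||
      any(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("inertia must be symmetric positive definite")
  structure(list(name = name, mass = mass, inertia = inertia,
                 com = as.numeric(com), pose = pose,
                 twist = list(v = c(0, 0, 0), w = c(0, 0, 0))),
            class = "rigid_body")
}

#' Assemble an elbow model
#'
#' In forward dynamics the model has no kinematic joints: all three bodies
#' carry their full 6 degrees of freedom (18 in total) and the joint is held
#' together purely by ligament, contact and muscle forces. The humerus is
#' driven along the trial motion; ulna and radius are free.
#'
#' @param bodies named list of `rigid_body` (humerus, ulna, radius).
#' @param ligaments a `ligament_complex` or `NULL`.
#' @param muscles list of `muscle_actuator`s.
#' @param contact a `contact_params`.
#' @param contact_pairs list of contact pairings; each either
#'   `list(name =, grid = <cartilage_grid>, opposing = <contact_surface or
#'   surface_mesh>)` for element-wise contact, or `list(name =, type =
#'   "point_sphere_cup", sphere = list(body =, center =, radius =), cup =
#'   <sphere_cup contact_surface>, area = <nominal mm^2>)` for the
#'   radioulnar point constraint.
#' @param frames named list of body-local `anatomical_frame`s used for
#'   kinematic decomposition.
#' @param gravity gravity vector in mm/s^2 (default `c(0, 0, -9810)`).
#' @param dampers optional passive soft-tissue dampers, each
#'   `list(body_a =, body_b =, c_rot =)` applying the torque
#'   `-c_rot * (w_b - w_a)` (N mm s/rad) between the two bodies. These model
#'   the measurable passive viscous damping of a human joint; they add no
#'   kinematic constraints.
#' @param free_bodies names of the bodies integrated in forward dynamics;
#'   the rest are prescribed from the trial.
#' @return an `elbow_model`.
#' @export
elbow_model <- function(bodies, ligaments = NULL, muscles = list(),
                        contact = contact_params(), contact_pairs = list(),
                        frames = list(), gravity = c(0, 0, -9810),
                        dampers = list(),
                        free_bodies = intersect(c("ulna", "radius"),
                                                names(bodies))) {
  stopifnot(all(vapply(bodies, inherits, TRUE, "rigid_body")))
  if (is.null(names(bodies)) || any(!nzchar(names(bodies))))
    names(bodies) <- vapply(bodies, `[[`, "", "name")
  structure(list(bodies = bodies, ligaments = ligaments, muscles = muscles,
                 contact = contact, contact_pairs = contact_pairs,
                 frames = frames, gravity = as.numeric(gravity),
                 dampers = dampers, free_bodies = free_bodies),
            class = "elbow_model")
}

#' Degree-of-freedom audit of a model
#'
#' Counts generalized coordinates before any motion driver is applied:
#' every rigid body contributes 6, and the ligament/contact constraint
#' forces add zero kinematic constraint equations.
#'
#' @param model an `elbow_model`.
#' @return list with `n_bodies`, `dof` and `constraint_equations`.
#' @export
model_dof <- function(model) {
  list(n_bodies = length(model$bodies),
       dof = 6L * length(model$bodies),
       constraint_equations = 0L)
}

#' @export
print.elbow_model <- function(x, ...) {
  dof <- model_dof(x)
  cat(sprintf("elbow_model: %d bodies (%s), %d DOF, %d kinematic constraints\n",
              dof$n_bodies, paste(names(x$bodies), collapse = ", "),
              dof$dof, dof$constraint_equations))
  if (!is.null(x$ligaments)) {
    cnt <- bundle_counts(x$ligaments)
    cat(sprintf("  ligaments: %d bundles (%s)\n", length(x$ligaments$bundles),
                paste(sprintf("%s x%d", names(cnt), cnt), collapse = ", ")))
  }
  cat(sprintf("  muscles: %d; contact pairs: %s\n", length(x$muscles),
              if (length(x$contact_pairs))
                paste(vapply(x$contact_pairs, `[[`, "", "name"),
                      collapse = ", ") else "none"))
  invisible(x)
}

# ---- inverse kinematics ------------------------------------------------------

#' Replay a motion trial and record muscle-length targets
#'
#' Phase one of the two-phase protocol: the bodies follow the trial poses
#' exactly (kinematic replay) and the shortening/lengthening pattern of
#' every muscle is recorded for the forward-dynamics controllers to track.
#'
#' @param model an `elbow_model`.
#' @param trial a `motion_trial` with poses for every body.
#' @return a `length_targets` object: list with `time`, `lengths` (frames x
#'   muscles matrix, mm) and `label`.
#' @export
run_inverse_kinematics <- function(model, trial) {
  miss <- setdiff(names(model$bodies), names(trial$poses))
  if (length(miss)) stop("trial lacks poses for: ", paste(miss, collapse = ", "))
  nm <- length(model$muscles)
  n <- length(trial$time)
  L <- matrix(0, n, nm)
  colnames(L) <- vapply(model$muscles, `[[`, "", "name")
  for (i in seq_len(n)) {
    poses <- trial_poses(trial, i)
    for (j in seq_len(nm))
      L[i, j] <- muscle_length(model$muscles[[j]], poses)
  }
  structure(list(time = trial$time, lengths = L, label = trial$label),
            class = "length_targets")
}

# ---- single-body integration primitive --------------------------------------

#' Advance one free rigid body by a single time step
#'
#' Semi-implicit update: the new generalized velocity solves
#' `[M/(1000 dt) + D] u' = M u/(1000 dt) + W` (damping implicit, everything
#' else explicit), then position and quaternion advance with the new
#' velocity. State is `(xc, vc, q, L)` with `L` the world-frame angular
#' momentum, so with `D = 0` and zero torque `|L|` is conserved exactly.
#'
#' @param state list `xc` (COM, mm), `vc` (mm/s), `q` (unit quaternion),
#'   `L` (kg mm^2/s).
#' @param mass kg.
#' @param inertia body-frame inertia about the COM (kg mm^2).
#' @param wrench list `F` (N) and `tau` (N mm about the COM) of all explicit
#'   forces.
#' @param dt step (s).
#' @param damping optional 6x6 generalized damping matrix (N s/mm blocks).
#' @return updated state.
#' @export
step_dynamics <- function(state, mass, inertia, wrench, dt, damping = NULL) {
  if (any(!is.finite(c(wrench$F, wrench$tau))))
    stop("numeric error: non-finite wrench")
  R <- quat_to_mat(state$q)
  Iw <- R %*% inertia %*% t(R)
  s <- 1 / (1000 * dt)
  rhs <- c(mass * state$vc * s + wrench$F,
           state$L * s + wrench$tau)
  A <- matrix(0, 6L, 6L)
  A[1:3, 1:3] <- diag(mass * s, 3L)
  A[4:6, 4:6] <- Iw * s
  if (!is.null(damping)) A <- A + damping
  u <- solve(A, rhs)
  vc <- u[1:3]; w <- u[4:6]
  tau_total <- wrench$tau - if (is.null(damping))
    c(0, 0, 0) else (damping %*% u)[4:6]
  L <- state$L + 1000 * dt * tau_total
  xc <- state$xc + dt * vc
  q <- state$q + 0.5 * dt * quat_mul(c(0, w), state$q)
  list(xc = xc, vc = vc, q = quat_normalize(q), L = as.numeric(L))
}

# ---- forward dynamics --------------------------------------------------------

#' Muscle-driven forward dynamics
#'
#' Phase two of the protocol: the kinematic constraints are removed, the
#' free bodies evolve under gravity, ligament, contact and muscle forces,
#' and each muscle's PID controller tracks the inverse-kinematics length
#' target. The humerus (any non-free body) stays prescribed from the trial.
#'
#' @param model calibrated `elbow_model` (all ligament `l0` set).
#' @param trial the `motion_trial` providing initial poses and the
#'   prescribed-body motion.
#' @param targets `length_targets` from [run_inverse_kinematics()]; computed
#'   on the fly when `NULL` and the model has muscles.
#' @param dt internal integration step in s (default 1e-4).
#' @param duration simulated time in s; defaults to the trial span.
#' @param dt_output reporting interval in s (default 0.01, the standard
#'   reporting step); must be a multiple of `dt`.
#' @param record_elements track per-element peak contact force for pressure
#'   maps.
#' @param record_energy record total mechanical energy (kinetic +
#'   gravitational + ligament elastic, in J) of the free bodies at each
#'   output step into `$energy` (used by conservation audits).
#' @return a `simulation_result`: shared `time` grid, per-body pose series,
#'   per-bundle tensions, per-muscle forces/lengths/targets, per-pair
#'   contact summaries and per-element peak forces.
#' @export
run_forward_dynamics <- function(model, trial, targets = NULL, dt = 1e-4,
                                 duration = NULL, dt_output = 0.01,
                                 record_elements = TRUE,
                                 record_energy = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(duration)) duration <- diff(range(trial$time))
  if (is.null(targets) && length(model$muscles))
    targets <- run_inverse_kinematics(model, trial)
  stride <- max(1L, round(dt_output / dt))
  n_steps <- floor(duration / dt + 1e-9)
  n_out <- if (duration <= 0) 0L else floor(n_steps / stride) + 1L
  t0 <- if (length(trial$time)) trial$time[1L] else 0

  body_names <- names(model$bodies)
  free <- intersect(model$free_bodies, body_names)
  prescribed <- setdiff(body_names, free)
  nm <- length(model$muscles)
  muscle_names <- vapply(model$muscles, `[[`, "", "name")

  # calibration guard
  if (!is.null(model$ligaments) &&
      any(is.na(vapply(model$ligaments$bundles, `[[`, 0, "l0"))))
    stop("state error: ligament complex is not calibrated (l0 missing)")

  # target interpolators (linear, clamped at the ends)
  target_fun <- if (nm && !is.null(targets)) {
    lapply(seq_len(nm), function(j)
      stats::approxfun(targets$time, targets$lengths[, j], rule = 2L))
  } else NULL

  cache <- build_engine_cache(model)

  # static-prescribed-body fast path
  static_prescribed <- vapply(prescribed, function(b) {
    m <- trial$poses[[b]]
    all(abs(sweep(m, 2L, m[1L, ])) < 1e-12)
  }, TRUE)
  names(static_prescribed) <- prescribed
  zero_twist <- list(v = c(0, 0, 0), w = c(0, 0, 0))

  # initial state
  poses <- trial_poses(trial, 1L)
  state <- list()
  for (b in free) {
    bd <- model$bodies[[b]]
    R <- .pose_R(poses[[b]])
    state[[b]] <- list(xc = poses[[b]]$p + as.numeric(R %*% bd$com),
                       vc = c(0, 0, 0), q = poses[[b]]$q, L = c(0, 0, 0))
  }
  twists <- stats::setNames(rep(list(zero_twist), length(body_names)), body_names)

  # controller state
  if (nm) {
    gains <- vapply(model$muscles, `[[`, numeric(3L), "gains")  # 3 x nm
    fmax <- vapply(model$muscles, `[[`, 0, "F_max")
    pid_state <- list(integral = numeric(nm), prev = numeric(nm))
  }

  # output buffers
  np <- length(model$contact_pairs)
  pair_names <- vapply(model$contact_pairs, `[[`, "", "name")
  out <- list(
    time = numeric(n_out),
    poses = stats::setNames(lapply(body_names, function(b)
      matrix(0, n_out, 7L, dimnames = list(NULL, c("x", "y", "z", "qw", "qx", "qy", "qz")))),
      body_names),
    ligament_tensions = if (!is.null(model$ligaments))
      matrix(0, n_out, length(model$ligaments$bundles),
             dimnames = list(NULL, names(model$ligaments$bundles))) else NULL,
    muscle_forces = matrix(0, n_out, nm, dimnames = list(NULL, muscle_names)),
    muscle_lengths = matrix(0, n_out, nm, dimnames = list(NULL, muscle_names)),
    muscle_targets = matrix(0, n_out, nm, dimnames = list(NULL, muscle_names)),
    contact = stats::setNames(lapply(seq_len(np), function(i)
      data.frame(time = numeric(n_out), total_force = numeric(n_out),
                 area_mm2 = numeric(n_out), peak_pressure = numeric(n_out),
                 n_loaded = integer(n_out))), pair_names),
    element_peak_force = stats::setNames(lapply(model$contact_pairs, function(cp)
      if (!is.null(cp$grid)) numeric(nrow(cp$grid$elements)) else numeric(1L)),
      pair_names),
    energy = if (record_energy) numeric(n_out) else NULL)

  record <- function(k_out, t, forces_m, lengths_m, targets_m, tensions,
                     contact_rows) {
    out$time[k_out] <<- t
    for (b in body_names) {
      ps <- poses[[b]]
      out$poses[[b]][k_out, ] <<- c(ps$p, ps$q)
    }
    if (!is.null(out$ligament_tensions))
      out$ligament_tensions[k_out, ] <<- tensions
    if (nm) {
      out$muscle_forces[k_out, ] <<- forces_m
      out$muscle_lengths[k_out, ] <<- lengths_m
      out$muscle_targets[k_out, ] <<- targets_m
    }
    for (i in seq_len(np)) {
      cr <- contact_rows[[i]]
      out$contact[[i]][k_out, ] <<- list(t, cr$total_force, cr$area,
                                         cr$peak_pressure, cr$n_loaded)
    }
    if (record_energy)
      out$energy[k_out] <<- model_energy(model, state, poses)
  }

  mk_result <- function() {
    structure(list(label = trial$label, time = out$time, poses = out$poses,
                   ligament_tensions = out$ligament_tensions,
                   muscle_forces = out$muscle_forces,
                   muscle_lengths = out$muscle_lengths,
                   muscle_targets = out$muscle_targets,
                   contact = out$contact,
                   element_peak_force = out$element_peak_force,
                   energy = out$energy,
                   contact_pairs = pair_names,
                   dt_internal = dt, dt_output = dt * stride),
              class = "simulation_result")
  }
  if (n_out == 0L) return(mk_result())

  k_out <- 0L
  for (k in seq_len(n_steps + 1L)) {
    t <- t0 + (k - 1L) * dt
    # prescribed bodies
    for (b in prescribed) {
      if (static_prescribed[[b]] && k > 1L) next
      poses[[b]] <- trial_pose_at(trial, b, t)
      twists[[b]] <- if (static_prescribed[[b]]) zero_twist else
        trial_twist_at(trial, b, t)
    }
    for (b in free) {
      st <- state[[b]]
      bd <- model$bodies[[b]]
      R <- quat_to_mat(st$q)
      p_origin <- st$xc - as.numeric(R %*% bd$com)
      poses[[b]] <- structure(list(p = p_origin, q = st$q, R = R),
                              class = "pose")
      Iw <- R %*% bd$inertia %*% t(R)
      w <- as.numeric(solve(Iw, st$L))
      twists[[b]] <- list(v = st$vc + vcross(w, p_origin - st$xc), w = w)
      state[[b]]$w <- w
      state[[b]]$Iw <- Iw
    }

    # --- explicit wrenches about each free body's COM ---
    Facc <- stats::setNames(rep(list(c(0, 0, 0)), length(free)), free)
    Tacc <- Facc
    for (b in free)
      Facc[[b]] <- model$bodies[[b]]$mass * model$gravity / 1000

    tensions <- NULL
    if (!is.null(cache$lig)) {
      lf <- ligament_forces_fast(cache$lig, poses)
      tensions <- lf$tensions
      acc <- accumulate_wrench(lf, free, state, Facc, Tacc)
      Facc <- acc$F; Tacc <- acc$tau
    }

    forces_m <- numeric(nm); lengths_m <- numeric(nm); targets_m <- numeric(nm)
    if (nm) {
      targets_m <- vapply(seq_len(nm), function(j) target_fun[[j]](t), 0)
      me <- muscle_eval_fast(cache$mus, poses)
      lengths_m <- me$lengths
      up <- pid_update_vec(lengths_m - targets_m, pid_state, gains, fmax, dt)
      forces_m <- up$force
      pid_state <- up$state
      if (any(forces_m > 0)) {
        am <- muscle_eval_fast(cache$mus, poses, forces_m)
        acc <- accumulate_wrench(am, free, state, Facc, Tacc)
        Facc <- acc$F; Tacc <- acc$tau
      }
    }

    # --- passive joint dampers (explicit; rates are mild) ---
    for (dp in model$dampers) {
      relw <- twists[[dp$body_b]]$w - twists[[dp$body_a]]$w
      tq <- dp$c_rot * relw
      if (dp$body_b %in% free) Tacc[[dp$body_b]] <- Tacc[[dp$body_b]] - tq
      if (dp$body_a %in% free) Tacc[[dp$body_a]] <- Tacc[[dp$body_a]] + tq
    }

    # --- contact: explicit elastic part + implicit damping assembly ---
    Dacc <- stats::setNames(rep(list(matrix(0, 6L, 6L)), length(free)), free)
    contact_rows <- vector("list", np)
    for (i in seq_len(np)) {
      pc <- cache$pairs[[i]]
      res <- if (identical(pc$type, "point_sphere_cup"))
        contact_pair_forces(pc, model$contact, poses, twists, state, free, dt)
      else
        grid_pair_fast(pc, model$contact, poses, twists, state, free)
      contact_rows[[i]] <- res$summary
      for (b in names(res$F)) {
        Facc[[b]] <- Facc[[b]] + res$F[[b]]
        Tacc[[b]] <- Tacc[[b]] + res$tau[[b]]
        Dacc[[b]] <- Dacc[[b]] + res$D[[b]]
      }
      if (record_elements && !is.null(res$element_force)) {
        pk <- out$element_peak_force[[i]]
        out$element_peak_force[[i]] <- pmax(pk, res$element_force)
      }
    }

    # --- record before advancing (state at time t) ---
    if ((k - 1L) %% stride == 0L && k_out < n_out) {
      k_out <- k_out + 1L
      record(k_out, t, forces_m, lengths_m, targets_m, tensions, contact_rows)
    }
    if (k == n_steps + 1L) break

    # --- integrate free bodies ---
    for (b in free) {
      st <- state[[b]]
      bd <- model$bodies[[b]]
      new <- step_dynamics(list(xc = st$xc, vc = st$vc, q = st$q, L = st$L),
                           bd$mass, bd$inertia,
                           list(F = Facc[[b]], tau = Tacc[[b]]), dt,
                           damping = Dacc[[b]])
      if (any(!is.finite(c(new$xc, new$vc, new$L))) ||
          max(abs(new$vc)) > 1e6)
        stop(sprintf("solver error: divergence at step %d (t = %.4f s), body '%s'",
                     k, t, b))
      state[[b]][c("xc", "vc", "q", "L")] <- new
    }
  }
  mk_result()
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result '%s': %d output frames @ %.3g s (internal dt %.1e s)\n",
              x$label, length(x$time), x$dt_output, x$dt_internal))
  if (length(x$time)) {
    if (!is.null(x$ligament_tensions))
      cat(sprintf("  peak bundle tension: %.1f N\n", max(x$ligament_tensions)))
    if (ncol(x$muscle_forces))
      cat(sprintf("  peak muscle force: %.1f N\n", max(x$muscle_forces)))
    for (nmp in x$contact_pairs)
      cat(sprintf("  %s: peak total force %.1f N\n", nmp,
                  max(x$contact[[nmp]]$total_force)))
  }
  invisible(x)
}

# forces, damping matrices and summary for one contact pair at the current
# poses/twists; returns per-free-body F, tau, D plus per-element forces
contact_pair_forces <- function(cp, params, poses, twists, state, free, dt) {
  zero <- list(F = list(), tau = list(), D = list(), summary = list(
    total_force = 0, area = 0, peak_pressure = 0, n_loaded = 0L),
    element_force = NULL)
  if (identical(cp$type, "point_sphere_cup")) {
    sp <- cp$sphere
    cup <- cp$cup
    c_s <- pose_transform(poses[[sp$body]], as.numeric(sp$center))
    c_c <- pose_transform(poses[[cup$body]], as.numeric(cup$center))
    off <- c_s - c_c
    d <- vnorm(off)
    gap <- cup$radius - sp$radius
    delta <- d - gap
    if (delta <= 0 || d < 1e-9) return(zero)
    nhat <- off / d                      # cup centre -> sphere centre
    # the contact normal passes through both centres, so applying the force
    # at each body's own centre point is torque-exact
    v_s <- point_velocity(poses[[sp$body]], twists[[sp$body]], c_s)
    v_c <- point_velocity(poses[[cup$body]], twists[[cup$body]], c_c)
    ddot <- sum((v_s - v_c) * nhat)
    f_el <- params$kc * delta^params$n
    ci <- smooth_step(delta / params$d_max) * params$c_max
    f_tot <- max(f_el + ci * ddot, 0)
    res <- list(F = list(), tau = list(), D = list(),
                summary = list(total_force = f_tot,
                               area = if (is.null(cp$area)) 0 else cp$area,
                               peak_pressure = if (is.null(cp$area) || cp$area <= 0)
                                 0 else f_tot / cp$area,
                               n_loaded = 1L),
                element_force = f_tot)
    if (sp$body %in% free) {             # sphere pushed back along -nhat
      r <- c_s - state[[sp$body]]$xc
      J <- c(nhat, vcross(r, nhat))      # ddot = J u_s - nhat.v_c
      f_expl <- f_el - ci * sum(v_c * nhat)
      res$F[[sp$body]] <- -nhat * f_expl
      res$tau[[sp$body]] <- vcross(r, -nhat * f_expl)
      res$D[[sp$body]] <- ci * tcrossprod(J)
    }
    if (cup$body %in% free) {            # cup pushed along +nhat
      r <- c_c - state[[cup$body]]$xc
      J <- c(nhat, vcross(r, nhat))      # ddot = nhat.v_s - J u_c
      f_expl <- f_el + ci * sum(v_s * nhat)
      res$F[[cup$body]] <- nhat * f_expl
      res$tau[[cup$body]] <- vcross(r, nhat * f_expl)
      res$D[[cup$body]] <- ci * tcrossprod(J)
    }
    return(res)
  }
  # element grid pair
  grid <- cp$grid
  opp <- cp$opposing
  det <- detect_penetrations(grid, opp, poses)
  active <- which(det$delta > 0)
  nel <- length(det$delta)
  if (!length(active)) {
    zero$element_force <- numeric(nel)
    return(zero)
  }
  delta <- det$delta[active]
  if (max(delta) > 5)
    stop("solver error: contact penetration exceeds 5 mm (divergence)")
  X <- det$points[active, , drop = FALSE]
  N <- det$normals[active, , drop = FALSE]
  f_el <- params$kc * delta^params$n
  ci <- smooth_step(delta / params$d_max) * params$c_max
  gb <- grid$parent_body
  ob <- if (inherits(opp, "surface_mesh")) opp$body_name else opp$body
  v_g <- point_velocity(poses[[gb]], twists[[gb]], X)
  v_o <- point_velocity(poses[[ob]], twists[[ob]], X)
  ddot <- rowSums((v_g - v_o) * N)
  f_tot <- pmax(f_el + ci * ddot, 0)

  res <- list(F = list(), tau = list(), D = list(), summary = NULL,
              element_force = numeric(nel))
  res$element_force[active] <- f_tot
  for (b in intersect(c(gb, ob), free)) {
    sgn <- if (b == ob) 1 else -1        # opposing body pushed along +normal
    r <- sweep(X, 2L, state[[b]]$xc)
    rxn <- cbind(r[, 2L] * N[, 3L] - r[, 3L] * N[, 2L],
                 r[, 3L] * N[, 1L] - r[, 1L] * N[, 3L],
                 r[, 1L] * N[, 2L] - r[, 2L] * N[, 1L])
    # explicit part: elastic + damping against the *other* body's velocity
    other_v <- if (b == ob) v_g else v_o
    b_term <- rowSums(other_v * N) * (if (b == ob) 1 else -1)
    f_expl <- f_el + ci * b_term
    Fv <- sgn * colSums(N * f_expl)
    Tv <- sgn * colSums(rxn * f_expl)
    # For the opposing body: ddot = b - (N, rxn).u_o; for the grid body
    # ddot = (N, rxn).u_g - b. Either way the damping force opposing the
    # body's own motion gives D = sum_i ci (N, rxn)_i (N, rxn)_i^T.
    Jm <- cbind(N, rxn)
    D <- crossprod(Jm * sqrt(ci))
    res$F[[b]] <- Fv
    res$tau[[b]] <- Tv
    res$D[[b]] <- D
  }
  e_area <- grid$elements$area[active]
  pressure <- f_tot / e_area
  res$summary <- list(total_force = sum(f_tot),
                      area = sum(e_area[f_tot > 0]),
                      peak_pressure = if (any(f_tot > 0)) max(pressure) else 0,
                      n_loaded = sum(f_tot > 0))
  res
}

# ---- energy bookkeeping (used by conservation tests) ------------------------

# total mechanical energy (J) of the free bodies plus ligament elastic energy
model_energy <- function(model, state_list, poses) {
  E <- 0
  for (b in names(state_list)) {
    st <- state_list[[b]]
    bd <- model$bodies[[b]]
    R <- quat_to_mat(st$q)
    Iw <- R %*% bd$inertia %*% t(R)
    w <- as.numeric(solve(Iw, st$L))
    E <- E + 0.5 * (bd$mass * sum(st$vc^2) + sum(w * (Iw %*% w))) / 1e6
    E <- E - bd$mass * sum(model$gravity * st$xc) / 1e6
  }
  if (!is.null(model$ligaments))
    E <- E + ligament_energy(model$ligaments, poses)
  E
}

# elastic energy stored in the ligament complex (J)
ligament_energy <- function(complex, poses) {
  E <- 0
  for (bd in complex$bundles) {
    L <- wrapped_length(bd, poses)
    eps <- bundle_strain(L, bd$l0)
    if (eps <= 0) next
    k <- bd$k; el <- bd$eps_l
    Emm <- if (eps <= 2 * el) k * eps^3 / (12 * el) else
      (2 / 3) * k * el^2 + 0.5 * k * ((eps - el)^2 - el^2)
    E <- E + Emm * bd$l0 / 1000
  }
  E
}
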