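# Element-wise compliant cartilage contact. Each humeral cartilage element
# exerts a frictionless normal force Fc = kc * delta^n + Bc(delta) * ddelta
# on the opposing bone when its reference point penetrates the opposing
# cartilage by delta. The damping coefficient ramps in smoothly over the
# first d_max of penetration so first touch is force-continuous, and the
# total element force is clamped at zero so damping can never pull.

#' Contact parameters of the compliant cartilage model
#'
#' Defaults are the optimized values for elbow cartilage: stiffness
#' 40 N/mm, damping 5 Ns/mm, exponent 3.05, full-damping penetration 0.1 mm.
#'
#' @param kc contact stiffness (N/mm^n).
#' @param n force exponent (>= 1).
#' @param c_max damping coefficient at full penetration (N s/mm).
#' @param d_max penetration depth at which damping is fully active (mm).
#' @return a `contact_params` object.
#' @export
contact_params <- function(kc = 40, n = 3.05, c_max = 5, d_max = 0.1) {
  if (kc <= 0 || n < 1 || c_max < 0 || d_max <= 0)
    stop("invalid contact parameters: need kc > 0, n >= 1, c_max >= 0, d_max > 0")
  structure(list(kc = kc, n = n, c_max = c_max, d_max = d_max),
            class = "contact_params")
}

#' @export
print.contact_params <- function(x, ...) {
  cat(sprintf("contact_params: kc = %g N/mm^n, n = %g, c_max = %g Ns/mm, d_max = %g mm\n",
              x$kc, x$n, x$c_max, x$d_max))
  invisible(x)
}

# cubic smooth-step for the damping ramp, s(u) = 3u^2 - 2u^3 on [0, 1]
smooth_step <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Compliant contact force of one cartilage element
#'
#' @param delta penetration depth (mm), vectorized; no force for
#'   `delta <= 0`.
#' @param delta_dot penetration rate (mm/s).
#' @param p a `contact_params` object.
#' @return normal force in N, clamped at `>= 0` (no adhesion).
#' @export
element_contact_force <- function(delta, delta_dot, p) {
  f <- ifelse(delta <= 0, 0,
              p$kc * delta^p$n +
                smooth_step(delta / p$d_max) * p$c_max * delta_dot)
  pmax(f, 0)
}

# ---- penetration detection ---------------------------------------------------

#' Per-element penetration depths against an opposing surface
#'
#' The grid's elements are posed into the world frame via their parent
#' body's pose; the opposing geometry via its own. `delta` is the depth of
#' the element centroid inside the opposing closed surface measured along
#' the element's outward normal (0 when outside); `delta_dot` is its rate
#' from the relative rigid-body velocities.
#'
#' @param grid a `cartilage_grid` whose `parent_body` appears in `poses`.
#' @param opposing a closed `surface_mesh` or an analytic
#'   `contact_surface()` description, in its own body's local frame.
#' @param poses named list of `pose` objects.
#' @param velocities optional named list of twists (`list(v =, w =)`,
#'   mm/s and rad/s at the body-frame origin); when omitted all rates are 0.
#' @return list with numeric vectors `delta`, `delta_dot` (one per element)
#'   and the world-frame element `points` and `normals` matrices.
#' @export
detect_penetrations <- function(grid, opposing, poses, velocities = NULL) {
  ps_g <- poses[[grid$parent_body]]
  if (is.null(ps_g)) stop("no pose for grid parent body '", grid$parent_body, "'")
  e <- grid$elements
  X <- pose_transform(ps_g, as.matrix(e[, c("cx", "cy", "cz")]))
  N <- pose_rotate(ps_g, as.matrix(e[, c("nx", "ny", "nz")]))
  if (inherits(opposing, "surface_mesh")) {
    opp_body <- opposing$body_name
    ps_o <- poses[[opp_body]]
    if (is.null(ps_o)) stop("no pose for opposing body '", opp_body, "'")
    delta <- mesh_penetration_depths(X, N, opposing, ps_o)
  } else if (inherits(opposing, "contact_surface")) {
    opp_body <- opposing$body
    ps_o <- poses[[opp_body]]
    if (is.null(ps_o)) stop("no pose for opposing body '", opp_body, "'")
    delta <- analytic_penetration_depths(X, opposing, ps_o)
  } else stop("opposing must be a surface_mesh or a contact_surface")
  delta_dot <- numeric(nrow(X))
  if (!is.null(velocities)) {
    active <- delta > 0
    if (any(active)) {
      vg <- point_velocity(ps_g, velocities[[grid$parent_body]],
                           X[active, , drop = FALSE])
      vo <- point_velocity(poses[[opp_body]], velocities[[opp_body]],
                           X[active, , drop = FALSE])
      delta_dot[active] <- rowSums((vg - vo) * N[active, , drop = FALSE])
    }
  }
  list(delta = delta, delta_dot = delta_dot, points = X, normals = N)
}

# depth of points inside a closed mesh along -normal (the way they came in)
mesh_penetration_depths <- function(X, N, mesh, ps_o) {
  Vw <- pose_transform(ps_o, mesh$vertices)
  f <- mesh$faces
  A <- Vw[f[, 1L], , drop = FALSE]
  E1 <- Vw[f[, 2L], , drop = FALSE] - A
  E2 <- Vw[f[, 3L], , drop = FALSE] - A
  n_el <- nrow(X)
  delta <- numeric(n_el)
  dir_in <- vhat(c(0.57735027, 0.52573111, 0.62480431))  # parity-test ray
  for (i in seq_len(n_el)) {
    hits <- ray_tri_hits(X[i, ], dir_in, A, E1, E2)
    if (length(hits) %% 2L == 1L) {       # inside the closed surface
      t <- ray_tri_hits(X[i, ], -N[i, ], A, E1, E2)
      delta[i] <- if (length(t)) min(t) else 0
    }
  }
  delta
}

# Moeller-Trumbore ray/triangle intersection, vectorized over triangles;
# returns the positive hit distances
ray_tri_hits <- function(orig, dir, A, E1, E2, eps = 1e-9) {
  pvx <- dir[2L] * E2[, 3L] - dir[3L] * E2[, 2L]
  pvy <- dir[3L] * E2[, 1L] - dir[1L] * E2[, 3L]
  pvz <- dir[1L] * E2[, 2L] - dir[2L] * E2[, 1L]
  det <- E1[, 1L] * pvx + E1[, 2L] * pvy + E1[, 3L] * pvz
  ok <- abs(det) > eps
  tx <- orig[1L] - A[, 1L]; ty <- orig[2L] - A[, 2L]; tz <- orig[3L] - A[, 3L]
  u <- (tx * pvx + ty * pvy + tz * pvz) / det
  qx <- ty * E1[, 3L] - tz * E1[, 2L]
  qy <- tz * E1[, 1L] - tx * E1[, 3L]
  qz <- tx * E1[, 2L] - ty * E1[, 1L]
  v <- (dir[1L] * qx + dir[2L] * qy + dir[3L] * qz) / det
  t <- (E2[, 1L] * qx + E2[, 2L] * qy + E2[, 3L] * qz) / det
  hit <- ok & u >= -eps & v >= -eps & (u + v) <= 1 + eps & t > eps
  t[hit]
}

#' Analytic opposing contact surface
#'
#' Fast closed-form alternative to a mesh for congruent articular
#' geometries: a concave cylindrical cup (trochlear notch), a concave
#' spherical cup (radial head dish), or a half-space slab.
#'
#' @param type `"cylinder_cup"`, `"sphere_cup"` or `"halfspace"`.
#' @param body owning body label.
#' @param ... geometry in body-local coordinates: for a cylinder cup
#'   `origin`, `axis`, `radius`, `axial_range` (length 2), `d0` (sector
#'   centre direction) and `half_angle`; for a sphere cup `center`,
#'   `radius`, `d0`, `half_angle`; for a halfspace `point` and `normal`
#'   (outward from the material).
#' @return a `contact_surface`.
#' @export
contact_surface <- function(type = c("cylinder_cup", "sphere_cup", "halfspace"),
                            body, ...) {
  type <- match.arg(type)
  structure(c(list(type = type, body = body), list(...)),
            class = "contact_surface")
}

# penetration of world points into the material behind an analytic surface
analytic_penetration_depths <- function(X, surf, ps_o) {
  Y <- pose_untransform(ps_o, X)        # into the owning body's frame
  if (surf$type == "cylinder_cup") {
    a <- vhat(surf$axis)
    rel <- sweep(Y, 2L, surf$origin)
    z <- as.numeric(rel %*% a)
    rad <- rel - z %*% t(a)
    r <- sqrt(rowSums(rad * rad))
    ang <- acos(pmin(1, pmax(-1, (rad %*% vhat(surf$d0)) / pmax(r, 1e-12))))
    inside <- z >= surf$axial_range[1L] & z <= surf$axial_range[2L] &
      ang <= surf$half_angle
    pmax(ifelse(inside, r - surf$radius, 0), 0)
  } else if (surf$type == "sphere_cup") {
    rel <- sweep(Y, 2L, surf$center)
    r <- sqrt(rowSums(rel * rel))
    ang <- acos(pmin(1, pmax(-1, (rel %*% vhat(surf$d0)) / pmax(r, 1e-12))))
    pmax(ifelse(ang <= surf$half_angle, r - surf$radius, 0), 0)
  } else if (surf$type == "halfspace") {
    n <- vhat(surf$normal)
    d <- as.numeric(sweep(Y, 2L, surf$point) %*% n)
    pmax(-d, 0)
  } else stop("unknown contact surface type")
}

# ---- aggregation -------------------------------------------------------------

#' Aggregate per-element contact forces into a contact state
#'
#' @param grid a `cartilage_grid`.
#' @param forces per-element normal forces (N).
#' @param points optional world-frame element points (defaults to local
#'   centroids) used for the centre of pressure.
#' @return a `contact_state`: per-element table plus aggregates `area`
#'   (mm^2, summed over loaded elements), `total_force` (N),
#'   `peak_pressure` and `mean_pressure` (MPa), and `cop` (centre of
#'   pressure, mm).
#' @export
aggregate_contact <- function(grid, forces, points = NULL) {
  e <- grid$elements
  if (length(forces) != nrow(e))
    stop("need one force per element (", nrow(e), "), got ", length(forces))
  if (is.null(points)) points <- as.matrix(e[, c("cx", "cy", "cz")])
  pressure <- forces / e$area
  loaded <- forces > 0
  total <- sum(forces)
  cop <- if (any(loaded)) colSums(points[loaded, , drop = FALSE] *
                                    forces[loaded]) / total else c(NA, NA, NA)
  structure(list(
    elements = data.frame(id = e$id, force = forces, pressure = pressure,
                          area = e$area, loaded = loaded),
    area = sum(e$area[loaded]),
    total_force = total,
    peak_pressure = if (any(loaded)) max(pressure) else 0,
    mean_pressure = if (any(loaded)) mean(pressure[loaded]) else 0,
    n_loaded = sum(loaded),
    cop = as.numeric(cop)),
    class = "contact_state")
}

#' @export
print.contact_state <- function(x, ...) {
  cat(sprintf(paste0("contact_state: %d loaded elements, area %.1f mm^2, ",
                     "total %.2f N, peak %.3f MPa\n"),
              x$n_loaded, x$area, x$total_force, x$peak_pressure))
  invisible(x)
}
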