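# Tension-only nonlinear ligament bundles. The force-strain law has a
# parabolic "toe" region up to twice the toe strain eps_l, then a linear
# region of stiffness k (N per unit strain); slack bundles carry no force.
# Zero-load lengths are calibrated from a laxity sweep as a fraction
# (default 80 percent) of the maximum path length seen.

#' Ligament bundle strain
#'
#' @param l current bundle length (mm).
#' @param l0 zero-load length (mm), must be positive.
#' @return engineering strain `(l - l0) / l0`; may be negative when slack.
#' @export
bundle_strain <- function(l, l0) {
  if (any(l0 <= 0)) stop("parameter error: l0 must be > 0")
  (l - l0) / l0
}

#' Ligament bundle force from strain
#'
#' Piecewise toe-region law: quadratic `k * eps^2 / (4 * eps_l)` for
#' `0 <= eps <= 2 eps_l`, linear `k * (eps - eps_l)` beyond, zero in
#' compression. Continuous with continuous slope at the knot `eps = 2 eps_l`.
#'
#' @param eps strain (dimensionless), vectorized.
#' @param k stiffness (N per unit strain), `> 0`.
#' @param eps_l toe-region strain parameter (default 0.03).
#' @return force in N (non-negative).
#' @export
bundle_force <- function(eps, k, eps_l = 0.03) {
  if (any(eps_l <= 0)) stop("parameter error: eps_l must be > 0")
  ifelse(eps < 0, 0,
         ifelse(eps <= 2 * eps_l,
                0.25 * k * eps * eps / eps_l,
                k * (eps - eps_l)))
}

#' Construct a ligament bundle
#'
#' @param name bundle label, `"<ligament>-<bundle>"` (e.g.
#'   `"MCL-anterior-central"`).
#' @param origin,insertion attachments: lists `list(body =, point =)` with
#'   the point in body-local mm.
#' @param k stiffness in N per unit strain.
#' @param eps_l toe strain parameter (default 0.03).
#' @param l0 zero-load length (mm); `NA` until calibrated.
#' @param via_points optional ordered list of `list(body =, point =)`
#'   attachments the path threads through.
#' @param wrap_obstacles optional list of analytic obstacles, each
#'   `list(type = "sphere"|"cylinder", body =, center =, radius =, axis =)`
#'   (axis only for cylinders), in body-local coordinates.
#' @return a `ligament_bundle`.
#' @export
ligament_bundle <- function(name, origin, insertion, k, eps_l = 0.03,
                            l0 = NA_real_, via_points = list(),
                            wrap_obstacles = list()) {
  if (k <= 0) stop("parameter error: k must be > 0")
  if (eps_l <= 0) stop("parameter error: eps_l must be > 0")
  structure(list(name = name, origin = origin, insertion = insertion,
                 via_points = via_points, wrap_obstacles = wrap_obstacles,
                 k = k, eps_l = eps_l, l0 = l0),
            class = "ligament_bundle")
}

#' Group ligament bundles into a ligament complex
#'
#' The default elbow model carries 3 MCL-anterior, 3 MCL-posterior, 3 LUCL,
#' 3 RCL and 2 annular bundles (14 in total).
#'
#' @param bundles list of `ligament_bundle` objects.
#' @return a `ligament_complex`.
#' @export
ligament_complex <- function(bundles) {
  stopifnot(all(vapply(bundles, inherits, TRUE, "ligament_bundle")))
  names(bundles) <- vapply(bundles, `[[`, "", "name")
  structure(list(bundles = bundles), class = "ligament_complex")
}

# ligament group of a bundle = name with the trailing "-<bundle>" stripped
bundle_group <- function(name) sub("-[^-]*$", "", name)

#' Per-ligament bundle counts of a complex
#' @param complex a `ligament_complex`.
#' @return named integer vector of bundles per ligament group.
#' @export
bundle_counts <- function(complex) {
  grp <- vapply(complex$bundles, function(b) bundle_group(b$name), "")
  table_ <- table(grp)
  out <- as.integer(table_)
  names(out) <- names(table_)
  out
}

#' @export
print.ligament_complex <- function(x, ...) {
  cnt <- bundle_counts(x)
  cal <- sum(!is.na(vapply(x$bundles, `[[`, 0, "l0")))
  cat(sprintf("ligament_complex: %d bundles (%s); %d calibrated\n",
              length(x$bundles),
              paste(sprintf("%s x%d", names(cnt), cnt), collapse = ", "), cal))
  invisible(x)
}

# ---- path geometry -----------------------------------------------------------

# world-frame polyline of a bundle/muscle path: origin, vias, insertion
path_points_world <- function(origin, via_points, insertion, poses) {
  pts <- vector("list", length(via_points) + 2L)
  att <- c(list(origin), via_points, list(insertion))
  for (i in seq_along(att)) {
    a <- att[[i]]
    ps <- poses[[a$body]]
    if (is.null(ps)) stop("state error: no pose for body '", a$body, "'")
    pts[[i]] <- pose_transform(ps, as.numeric(a$point))
  }
  pts
}

# wrap a single segment around a sphere; returns NULL when no wrap engages
wrap_sphere_segment <- function(p1, p2, C, r) {
  u1 <- p1 - C; u2 <- p2 - C
  d1 <- vnorm(u1); d2 <- vnorm(u2)
  if (d1 <= r || d2 <= r)
    stop("geometry error: path endpoint inside a wrap obstacle")
  seg <- p2 - p1
  t <- sum((C - p1) * seg) / sum(seg * seg)
  if (t <= 0 || t >= 1) return(NULL)
  if (vnorm(p1 + t * seg - C) >= r) return(NULL)
  alpha <- acos(pmin(1, pmax(-1, sum(u1 * u2) / (d1 * d2))))
  g1 <- acos(pmin(1, r / d1)); g2 <- acos(pmin(1, r / d2))
  arc <- alpha - g1 - g2
  if (arc <= 0) return(NULL)
  uh1 <- u1 / d1; uh2 <- u2 / d2
  w1 <- u2 - sum(u2 * uh1) * uh1
  w2 <- u1 - sum(u1 * uh2) * uh2
  if (vnorm(w1) < 1e-12 || vnorm(w2) < 1e-12) return(NULL)  # through centre
  T1 <- C + r * (uh1 * cos(g1) + vhat(w1) * sin(g1))
  T2 <- C + r * (uh2 * cos(g2) + vhat(w2) * sin(g2))
  list(length = sqrt(d1^2 - r^2) + sqrt(d2^2 - r^2) + r * arc,
       d_in = vhat(T1 - p1), d_out = vhat(p2 - T2), center = C)
}

# cylinder wrap via the developable unrolling: wrap in the cross-section
# plane, then combine with the axial offset
wrap_cylinder_segment <- function(p1, p2, C, a, r) {
  a <- vhat(a)
  z1 <- sum((p1 - C) * a); z2 <- sum((p2 - C) * a)
  q1 <- p1 - C - z1 * a; q2 <- p2 - C - z2 * a
  d1 <- vnorm(q1); d2 <- vnorm(q2)
  if (d1 <= r || d2 <= r)
    stop("geometry error: path endpoint inside a wrap obstacle")
  # 2D wrap test in the cross-section
  seg <- q2 - q1
  t <- sum(-q1 * seg) / sum(seg * seg)
  if (t <= 0 || t >= 1) return(NULL)
  if (vnorm(q1 + t * seg) >= r) return(NULL)
  alpha <- acos(pmin(1, pmax(-1, sum(q1 * q2) / (d1 * d2))))
  g1 <- acos(pmin(1, r / d1)); g2 <- acos(pmin(1, r / d2))
  arc <- alpha - g1 - g2
  if (arc <= 0) return(NULL)
  t1 <- sqrt(d1^2 - r^2); t2 <- sqrt(d2^2 - r^2)
  L2 <- t1 + t2 + r * arc
  dz <- z2 - z1
  qh1 <- q1 / d1; qh2 <- q2 / d2
  w1 <- q2 - sum(q2 * qh1) * qh1
  w2 <- q1 - sum(q1 * qh2) * qh2
  T1p <- r * (qh1 * cos(g1) + vhat(w1) * sin(g1))
  T2p <- r * (qh2 * cos(g2) + vhat(w2) * sin(g2))
  T1 <- C + T1p + (z1 + dz * t1 / L2) * a
  T2 <- C + T2p + (z1 + dz * (t1 + r * arc) / L2) * a
  list(length = sqrt(L2^2 + dz^2),
       d_in = vhat(T1 - p1), d_out = vhat(p2 - T2),
       center = C + (z1 + dz * (t1 + 0.5 * r * arc) / L2) * a)
}

# full path geometry: length, end directions, and tension-proportional force
# applications at via points and wrap obstacles
path_geometry <- function(origin, via_points, insertion, poses,
                          wrap_obstacles = list(), straight_line = FALSE) {
  pts <- path_points_world(origin, via_points, insertion, poses)
  n <- length(pts)
  if (straight_line || (length(wrap_obstacles) == 0L && n == 2L)) {
    if (straight_line) pts <- pts[c(1L, n)]
    total <- 0; dirs <- vector("list", length(pts) - 1L)
    for (i in seq_len(length(pts) - 1L)) {
      d <- pts[[i + 1L]] - pts[[i]]
      total <- total + vnorm(d)
      dirs[[i]] <- vhat(d)
    }
    return(list(length = total, d_first = dirs[[1L]],
                d_last = dirs[[length(dirs)]],
                seg_dirs_in = dirs, seg_dirs_out = dirs,
                obstacle_forces = list()))
  }
  obs_world <- lapply(wrap_obstacles, function(o) {
    ps <- poses[[o$body]]
    out <- list(type = o$type, body = o$body,
                center = pose_transform(ps, as.numeric(o$center)),
                radius = o$radius)
    if (identical(o$type, "cylinder"))
      out$axis <- pose_rotate(ps, vhat(as.numeric(o$axis)))
    out
  })
  total <- 0
  d_in_seg <- vector("list", n - 1L)   # direction leaving pts[[i]]
  d_out_seg <- vector("list", n - 1L)  # direction arriving at pts[[i+1]]
  obstacle_forces <- list()
  for (i in seq_len(n - 1L)) {
    p1 <- pts[[i]]; p2 <- pts[[i + 1L]]
    wrapped <- NULL
    for (o in obs_world) {
      w <- if (identical(o$type, "sphere"))
        wrap_sphere_segment(p1, p2, o$center, o$radius)
      else
        wrap_cylinder_segment(p1, p2, o$center, o$axis, o$radius)
      if (!is.null(w)) { w$body <- o$body; wrapped <- w; break }
    }
    if (is.null(wrapped)) {
      d <- vhat(p2 - p1)
      total <- total + vnorm(p2 - p1)
      d_in_seg[[i]] <- d; d_out_seg[[i]] <- d
    } else {
      total <- total + wrapped$length
      d_in_seg[[i]] <- wrapped$d_in
      d_out_seg[[i]] <- wrapped$d_out
      obstacle_forces[[length(obstacle_forces) + 1L]] <-
        list(body = wrapped$body, point = wrapped$center,
             dir = wrapped$d_out - wrapped$d_in)
    }
  }
  list(length = total, d_first = d_in_seg[[1L]], d_last = d_out_seg[[n - 1L]],
       seg_dirs_in = d_in_seg, seg_dirs_out = d_out_seg,
       obstacle_forces = obstacle_forces)
}

#' Wrapped path length of a ligament bundle
#'
#' Length of the path origin -> via points -> insertion, with segments that
#' intersect a wrap obstacle replaced by the tangent-arc-tangent geodesic
#' over the obstacle. Never shorter than the straight origin-insertion
#' distance.
#'
#' @param bundle a `ligament_bundle`.
#' @param poses named list of `pose` objects for every body the bundle
#'   touches.
#' @param straight_line if `TRUE`, return the straight origin-insertion
#'   distance instead (laxity-calibration option).
#' @return length in mm.
#' @export
wrapped_length <- function(bundle, poses, straight_line = FALSE) {
  path_geometry(bundle$origin, bundle$via_points, bundle$insertion, poses,
                bundle$wrap_obstacles, straight_line = straight_line)$length
}

#' Calibrate ligament zero-load lengths from a laxity sweep
#'
#' For each bundle, the zero-load length is `factor` times the maximum
#' (wrapped) origin-insertion path length observed over the laxity trial —
#' the 80 percent correction compensating the small force the examiner
#' applies during the test.
#'
#' @param complex a `ligament_complex`.
#' @param laxity a `motion_trial` spanning the joint's motion range.
#' @param factor correction factor applied to the maximum length
#'   (default 0.8). May be a single value or one per bundle.
#' @param straight_line use straight insertion-origin distances instead of
#'   wrapped path lengths.
#' @return the calibrated `ligament_complex`; attribute `"report"` holds a
#'   data frame with `bundle`, `max_length_mm`, `l0_mm`.
#' @export
estimate_zero_load_lengths <- function(complex, laxity, factor = 0.8,
                                       straight_line = FALSE) {
  nb <- length(complex$bundles)
  if (!inherits(laxity, "motion_trial") || length(laxity$time) == 0L)
    stop("calibration error: laxity trial is empty")
  factor <- rep_len(factor, nb)
  maxlen <- rep(-Inf, nb)
  for (i in seq_along(laxity$time)) {
    poses <- trial_poses(laxity, i)
    for (b in seq_len(nb)) {
      L <- wrapped_length(complex$bundles[[b]], poses,
                          straight_line = straight_line)
      if (L > maxlen[b]) maxlen[b] <- L
    }
  }
  for (b in seq_len(nb)) complex$bundles[[b]]$l0 <- factor[b] * maxlen[b]
  attr(complex, "report") <- data.frame(
    bundle = vapply(complex$bundles, `[[`, "", "name"),
    max_length_mm = maxlen,
    l0_mm = factor * maxlen,
    row.names = NULL)
  complex
}

#' Evaluate ligament forces for a set of body poses
#'
#' Each taut bundle applies its tension along the local path direction at
#' the origin and insertion (equal and opposite), with redirection forces at
#' via points and through wrap-obstacle centres, so the ligament system
#' contributes zero net force and torque to the model.
#'
#' @param complex calibrated `ligament_complex`.
#' @param poses named list of `pose` objects.
#' @return list with `tensions` (named numeric, N) and `applications`, a
#'   data frame of point forces (`body`, world point `px,py,pz`, force
#'   `fx,fy,fz` in N).
#' @export
apply_ligament_forces <- function(complex, poses) {
  nb <- length(complex$bundles)
  tensions <- numeric(nb)
  names(tensions) <- names(complex$bundles)
  rows <- list()
  for (b in seq_len(nb)) {
    bd <- complex$bundles[[b]]
    if (is.na(bd$l0)) stop("state error: bundle '", bd$name,
                           "' has no calibrated zero-load length")
    pg <- path_geometry(bd$origin, bd$via_points, bd$insertion, poses,
                        bd$wrap_obstacles)
    tension <- bundle_force(bundle_strain(pg$length, bd$l0), bd$k, bd$eps_l)
    tensions[b] <- tension
    if (tension <= 0) next
    rows[[length(rows) + 1L]] <-
      path_force_applications(bd$origin, bd$via_points, bd$insertion,
                              poses, pg, tension)
  }
  applications <- if (length(rows)) do.call(rbind, rows) else
    data.frame(body = character(), px = numeric(), py = numeric(),
               pz = numeric(), fx = numeric(), fy = numeric(),
               fz = numeric())
  list(tensions = tensions, applications = applications)
}

# point forces of a taut path under tension T as plain vectors/matrices
path_force_app_list <- function(origin, via_points, insertion, poses,
                                pg, tension) {
  pts <- path_points_world(origin, via_points, insertion, poses)
  att <- c(list(origin), via_points, list(insertion))
  n <- length(pts)
  body <- character(); P <- NULL; F <- NULL
  add <- function(b, p, f) {
    body <<- c(body, b); P <<- rbind(P, p); F <<- rbind(F, f)
  }
  add(att[[1L]]$body, pts[[1L]], tension * pg$d_first)
  if (n > 2L) for (i in 2:(n - 1L)) {
    dir <- pg$seg_dirs_in[[i]] - pg$seg_dirs_out[[i - 1L]]
    add(att[[i]]$body, pts[[i]], tension * dir)
  }
  add(att[[n]]$body, pts[[n]], -tension * pg$d_last)
  for (of in pg$obstacle_forces)
    add(of$body, of$point, tension * of$dir)
  list(body = body, P = P, F = F)
}

# data-frame wrapper used by the exported force interfaces
path_force_applications <- function(origin, via_points, insertion, poses,
                                    pg, tension) {
  ap <- path_force_app_list(origin, via_points, insertion, poses, pg, tension)
  data.frame(body = ap$body, px = ap$P[, 1L], py = ap$P[, 2L],
             pz = ap$P[, 3L], fx = ap$F[, 1L], fy = ap$F[, 2L],
             fz = ap$F[, 3L], row.names = NULL)
}

# default stiffnesses (N per unit strain) per *bundle*: literature linear
# stiffnesses of ~40-70 N/mm per whole ligament, split across its bundles
# and multiplied by typical bundle lengths (~15 mm)
default_ligament_stiffness <- function() {
  c("MCL-anterior" = 350, "MCL-posterior" = 300,
    "LUCL" = 350, "RCL" = 300, "annular" = 200)
}
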