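# Muscle actuators: origin/via/insertion polyline paths with PCSA-scaled PID
# controllers. During forward dynamics each controller tracks the muscle
# length recorded in the inverse-kinematics replay; its output force is
# clamped to [0, F_max] (muscles pull, never push).

#' Global PID gain schedule
#'
#' The controller gains of each muscle scale linearly with its physiological
#' cross-sectional area relative to the reference PCSA (the across-muscle
#' average, 487 mm^2): `gain_i = PCSA_i / 487 * global_gain`. Defaults are
#' the global values P = 50, I = 5, D = 0.0005.
#'
#' @param P,I,D global proportional (N/mm), integral (N/(mm s)) and
#'   derivative (N s/mm) gains.
#' @param reference_PCSA reference cross-sectional area in mm^2.
#' @return a `gain_schedule`.
#' @export
gain_schedule <- function(P = 50, I = 5, D = 0.0005, reference_PCSA = 487) {
  if (any(c(P, I, D, reference_PCSA) <= 0))
    stop("all gains and the reference PCSA must be > 0")
  structure(list(P = P, I = I, D = D, reference_PCSA = reference_PCSA),
            class = "gain_schedule")
}

#' Scale PID gains by muscle cross-sectional area
#'
#' @param PCSA physiological cross-sectional area (mm^2), `> 0`.
#' @param schedule a `gain_schedule`.
#' @return named numeric `(P, I, D)` after scaling by
#'   `PCSA / reference_PCSA`.
#' @export
scale_gains <- function(PCSA, schedule = gain_schedule()) {
  if (any(PCSA <= 0)) stop("parameter error: PCSA must be > 0")
  r <- PCSA / schedule$reference_PCSA
  c(P = r * schedule$P, I = r * schedule$I, D = r * schedule$D)
}

#' Construct a muscle actuator
#'
#' @param name muscle label (e.g. `"biceps-long"`).
#' @param origin,insertion attachments `list(body =, point =)` in body-local
#'   mm.
#' @param PCSA physiological cross-sectional area (mm^2).
#' @param F_max maximum force (N); defaults to `0.5 * PCSA` (a specific
#'   tension of 0.5 MPa).
#' @param via_points ordered list of `list(body =, point =)` path points.
#' @param schedule `gain_schedule` used to derive this muscle's gains.
#' @return a `muscle_actuator` with zeroed controller state.
#' @export
muscle_actuator <- function(name, origin, insertion, PCSA,
                            F_max = 0.5 * PCSA, via_points = list(),
                            schedule = gain_schedule()) {
  if (PCSA <= 0) stop("parameter error: PCSA must be > 0")
  if (F_max <= 0) stop("parameter error: F_max must be > 0")
  structure(list(name = name, origin = origin, insertion = insertion,
                 via_points = via_points, PCSA = PCSA, F_max = F_max,
                 gains = scale_gains(PCSA, schedule),
                 state = list(integral = 0, prev_error = 0)),
            class = "muscle_actuator")
}

#' @export
print.muscle_actuator <- function(x, ...) {
  cat(sprintf("muscle_actuator '%s': PCSA %.0f mm^2, F_max %.0f N, gains P=%.2f I=%.3f D=%.2e\n",
              x$name, x$PCSA, x$F_max, x$gains["P"], x$gains["I"], x$gains["D"]))
  invisible(x)
}

#' Current muscle path length
#'
#' Polyline length origin -> via points -> insertion in the world frame.
#'
#' @param m a `muscle_actuator`.
#' @param poses named list of `pose` objects for every body on the path.
#' @return length in mm.
#' @export
muscle_length <- function(m, poses) {
  pts <- path_points_world(m$origin, m$via_points, m$insertion, poses)
  total <- 0
  for (i in seq_len(length(pts) - 1L))
    total <- total + vnorm(pts[[i + 1L]] - pts[[i]])
  total
}

#' One discrete PID controller update for a muscle
#'
#' Error convention: `e = l_current - l_target`, so a longer-than-target
#' muscle produces tension. Rectangular integration, backward-difference
#' derivative, controller state zero at trial start, output clamped to
#' `[0, F_max]` with integral anti-windup (the accumulator freezes while
#' the clamp is active and the error pushes further into it).
#'
#' @param m a `muscle_actuator` (carries gains and controller state).
#' @param l_target,l_current target and current lengths (mm).
#' @param dt controller step (s), `> 0`.
#' @return list with `force` (N) and the updated `muscle`.
#' @export
pid_update <- function(m, l_target, l_current, dt) {
  if (dt <= 0) stop("dt must be > 0")
  e <- l_current - l_target
  prev <- m$state$prev_error
  integ_try <- m$state$integral + e * dt
  u <- m$gains[["P"]] * e + m$gains[["I"]] * integ_try +
    m$gains[["D"]] * (e - prev) / dt
  force <- min(max(u, 0), m$F_max)
  windup <- (u > m$F_max && e > 0) || (u < 0 && e < 0)
  m$state$integral <- if (windup) m$state$integral else integ_try
  m$state$prev_error <- e
  list(force = force, muscle = m)
}

# vectorized controller update used by the engine; st is a list of numeric
# vectors (integral, prev) and gains a 3 x n matrix rows P, I, D
pid_update_vec <- function(e, st, gains, fmax, dt) {
  prev <- st$prev
  integ_try <- st$integral + e * dt
  u <- gains[1L, ] * e + gains[2L, ] * integ_try + gains[3L, ] * (e - prev) / dt
  force <- pmin(pmax(u, 0), fmax)
  windup <- (u > fmax & e > 0) | (u < 0 & e < 0)
  st$integral <- ifelse(windup, st$integral, integ_try)
  st$prev <- e
  list(force = force, state = st)
}

#' Point-force applications of a set of muscle forces
#'
#' Tension acts along the terminal path segments at origin and insertion;
#' via points receive the redirection force, so the muscle system applies
#' zero net force and torque to the model as a whole.
#'
#' @param muscles list of `muscle_actuator` objects.
#' @param poses named list of `pose` objects.
#' @param forces one non-negative force per muscle (N).
#' @return data frame of point forces (`body`, `px,py,pz`, `fx,fy,fz`).
#' @export
apply_muscle_forces <- function(muscles, poses, forces) {
  stopifnot(length(forces) == length(muscles))
  rows <- list()
  for (i in seq_along(muscles)) {
    if (forces[i] <= 0) next
    m <- muscles[[i]]
    pg <- path_geometry(m$origin, m$via_points, m$insertion, poses)
    rows[[length(rows) + 1L]] <-
      path_force_applications(m$origin, m$via_points, m$insertion, poses,
                              pg, forces[i])
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(body = character(), px = numeric(), py = numeric(),
               pz = numeric(), fx = numeric(), fy = numeric(),
               fz = numeric())
}

# default muscle set: PCSA (mm^2) of the six modelled elements, literature
# order of magnitude (triceps long/lateral/medial, biceps long/short,
# brachialis)
default_muscle_pcsa <- function() {
  c("triceps-long" = 570, "triceps-lateral" = 450, "triceps-medial" = 450,
    "biceps-long" = 310, "biceps-short" = 270, "brachialis" = 710)
}
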