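# ---- small vector helpers (all lengths in mm, angles in rad) -----------------

vnorm <- function(x) sqrt(sum(x * x))

vhat <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  x / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# skew-symmetric cross-product matrix
skew <- function(v) {
  matrix(c(0, v[3L], -v[2L],
           -v[3L], 0, v[1L],
           v[2L], -v[1L], 0), 3L, 3L)
}

# ---- quaternions (w, x, y, z convention, unit norm) --------------------------

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q * q))

quat_mul <- function(a, b) {
  c(a[1L] * b[1L] - a[2L] * b[2L] - a[3L] * b[3L] - a[4L] * b[4L],
    a[1L] * b[2L] + a[2L] * b[1L] + a[3L] * b[4L] - a[4L] * b[3L],
    a[1L] * b[3L] - a[2L] * b[4L] + a[3L] * b[1L] + a[4L] * b[2L],
    a[1L] * b[4L] + a[2L] * b[3L] - a[3L] * b[2L] + a[4L] * b[1L])
}

quat_conj <- function(q) c(q[1L], -q[2L], -q[3L], -q[4L])

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q numeric length-4 quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @keywords internal
quat_to_mat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y * y + z * z), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x * x + z * z), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x * x + y * y)),
         3L, 3L)
}

mat_to_quat <- function(R) {
  tr <- R[1L, 1L] + R[2L, 2L] + R[3L, 3L]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3L, 2L] - R[2L, 3L]) / s,
           (R[1L, 3L] - R[3L, 1L]) / s,
           (R[2L, 1L] - R[1L, 2L]) / s)
  } else {
    i <- which.max(c(R[1L, 1L], R[2L, 2L], R[3L, 3L]))
    if (i == 1L) {
      s <- sqrt(1 + R[1L, 1L] - R[2L, 2L] - R[3L, 3L]) * 2
      q <- c((R[3L, 2L] - R[2L, 3L]) / s, 0.25 * s,
             (R[1L, 2L] + R[2L, 1L]) / s, (R[1L, 3L] + R[3L, 1L]) / s)
    } else if (i == 2L) {
      s <- sqrt(1 + R[2L, 2L] - R[1L, 1L] - R[3L, 3L]) * 2
      q <- c((R[1L, 3L] - R[3L, 1L]) / s, (R[1L, 2L] + R[2L, 1L]) / s,
             0.25 * s, (R[2L, 3L] + R[3L, 2L]) / s)
    } else {
      s <- sqrt(1 + R[3L, 3L] - R[1L, 1L] - R[2L, 2L]) * 2
      q <- c((R[2L, 1L] - R[1L, 2L]) / s, (R[1L, 3L] + R[3L, 1L]) / s,
             (R[2L, 3L] + R[3L, 2L]) / s, 0.25 * s)
    }
  }
  quat_normalize(q)
}

# axis-angle to quaternion; axis need not be unit
quat_from_axis_angle <- function(axis, angle) {
  a <- vhat(axis)
  c(cos(angle / 2), sin(angle / 2) * a)
}

# elementary rotation matrices
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L, 3L)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)

# ---- poses -------------------------------------------------------------------

#' Construct a rigid-body pose
#'
#' A pose is the position of the body-frame origin (mm, world coordinates)
#' plus a unit quaternion giving the body-to-world rotation.
#'
#' @param p numeric length-3 position (mm).
#' @param q numeric length-4 unit quaternion `(w, x, y, z)`.
#' @return a `pose` object (list with `p`, `q`).
#' @export
pose <- function(p = c(0, 0, 0), q = c(1, 0, 0, 0)) {
  stopifnot(length(p) == 3L, length(q) == 4L)
  q <- quat_normalize(as.numeric(q))
  structure(list(p = as.numeric(p), q = q, R = quat_to_mat(q)),
            class = "pose")
}

pose_identity <- function() pose()

.pose_R <- function(ps) if (is.null(ps$R)) quat_to_mat(ps$q) else ps$R

# transform local points (n x 3 matrix or length-3 vector) to world
pose_transform <- function(ps, X) {
  R <- .pose_R(ps)
  if (is.matrix(X)) {
    sweep(X %*% t(R), 2L, ps$p, "+")
  } else {
    as.numeric(R %*% X + ps$p)
  }
}

# rotate local directions to world (no translation)
pose_rotate <- function(ps, X) {
  R <- .pose_R(ps)
  if (is.matrix(X)) X %*% t(R) else as.numeric(R %*% X)
}

# world point to local coordinates
pose_untransform <- function(ps, X) {
  R <- .pose_R(ps)
  if (is.matrix(X)) {
    sweep(X, 2L, ps$p, "-") %*% R
  } else {
    as.numeric(t(R) %*% (X - ps$p))
  }
}

# velocity of a world-frame point attached to a body with twist (v at origin, w)
point_velocity <- function(ps, twist, x_world) {
  if (is.matrix(x_world)) {
    r <- sweep(x_world, 2L, ps$p, "-")
    wx <- twist$w
    # w x r for each row
    cbind(wx[2L] * r[, 3L] - wx[3L] * r[, 2L],
          wx[3L] * r[, 1L] - wx[1L] * r[, 3L],
          wx[1L] * r[, 2L] - wx[2L] * r[, 1L]) +
      matrix(twist$v, nrow(x_world), 3L, byrow = TRUE)
  } else {
    twist$v + vcross(twist$w, x_world - ps$p)
  }
}

# ---- anatomical frames -------------------------------------------------------

#' Build a right-handed anatomical coordinate frame from bony landmarks
#'
#' The frame follows the convention used throughout the package for a right
#' arm: the first axis points medially (M-L), the second anteriorly (A-P),
#' and the third proximally (S-I). For the humerus the landmarks are the
#' medial and lateral epicondyles plus a proximal shaft point; analogous
#' triads are used for the ulna and radius.
#'
#' @param landmarks named list with entries `medial`, `lateral`,
#'   `proximal` (each a length-3 point, mm): `medial`/`lateral` span the
#'   joint axis, `proximal` lies along the shaft.
#' @param origin optional frame origin; defaults to the midpoint of the
#'   medial and lateral landmarks.
#' @return an `anatomical_frame`: list with `origin` (mm) and `axes`, a 3x3
#'   matrix whose columns are the M-L, A-P and S-I unit axes (world
#'   coordinates of the frame directions), right-handed with determinant +1.
#' @export
build_anatomical_frame <- function(landmarks, origin = NULL) {
  need <- c("medial", "lateral", "proximal")
  if (!all(need %in% names(landmarks)))
    stop("landmarks must contain 'medial', 'lateral' and 'proximal'")
  m <- as.numeric(landmarks$medial)
  l <- as.numeric(landmarks$lateral)
  p <- as.numeric(landmarks$proximal)
  if (vnorm(m - l) < 1e-9) stop("degenerate landmarks: medial and lateral coincide")
  mid <- (m + l) / 2
  ml <- vhat(m - l)                      # +M-L points medially (right arm)
  shaft <- p - mid
  if (vnorm(vcross(ml, shaft)) < 1e-9 * max(vnorm(shaft), 1))
    stop("degenerate landmarks: collinear")
  ap <- vhat(vcross(vhat(shaft), ml))    # anterior = SI x ML
  si <- vcross(ml, ap)                   # completes right-handed triad
  axes <- cbind(ml, ap, si)
  colnames(axes) <- c("ML", "AP", "SI")
  structure(list(origin = if (is.null(origin)) mid else as.numeric(origin),
                 axes = axes),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame\n  origin:", sprintf("%.3f", x$origin), "mm\n")
  cat("  axes (columns M-L, A-P, S-I):\n")
  print(round(x$axes, 6))
  invisible(x)
}

# express a local frame in world coordinates given the body pose
frame_in_world <- function(frame, ps) {
  R <- .pose_R(ps)
  structure(list(origin = as.numeric(R %*% frame$origin + ps$p),
                 axes = R %*% frame$axes),
            class = "anatomical_frame")
}
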