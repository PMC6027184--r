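# Motion trials: uniform time grid plus a pose series (position + unit
# quaternion) per body. Trials are both the input of the inverse-kinematics
# replay and the reference against which forward dynamics is evaluated.

#' Construct a motion trial
#'
#' @param label trial label (`"10deg/s"`, `"60deg/s"`, `"free"`,
#'   `"laxity"`, or any other tag).
#' @param time strictly increasing, uniformly spaced time grid (s).
#' @param poses named list, one entry per body, each an `n x 7` matrix with
#'   columns `x, y, z, qw, qx, qy, qz` (mm and unit quaternion rows).
#' @return a `motion_trial`.
#' @export
motion_trial <- function(label, time, poses) {
  time <- as.numeric(time)
  n <- length(time)
  if (n >= 2L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("input error: time grid must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9 * max(dt))
      stop("input error: time grid must be uniform")
  }
  poses <- lapply(poses, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 7L || nrow(m) != n)
      stop("each pose series must be an n x 7 matrix matching the time grid")
    colnames(m) <- c("x", "y", "z", "qw", "qx", "qy", "qz")
    # enforce quaternion sign continuity so interpolation stays short-arc
    for (i in seq_len(nrow(m))[-1L])
      if (sum(m[i, 4:7] * m[i - 1L, 4:7]) < 0) m[i, 4:7] <- -m[i, 4:7]
    m[, 4:7] <- m[, 4:7] / sqrt(rowSums(m[, 4:7, drop = FALSE]^2))
    m
  })
  structure(list(label = label, time = time, poses = poses),
            class = "motion_trial")
}

#' @export
print.motion_trial <- function(x, ...) {
  cat(sprintf("motion_trial '%s': %d frames @ %.0f Hz, %.2f s, bodies: %s\n",
              x$label, length(x$time),
              if (length(x$time) > 1L) 1 / diff(x$time)[1L] else 0,
              if (length(x$time)) diff(range(x$time)) else 0,
              paste(names(x$poses), collapse = ", ")))
  invisible(x)
}

# named list of pose objects at frame i
trial_poses <- function(trial, i) {
  lapply(trial$poses, function(m) pose(m[i, 1:3], m[i, 4:7]))
}

# linear position / normalized-linear quaternion interpolation at time t
trial_pose_at <- function(trial, body, t) {
  tm <- trial$time
  m <- trial$poses[[body]]
  if (t <= tm[1L]) return(pose(m[1L, 1:3], m[1L, 4:7]))
  n <- length(tm)
  if (t >= tm[n]) return(pose(m[n, 1:3], m[n, 4:7]))
  i <- findInterval(t, tm)
  s <- (t - tm[i]) / (tm[i + 1L] - tm[i])
  p <- (1 - s) * m[i, 1:3] + s * m[i + 1L, 1:3]
  q <- (1 - s) * m[i, 4:7] + s * m[i + 1L, 4:7]
  pose(p, q)
}

# finite-difference twist (v at body origin, w) of a prescribed body at t
trial_twist_at <- function(trial, body, t, h = 1e-3) {
  p1 <- trial_pose_at(trial, body, t - h / 2)
  p2 <- trial_pose_at(trial, body, t + h / 2)
  v <- (p2$p - p1$p) / h
  dq <- quat_mul(p2$q, quat_conj(p1$q))
  ang <- 2 * atan2(vnorm(dq[2:4]), dq[1L])
  w <- if (ang < 1e-12) c(0, 0, 0) else vhat(dq[2:4]) * ang / h
  list(v = v, w = w)
}

#' Write a motion trial to CSV
#'
#' Long format with columns `time_s, body, x_mm, y_mm, z_mm, qw, qx, qy, qz`.
#'
#' @param trial a `motion_trial`.
#' @param path output CSV path.
#' @export
write_trial_csv <- function(trial, path) {
  rows <- lapply(names(trial$poses), function(b) {
    m <- trial$poses[[b]]
    data.frame(time_s = trial$time, body = rep(b, length(trial$time)),
               x_mm = m[, 1L], y_mm = m[, 2L], z_mm = m[, 3L],
               qw = m[, 4L], qx = m[, 5L], qy = m[, 6L], qz = m[, 7L])
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$time_s, df$body), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a motion trial from CSV
#' @param path CSV path in the format written by [write_trial_csv()].
#' @param label trial label; defaults to the file stem.
#' @return a `motion_trial`.
#' @export
read_trial_csv <- function(path, label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "body", "x_mm", "y_mm", "z_mm", "qw", "qx", "qy", "qz")
  if (!all(need %in% names(df))) stop("trial CSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  tm <- sort(unique(df$time_s))
  poses <- lapply(split(df, df$body), function(d) {
    d <- d[order(d$time_s), ]
    as.matrix(d[, c("x_mm", "y_mm", "z_mm", "qw", "qx", "qy", "qz")])
  })
  motion_trial(label, tm, poses)
}
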