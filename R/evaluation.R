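# Model-vs-experiment comparison: anatomical 6-DOF decomposition of the
# forearm bones relative to the humerus, RMS error and Pearson correlation
# per channel, EMG envelope processing, and muscle-force normalization.

# body-fixed X-Y-Z Euler angles (flexion-extension about M-L, then
# varus-valgus, then internal-external) from a relative rotation matrix
euler_xyz <- function(R, warn_gimbal = TRUE) {
  b <- asin(pmin(1, pmax(-1, R[1L, 3L])))
  if (warn_gimbal && abs(abs(b) - pi / 2) < deg2rad(1))
    warning("varus-valgus angle within 1 degree of gimbal lock")
  a <- atan2(-R[2L, 3L], R[3L, 3L])
  c_ <- atan2(-R[1L, 2L], R[1L, 1L])
  c(a, b, c_)
}

#' Decompose relative bone poses into anatomical rotations and translations
#'
#' The ulna and radius anatomical frames are expressed in the humeral frame
#' and decomposed into a body-fixed flexion-extension -> varus-valgus ->
#' internal-external Euler sequence (rotations about the humeral M-L, then
#' A-P, then S-I directions, a joint-coordinate-system convention);
#' translations are the child frame origin in humeral frame coordinates
#' (M-L, A-P, S-I components).
#'
#' @param poses_series list with `time` and per-body `n x 7` pose matrices
#'   (a `motion_trial` or the `poses`+`time` of a `simulation_result`).
#' @param frames named list of body-local `anatomical_frame`s, with at least
#'   `humerus` and one of `ulna`, `radius`.
#' @return a `kinematics_series`: list with `time` and `channels`, an
#'   `n x 12` matrix `<bone>_<FE|VV|IE>` (deg) and `<bone>_<ML|AP|SI>` (mm).
#' @export
decompose_kinematics <- function(poses_series, frames) {
  poses <- if (inherits(poses_series, "motion_trial")) poses_series$poses
  else poses_series$poses
  time <- poses_series$time
  if (!("humerus" %in% names(frames)))
    stop("frames must include 'humerus'")
  bones <- intersect(c("ulna", "radius"), intersect(names(frames), names(poses)))
  if (!length(bones)) stop("no ulna/radius frames to decompose")
  n <- length(time)
  cols <- as.vector(outer(c("FE", "VV", "IE", "ML", "AP", "SI"), bones,
                          function(ch, b) paste(b, ch, sep = "_")))
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  warned <- FALSE
  for (i in seq_len(n)) {
    ph <- pose(poses$humerus[i, 1:3], poses$humerus[i, 4:7])
    fh <- frame_in_world(frames$humerus, ph)
    for (b in bones) {
      pb <- pose(poses[[b]][i, 1:3], poses[[b]][i, 4:7])
      fb <- frame_in_world(frames[[b]], pb)
      Rrel <- t(fh$axes) %*% fb$axes
      ang <- withCallingHandlers(
        euler_xyz(Rrel, warn_gimbal = !warned),
        warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
      tr <- as.numeric(t(fh$axes) %*% (fb$origin - fh$origin))
      out[i, paste(b, c("FE", "VV", "IE"), sep = "_")] <- rad2deg(ang)
      out[i, paste(b, c("ML", "AP", "SI"), sep = "_")] <- tr
    }
  }
  if (warned) warning("varus-valgus angle approached gimbal lock in the series")
  structure(list(time = time, channels = out), class = "kinematics_series")
}

#' Root-mean-square error between two series
#' @param a,b numeric series of equal length (>= 2).
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rms_error <- function(a, b) {
  if (length(a) != length(b)) stop("shape error: series lengths differ")
  if (length(a) < 2L) stop("need at least 2 samples")
  sqrt(mean((a - b)^2))
}

#' Pearson product-moment correlation between two series
#' @param a,b numeric series of equal length with nonzero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("shape error: series lengths differ")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: a series has zero variance")
  as.numeric(stats::cor(a, b))
}

#' Channel-by-channel kinematic comparison report
#'
#' RMS error and Pearson correlation for each of the 12 anatomical channels
#' (2 bones x 6 DOF), with correlations above 0.8 flagged as good. The
#' predicted series is linearly resampled onto the reference time grid
#' before comparison. Row order: I-E, VR-VL, F-E rotations for ulna then
#' radius, then S-I, A-P, M-L translations for ulna then radius.
#'
#' @param reference,predicted `kinematics_series` objects with matching
#'   channel sets.
#' @return a `kinematics_report` data frame with columns `channel`, `unit`,
#'   `rms_error`, `correlation`, `good` (r > 0.8).
#' @export
build_report <- function(reference, predicted) {
  chans <- colnames(reference$channels)
  if (!all(chans %in% colnames(predicted$channels)))
    stop("report error: predicted series lacks channels: ",
         paste(setdiff(chans, colnames(predicted$channels)), collapse = ", "))
  row_order <- as.vector(outer(c("IE", "VV", "FE"), c("ulna", "radius"),
                               function(ch, b) paste(b, ch, sep = "_")))
  row_order <- c(row_order,
                 as.vector(outer(c("SI", "AP", "ML"), c("ulna", "radius"),
                                 function(ch, b) paste(b, ch, sep = "_"))))
  row_order <- row_order[row_order %in% chans]
  rows <- lapply(row_order, function(ch) {
    p <- stats::approx(predicted$time, predicted$channels[, ch],
                       xout = reference$time, rule = 2L)$y
    r <- reference$channels[, ch]
    # a flat channel (e.g. a locked DOF) has no defined correlation
    rr <- if (stats::sd(r) == 0 || stats::sd(p) == 0) NA_real_
    else pearson_r(r, p)
    data.frame(channel = ch,
               unit = if (grepl("_(FE|VV|IE)$", ch)) "deg" else "mm",
               rms_error = rms_error(r, p),
               correlation = rr)
  })
  rep_ <- do.call(rbind, rows)
  rep_$good <- !is.na(rep_$correlation) & rep_$correlation > 0.8
  class(rep_) <- c("kinematics_report", "data.frame")
  rep_
}

#' @export
print.kinematics_report <- function(x, ...) {
  cat(sprintf("kinematics_report: %d channels, %d/%d good correlations (r > 0.8)\n",
              nrow(x), sum(x$good), nrow(x)))
  df <- data.frame(x)
  df$rms_error <- sprintf("%.2f", df$rms_error)
  df$correlation <- sprintf("%.2f", df$correlation)
  print(df, row.names = FALSE)
  invisible(x)
}

# ---- EMG processing ----------------------------------------------------------

# biquad coefficients of a 2nd-order Butterworth low-pass (bilinear
# transform with prewarping); returns list(b, a) with a[1] = 1
butter2_lowpass <- function(fc, fs) {
  if (fs <= 2 * fc) stop("sampling rate must exceed twice the cutoff")
  K <- tan(pi * fc / fs)
  a0 <- 1 + sqrt(2) * K + K * K
  list(b = c(K * K, 2 * K * K, K * K) / a0,
       a = c(1, 2 * (K * K - 1) / a0, (1 - sqrt(2) * K + K * K) / a0))
}

# direct-form II transposed filtering, zero initial state
biquad_filter <- function(x, coef) {
  b <- coef$b; a <- coef$a
  y <- numeric(length(x))
  z1 <- 0; z2 <- 0
  for (i in seq_along(x)) {
    y[i] <- b[1L] * x[i] + z1
    z1 <- b[2L] * x[i] - a[2L] * y[i] + z2
    z2 <- b[3L] * x[i] - a[3L] * y[i]
  }
  y
}

# |H(f)| of the digital biquad at frequency f (Hz) for sampling rate fs
biquad_gain <- function(coef, f, fs) {
  z <- exp(-2i * pi * f / fs)
  Mod((coef$b[1L] + coef$b[2L] * z + coef$b[3L] * z^2) /
        (1 + coef$a[2L] * z + coef$a[3L] * z^2))
}

#' Process raw EMG into normalized linear envelopes
#'
#' Standard surface-EMG conditioning: each channel is demeaned, rectified,
#' low-pass filtered with a second-order Butterworth at 6 Hz, and divided by
#' its own maximum over the trial, so every active channel peaks at exactly 1.
#'
#' @param raw numeric vector, matrix (samples x channels) or data frame of
#'   raw EMG; a `time`/`time_s` column is carried through if present.
#' @param rate sampling rate in Hz (default 1400); must exceed twice the
#'   cutoff.
#' @param cutoff low-pass cutoff in Hz (default 6).
#' @param zero_phase apply the filter forward and backward instead of the
#'   single causal pass (doubles the effective order; off by default).
#' @return an `emg_envelope`: list with `time` (s) and `envelopes`
#'   (samples x channels, each active channel scaled to max 1).
#' @export
process_emg <- function(raw, rate = 1400, cutoff = 6, zero_phase = FALSE) {
  if (rate <= 2 * cutoff)
    stop("sampling rate must be above twice the cutoff (Nyquist)")
  time <- NULL
  if (is.data.frame(raw)) {
    tc <- intersect(c("time_s", "time"), names(raw))
    if (length(tc)) {
      time <- raw[[tc[1L]]]
      raw <- raw[, setdiff(names(raw), tc), drop = FALSE]
    }
    raw <- as.matrix(raw)
  }
  if (!is.matrix(raw)) raw <- matrix(raw, ncol = 1L)
  if (is.null(time)) time <- (seq_len(nrow(raw)) - 1L) / rate
  coef <- butter2_lowpass(cutoff, rate)
  env <- raw
  for (j in seq_len(ncol(raw))) {
    x <- abs(raw[, j] - mean(raw[, j]))
    y <- biquad_filter(x, coef)
    if (zero_phase) y <- rev(biquad_filter(rev(y), coef))
    m <- max(y)
    if (m <= 0) {
      warning("channel ", j, " is identically zero after processing")
      env[, j] <- 0
    } else env[, j] <- y / m
  }
  structure(list(time = time, envelopes = env), class = "emg_envelope")
}

#' Normalize simulated muscle forces to their trial maxima
#'
#' Each muscle's force series is divided by its own peak over the trial,
#' the same normalization applied to the measured EMG envelopes, so model
#' and experiment can be compared on a common 0-1 scale.
#'
#' @param result a `simulation_result` (or a samples x muscles matrix).
#' @return matrix of normalized forces in `[0, 1]`.
#' @export
normalize_muscle_forces <- function(result) {
  Fm <- if (inherits(result, "simulation_result")) result$muscle_forces
  else as.matrix(result)
  out <- Fm
  for (j in seq_len(ncol(Fm))) {
    m <- max(Fm[, j])
    if (m <= 0) {
      warning("muscle ", colnames(Fm)[j] %||% j,
              " produced no force in this trial")
      out[, j] <- 0
    } else out[, j] <- Fm[, j] / m
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
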