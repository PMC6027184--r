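# independent filter helpers for the analytic-gain check
butter2_coef_test <- function(fc, fs) {
  K <- tan(pi * fc / fs)
  a0 <- 1 + sqrt(2) * K + K^2
  list(b = c(K^2, 2 * K^2, K^2) / a0,
       a = c(1, 2 * (K^2 - 1) / a0, (1 - sqrt(2) * K + K^2) / a0))
}
biquad_gain_test <- function(coef, f, fs) {
  z <- exp(-2i * pi * f / fs)
  Mod((coef$b[1] + coef$b[2] * z + coef$b[3] * z^2) /
        (1 + coef$a[2] * z + coef$a[3] * z^2))
}
rotx_t <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
roty_t <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rotz_t <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
mat2quat_t <- function(R) {
  w <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
  c(w, (R[3, 2] - R[2, 3]) / (4 * w), (R[1, 3] - R[3, 1]) / (4 * w),
    (R[2, 1] - R[1, 2]) / (4 * w))
}

# kinematic decomposition, RMS/correlation metrics, EMG processing

mk_series <- function(time, poses) list(time = time, poses = poses)

id_frames <- function() {
  fr <- build_anatomical_frame(list(medial = c(20, 0, 0),
                                    lateral = c(-20, 0, 0),
                                    proximal = c(0, 0, 50)),
                               origin = c(0, 0, 0))
  list(humerus = fr, ulna = fr, radius = fr)
}

pose_row <- function(p = c(0, 0, 0), q = c(1, 0, 0, 0)) c(p, q)

test_that("decomposition recovers pure rotations and translations", {
  frames <- id_frames()
  n <- 2L
  mk <- function(ulna_row) mk_series(c(0, 0.01), list(
    humerus = matrix(rep(pose_row(), each = n), n, 7L),
    ulna = matrix(rep(ulna_row, each = n), n, 7L),
    radius = matrix(rep(pose_row(), each = n), n, 7L)))

  # identity: all channels zero
  ks0 <- decompose_kinematics(mk(pose_row()), frames)
  expect_equal(max(abs(ks0$channels)), 0, tolerance = 1e-9)
  expect_equal(ncol(ks0$channels), 12L)

  # pure 30 deg flexion about the M-L axis
  q30 <- c(cos(pi / 12), sin(pi / 12), 0, 0)
  ks1 <- decompose_kinematics(mk(pose_row(q = q30)), frames)
  expect_equal(unname(ks1$channels[1L, "ulna_FE"]), 30, tolerance = 1e-9)
  expect_equal(unname(ks1$channels[1L, c("ulna_VV", "ulna_IE", "ulna_ML",
                                         "ulna_AP", "ulna_SI")]),
               rep(0, 5L), tolerance = 1e-9)

  # pure 5 mm medial translation
  ks2 <- decompose_kinematics(mk(pose_row(p = c(5, 0, 0))), frames)
  expect_equal(unname(ks2$channels[1L, "ulna_ML"]), 5, tolerance = 1e-12)
  expect_equal(unname(ks2$channels[1L, c("ulna_FE", "ulna_VV", "ulna_IE")]),
               rep(0, 3L), tolerance = 1e-12)
})

test_that("decomposition round-trips random relative poses", {
  frames <- id_frames()
  set.seed(9)
  for (i in 1:20) {
    ang <- runif(3, -1.2, 1.2)  # FE, VV, IE in rad (clear of gimbal)
    ang[2L] <- runif(1, -1.0, 1.0)
    R <- rotx_t(ang[1L]) %*% roty_t(ang[2L]) %*% rotz_t(ang[3L])
    q <- mat2quat_t(R)
    p <- rnorm(3, sd = 10)
    ser <- mk_series(c(0, 1), list(
      humerus = matrix(rep(pose_row(), each = 2L), 2L, 7L),
      ulna = matrix(rep(c(p, q), each = 2L), 2L, 7L),
      radius = matrix(rep(pose_row(), each = 2L), 2L, 7L)))
    ks <- decompose_kinematics(ser, frames)
    got <- ks$channels[1L, c("ulna_FE", "ulna_VV", "ulna_IE")] * pi / 180
    R2 <- rotx_t(got[1L]) %*% roty_t(got[2L]) %*% rotz_t(got[3L])
    expect_equal(R2, R, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(unname(ks$channels[1L, c("ulna_ML", "ulna_AP", "ulna_SI")]),
                 p, tolerance = 1e-9)
  }
})

test_that("rms_error and pearson_r match brute-force loops", {
  expect_equal(rms_error(1:10, 1:10), 0)
  expect_equal(rms_error(1:10, 1:10 + 2), 2)
  expect_error(rms_error(1:3, 1:4), "shape error")

  set.seed(2)
  a <- rnorm(200); b <- rnorm(200)
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  expect_equal(rms_error(a, b), sqrt(s / length(a)), tolerance = 1e-12)

  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  # textbook formula on a 5-point pair
  x <- c(1, 2, 4, 5, 8); y <- c(2, 1, 5, 4, 9)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), num / den, tolerance = 1e-14)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("the kinematics report has 12 ordered rows and flags r > 0.8", {
  frames <- id_frames()
  n <- 60L
  tm <- seq(0, 1, length.out = n)
  th <- 0.5 * sin(2 * pi * tm)
  mkp <- function(th_off, ml_off = 0) {
    u <- t(vapply(seq_len(n), function(i)
      c(ml_off, 0, 0, cos((th[i] + th_off) / 2), sin((th[i] + th_off) / 2),
        0, 0), numeric(7L)))
    list(humerus = matrix(rep(pose_row(), each = n), n, 7L), ulna = u,
         radius = u)
  }
  ref <- mk_series(tm, mkp(0))
  k_ref <- decompose_kinematics(ref, frames)
  rep0 <- build_report(k_ref, k_ref)
  expect_equal(nrow(rep0), 12L)
  expect_true(all(rep0$rms_error == 0))
  # the moving channels self-correlate perfectly; flat (locked) channels
  # have undefined correlation and are never flagged good
  fe <- grepl("_FE$", rep0$channel)
  expect_equal(rep0$correlation[fe], rep(1, sum(fe)))
  expect_true(all(rep0$good[fe]))
  expect_true(all(is.na(rep0$correlation[!fe])))
  expect_false(any(rep0$good[!fe]))
  # rotation rows come bone-block-wise: I-E, VR-VL, F-E for the ulna, then
  # the radius, before the translation rows
  expect_equal(rep0$channel[1:6],
               c("ulna_IE", "ulna_VV", "ulna_FE",
                 "radius_IE", "radius_VV", "radius_FE"))

  # constant 2 deg offset on FE: rms 2, r still 1
  k_off <- decompose_kinematics(mk_series(tm, mkp(2 * pi / 180)), frames)
  rep1 <- build_report(k_ref, k_off)
  expect_equal(rep1$rms_error[rep1$channel == "ulna_FE"], 2, tolerance = 1e-6)
  expect_equal(rep1$correlation[rep1$channel == "ulna_FE"], 1,
               tolerance = 1e-9)

  # shuffled prediction decorrelates on average
  set.seed(33)
  rs <- replicate(20, {
    k_sh <- k_ref
    k_sh$channels <- k_ref$channels[sample(n), , drop = FALSE]
    rp <- build_report(k_ref, k_sh)
    rp$correlation[rp$channel == "ulna_FE"]
  })
  expect_lt(mean(abs(rs)), 0.35)
})

test_that("EMG processing: demean, rectify, Butterworth, normalize", {
  rate <- 1400
  tm <- seq(0, 2, by = 1 / rate)
  # constant signal vanishes after demeaning
  expect_warning(env0 <- process_emg(rep(3, length(tm)), rate),
                 "identically zero")
  expect_true(all(env0$envelopes == 0))

  # 50 Hz sinusoid: mean of |sin| passes; the 50 Hz ripple in |x| (at 100
  # Hz) is attenuated by the analytic digital filter gain
  x <- sin(2 * pi * 50 * tm)
  env <- process_emg(x, rate)
  e <- env$envelopes[, 1L]
  expect_equal(max(e), 1)
  tail_e <- e[tm > 0.5]
  # analytic gain of the biquad at 100 Hz relative to DC
  coef <- butter2_coef_test(6, rate)
  g100 <- biquad_gain_test(coef, 100, rate)
  ripple <- (max(tail_e) - min(tail_e)) / 2
  dc <- mean(tail_e)
  # |x| = 2/pi - 4/pi sum cos(2k w t)/(4k^2-1): first harmonic amplitude
  # relative to DC is 2/3; after filtering it is scaled by g100
  expect_equal(ripple / dc, (2 / 3) * g100, tolerance = 0.1)

  # nonzero channels normalize to exactly 1
  set.seed(4)
  raw <- matrix(rnorm(length(tm) * 2L), ncol = 2L)
  raw[, 2L] <- raw[, 2L] * (1 + sin(2 * pi * tm))
  env2 <- process_emg(raw, rate)
  expect_equal(apply(env2$envelopes, 2L, max), c(1, 1), ignore_attr = TRUE)
  expect_error(process_emg(x, rate = 10), "Nyquist|twice the cutoff")
})

test_that("muscle-force normalization preserves shape and onsets", {
  tm <- seq(0, 1, by = 0.01)
  f1 <- pmax(0, sin(2 * pi * tm)) * 120
  f2 <- pmax(0, sin(2 * pi * tm + 1)) * 40
  Fm <- cbind(a = f1, b = f2)
  nf <- normalize_muscle_forces(Fm)
  expect_equal(apply(nf, 2L, max), c(a = 1, b = 1))
  expect_equal(normalize_muscle_forces(2 * Fm), nf)
  onset <- function(x) which(x > 0.1)[1L]
  expect_equal(onset(nf[, "a"]), onset(f1 / max(f1)))
  expect_warning(normalize_muscle_forces(cbind(z = rep(0, 10L))),
                 "no force")
})

test_that("process_emg recovers a synthetic modulation envelope (r > 0.95)", {
  # known smooth activation bursts standing in for simulated muscle forces
  tm <- seq(0, 3, by = 0.01)
  burst <- function(t0, w, amp) amp * exp(-0.5 * ((tm - t0) / w)^2)
  forces <- cbind("flexor-a" = burst(0.8, 0.25, 90) + burst(2.2, 0.3, 60),
                  "flexor-b" = burst(1.5, 0.4, 120),
                  "extensor" = burst(2.6, 0.2, 45))
  res <- structure(list(time = tm, muscle_forces = forces),
                   class = "simulation_result")
  spec <- trial_spec("60deg/s", seed = 5L)
  raw <- generate_synthetic_emg(res, spec)
  raw2 <- generate_synthetic_emg(res, spec)
  expect_identical(raw, raw2)                      # seeded determinism
  env <- process_emg(raw, rate = spec$emg_rate)
  truth <- normalize_muscle_forces(forces)
  for (j in 1:3) {
    tr_env <- stats::approx(tm, truth[, j], xout = env$time, rule = 2L)$y
    expect_gt(pearson_r(env$envelopes[, j], tr_env), 0.95)
  }
  # an always-silent muscle yields a near-zero envelope before scaling
  forces0 <- cbind(forces, silent = rep(0, length(tm)))
  res0 <- structure(list(time = tm, muscle_forces = forces0),
                    class = "simulation_result")
  raw0 <- suppressWarnings(generate_synthetic_emg(res0, spec))
  env0 <- process_emg(raw0, rate = spec$emg_rate)
  # baseline-only channel: envelope is pure noise floor, uncorrelated with
  # every activation burst
  expect_lt(abs(pearson_r(env0$envelopes[, "silent"],
                          stats::approx(tm, truth[, 1L], xout = env0$time,
                                        rule = 2L)$y)), 0.5)
})
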