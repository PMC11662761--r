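# Joint angles, phase detection, time normalization, representative cycles,
# and the average-angle / RMS gait metrics.

test_that("interior joint angles match forced geometric cases", {
  cases <- list(
    list(hip = c(0, 2), knee = c(0, 1), ankle = c(0, 0), expect = 180), # collinear
    list(hip = c(0, 1), knee = c(0, 0), ankle = c(1, 0), expect = 90),  # orthogonal
    list(hip = c(0, 1), knee = c(0, 0), ankle = c(1, 1), expect = 45))
  for (cs in cases) {
    ct <- constant_pose_track(hip = cs$hip, knee = cs$knee, ankle = cs$ankle)
    ang <- joint_angle_series(ct)
    expect_equal(ang$knee_deg[1], cs$expect, tolerance = 1e-10)
    expect_true(all(ang$hip_deg >= 0 & ang$hip_deg <= 180))
  }
})

test_that("angle series rejects mostly-degenerate geometry", {
  ct <- constant_pose_track(hip = c(0, 0), knee = c(0, 0)) # hip == knee always
  expect_error(joint_angle_series(ct), "degenerate geometry")
})

test_that("phase detection recovers ground-truth boundaries and duty factor", {
  rec <- gen_gait_recording(gait_sim_params(duration_s = 2.4, seed = 1)) # 6 cycles
  ct <- calibrate_track(rec$track, rec$calibration,
                        image_height_px = rec$image_height_px)
  seg <- detect_phases(ct)
  expect_gte(nrow(seg$cycles), 4)
  expect_lte(nrow(seg$cycles), 6)
  tb <- rec$truth$phase_bounds
  for (i in seq_len(nrow(seg$cycles))) {
    j <- which.min(abs(tb$stance_start - seg$cycles$stance_start[i]))
    expect_lte(max(abs(unlist(seg$cycles[i, ]) - unlist(tb[j, -1]))), 2)
  }
  expect_lt(abs(duty_factor(seg) - rec$truth$duty_factor), 0.02)
})

test_that("orientation is auto-detected from stance-phase toe motion", {
  rec <- gen_gait_recording(gait_sim_params(duration_s = 2, seed = 8))
  ct <- calibrate_track(rec$track, rec$calibration,
                        image_height_px = rec$image_height_px)
  mirrored <- ct
  mirrored$x_cm <- -mirrored$x_cm
  seg1 <- detect_phases(ct)
  seg2 <- detect_phases(mirrored)
  expect_identical(seg2$orientation, "-x")
  expect_equal(seg2$cycles, seg1$cycles)
})

test_that("tracks without a stance phase or too short fail cleanly", {
  lms <- KINEMATIC_LANDMARKS
  n <- 200
  coords <- lapply(stats::setNames(seq_along(lms), lms), function(i)
    cbind(seq_len(n) * 0.05 + i, rep(2 + i / 2, n))) # constant forward drift
  ct <- make_calibrated_track(coords)
  expect_warning(seg <- detect_phases(ct), "no complete step cycles")
  expect_equal(nrow(seg$cycles), 0)

  short <- make_calibrated_track(lapply(coords, function(m) m[1:15, ]))
  expect_error(detect_phases(short, phase_params(min_phase = 10)), "too short")
})

test_that("phase normalization preserves endpoints, identity and linearity", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_identical(normalize_phase(v, length(v)), v)

  ramp <- seq(0, 1, length.out = 50)
  out <- normalize_phase(ramp, 100)
  expect_equal(out[1], 0)
  expect_equal(out[100], 1)
  expect_lt(max(abs(out - seq(0, 1, length.out = 100))), 1e-12)

  expect_error(normalize_phase(3, 10), "at least two")
})

test_that("phase normalization error on a sine stays within the chord bound", {
  n_in <- 73
  h <- 2 * pi / (n_in - 1)
  x_in <- seq(0, 2 * pi, length.out = n_in)
  out <- normalize_phase(sin(x_in), 100)
  x_out <- seq(0, 2 * pi, length.out = 100)
  expect_lt(max(abs(out - sin(x_out))), h^2 / 8)
})

test_that("representative cycle is the mean of normalized phases", {
  st <- 110 + 15 * sin(seq(0, pi, length.out = 37))
  sw <- 110 - 10 * sin(seq(0, pi, length.out = 23))
  one <- make_series_with_cycles(list(st), list(sw))
  rc1 <- representative_cycle(one$angles, one$seg)
  expect_length(rc1$knee_deg, 200)
  expect_equal(rc1$knee_deg, c(normalize_phase(st, 100), normalize_phase(sw, 100)))
  expect_equal(rc1$n_cycles_averaged, 1)

  # k identical copies leave the mean unchanged
  four <- make_series_with_cycles(rep(list(st), 4), rep(list(sw), 4))
  rc4 <- representative_cycle(four$angles, four$seg)
  expect_equal(rc4$knee_deg, rc1$knee_deg, tolerance = 1e-12)

  # zero-sum per-cycle constant offsets cancel in the average
  offs <- c(2, -2, 1, -1)
  noisy <- make_series_with_cycles(lapply(offs, function(d) st + d),
                                   lapply(offs, function(d) sw + d))
  rcn <- representative_cycle(noisy$angles, noisy$seg)
  expect_lt(max(abs(rcn$knee_deg - rc1$knee_deg)), 1e-9)

  # swing-first ordering just swaps the halves
  rc_sw <- representative_cycle(one$angles, one$seg, phase_order = "swing_stance")
  expect_equal(rc_sw$knee_deg, rc1$knee_deg[c(101:200, 1:100)])
})

test_that("average angle is the plain mean of the cycle samples", {
  expect_equal(average_angle(make_cycle(rep(120, 200)), "knee"), 120)
  expect_equal(average_angle(make_cycle(c(rep(100, 100), rep(140, 100))), "knee"), 120)
  expect_error(average_angle(make_cycle(rep(1, 200)), "elbow"), "'arg'")
})

test_that("RMS difference is a scaled Euclidean metric on cycle vectors", {
  c1 <- make_cycle(rep(120, 200))
  expect_equal(rms_difference(c1, c1, "knee"), 0)
  expect_equal(rms_difference(c1, make_cycle(rep(125, 200)), "knee"), 5)

  # hand-computed toy curves
  a <- make_cycle(c(10, 20, 30, 40))
  b <- make_cycle(c(12, 18, 33, 39))
  expect_equal(rms_difference(a, b, "knee"), sqrt(4.5), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:10) {
    x <- make_cycle(runif(200, 80, 160))
    y <- make_cycle(runif(200, 80, 160))
    z <- make_cycle(runif(200, 80, 160))
    expect_equal(rms_difference(x, y, "knee"), rms_difference(y, x, "knee"))
    expect_lte(rms_difference(x, z, "knee"),
               rms_difference(x, y, "knee") + rms_difference(y, z, "knee") + 1e-12)
  }
  expect_error(rms_difference(c1, make_cycle(rep(1, 100)), "knee"), "mismatched")
})

test_that("injected knee offsets are recovered by average-angle differences", {
  base <- gait_pipeline(gen_gait_recording(gait_sim_params(duration_s = 2, seed = 21)))
  ref_avg <- average_angle(base$rc, "knee")
  for (delta in c(-10, -5)) {
    run <- gait_pipeline(gen_gait_recording(
      gait_sim_params(duration_s = 2, seed = 21, knee_offset_deg = delta)))
    expect_lt(abs((ref_avg - average_angle(run$rc, "knee")) - (-delta)), 1)
  }
})

test_that("cycle-to-cycle angle noise monotonically increases knee RMS", {
  med_rms <- vapply(c(0, 2, 4), function(sigma) {
    stats::median(vapply(1:20, function(s) {
      noisy <- gait_pipeline(gen_gait_recording(gait_sim_params(
        duration_s = 1.6, seed = 100 + s, cycle_noise_sd_deg = sigma)))
      clean <- gait_pipeline(gen_gait_recording(gait_sim_params(
        duration_s = 1.6, seed = 100 + s)))
      rms_difference(noisy$rc, clean$rc, "knee")
    }, numeric(1)))
  }, numeric(1))
  expect_lt(med_rms[1], med_rms[2])
  expect_lt(med_rms[2], med_rms[3])
})

test_that("within-recording RMS reflects cycle-to-cycle variability", {
  st <- 110 + 15 * sin(seq(0, pi, length.out = 30))
  sw <- 110 - 10 * sin(seq(0, pi, length.out = 20))
  same <- make_series_with_cycles(rep(list(st), 3), rep(list(sw), 3))
  expect_equal(within_recording_rms(same$angles, same$seg, "knee"), 0)
  offs <- c(3, -3, 0)
  var3 <- make_series_with_cycles(lapply(offs, function(d) st + d),
                                  lapply(offs, function(d) sw + d))
  expect_gt(within_recording_rms(var3$angles, var3$seg, "knee"), 1)
})
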