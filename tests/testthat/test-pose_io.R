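# Pose CSV parsing, marker-rectangle calibration, and pixel-to-cm conversion.

write_toy_pose_csv <- function(path, landmarks = KINEMATIC_LANDMARKS,
                               rows = 3, bad_cell = NULL) {
  per <- 3
  h1 <- c("scorer", rep("toy", length(landmarks) * per))
  h2 <- c("bodyparts", rep(landmarks, each = per))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), length(landmarks)))
  body <- lapply(seq_len(rows), function(i)
    c(i - 1, rep(c(10 * i, 20 * i, 1), length(landmarks))))
  body <- do.call(rbind, body)
  if (!is.null(bad_cell)) body[bad_cell[1], bad_cell[2]] <- "oops"
  lines <- c(paste(h1, collapse = ","), paste(h2, collapse = ","),
             paste(h3, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  path
}

test_that("generator output round-trips through the three-header CSV dialect", {
  rec <- gen_gait_recording(gait_sim_params(duration_s = 0.5, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gait_recording(rec$track, path)
  back <- read_pose_track(path)
  expect_equal(back$frames, rec$track$frames)
  expect_identical(back$landmarks, KINEMATIC_LANDMARKS)
  expect_lt(max(abs(back$x_px - rec$track$x_px)), 1e-9)
  expect_lt(max(abs(back$y_px - rec$track$y_px)), 1e-9)
})

test_that("malformed pose files fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_pose_csv(path, landmarks = setdiff(KINEMATIC_LANDMARKS, "toe"))
  expect_error(read_pose_track(path), "landmark 'toe' not found")

  write_toy_pose_csv(path, bad_cell = c(2, 3))
  expect_error(read_pose_track(path), "non-numeric cell.*row 2")

  file.create(path2 <- withr::local_tempfile(fileext = ".csv"))
  expect_error(read_pose_track(path2), "empty|no data")

  writeLines(c("scorer,a", "bodyparts,hip", "coords,x"), path)
  expect_error(read_pose_track(path), "no data rows")
})

test_that("calibration recovers the cm-per-pixel coefficient", {
  markers <- rbind(c(100, 100), c(800, 100), c(800, 500), c(100, 500))
  cal <- compute_calibration(markers, rect_width_cm = 7, rect_height_cm = 4)
  expect_equal(cal$coefficient, 0.01)
  expect_equal(cal$anisotropy, 0)
  # corner order must not matter (matched by sorting)
  cal2 <- compute_calibration(markers[c(3, 1, 4, 2), ])
  expect_equal(cal2$coefficient, cal$coefficient)
})

test_that("calibration rejects anisotropic, degenerate and rotated rectangles", {
  # scale_x = 0.01, scale_y = 0.02 -> anisotropy 2/3
  bad <- rbind(c(0, 0), c(700, 0), c(700, 200), c(0, 200))
  expect_error(compute_calibration(bad), "anisotropy")
  degen <- rbind(c(0, 0), c(0, 0), c(0, 400), c(0, 400))
  expect_error(compute_calibration(degen), "degenerate")
  rot <- rbind(c(0, 0), c(700, 150), c(640, 430), c(-60, 280))
  expect_error(compute_calibration(rot), "axis-aligned|anisotropy")
})

test_that("pixel coordinates convert to y-up centimetres", {
  markers <- rbind(c(100, 100), c(800, 100), c(800, 500), c(100, 500))
  cal <- compute_calibration(markers)
  n <- 4
  x_px <- matrix(100, n, 6, dimnames = list(NULL, KINEMATIC_LANDMARKS))
  y_px <- matrix(500, n, 6, dimnames = list(NULL, KINEMATIC_LANDMARKS))
  track <- eaequant:::new_pose_track(x_px, y_px, NULL, fps = 250)
  ct <- calibrate_track(track, cal, image_height_px = 600)
  expect_equal(unname(ct$x_cm[1, "toe"]), 1.00)
  expect_equal(unname(ct$y_cm[1, "toe"]), 1.00)
})

test_that("dropped frames are linearly interpolated within the bounding values", {
  x_px <- matrix(200, 5, 6, dimnames = list(NULL, KINEMATIC_LANDMARKS))
  y_px <- x_px
  lik <- matrix(1, 5, 6, dimnames = list(NULL, KINEMATIC_LANDMARKS))
  x_px[, "toe"] <- c(200, 200, 999, 400, 400) # frame 3 is a dropout
  lik[3, "toe"] <- 0.1
  cal <- compute_calibration(rbind(c(0, 0), c(700, 0), c(700, 400), c(0, 400)))
  track <- eaequant:::new_pose_track(x_px, y_px, lik, fps = 250)
  ct <- calibrate_track(track, cal, likelihood_min = 0.9, image_height_px = 600)
  expect_equal(unname(ct$x_cm[3, "toe"]), 3.00) # midpoint of 2 and 4 cm
  # convex-hull property on a random gappy series
  set.seed(42)
  v <- cumsum(rnorm(60))
  valid <- runif(60) > 0.3
  valid[c(1, 60)] <- TRUE
  f <- eaequant:::fill_gaps(v, valid)
  iv <- which(valid)
  for (i in which(!valid)) {
    lo <- max(iv[iv < i])
    hi <- min(iv[iv > i])
    expect_gte(f[i], min(v[lo], v[hi]) - 1e-12)
    expect_lte(f[i], max(v[lo], v[hi]) + 1e-12)
  }
})

test_that("calibration is linear: scaling pixels by k and coefficient by 1/k cancels", {
  rec <- gen_gait_recording(gait_sim_params(duration_s = 0.5, seed = 3))
  ct1 <- calibrate_track(rec$track, rec$calibration,
                         image_height_px = rec$image_height_px)
  k <- 2.5
  tr2 <- eaequant:::new_pose_track(rec$track$x_px * k, rec$track$y_px * k,
                                   rec$track$likelihood, rec$track$fps)
  cal2 <- rec$calibration
  cal2$coefficient <- cal2$coefficient / k
  ct2 <- calibrate_track(tr2, cal2, image_height_px = rec$image_height_px * k)
  expect_equal(ct2$x_cm, ct1$x_cm, tolerance = 1e-10)
  expect_equal(ct2$y_cm, ct1$y_cm, tolerance = 1e-10)
})

test_that("the y-axis flip is an involution", {
  rec <- gen_gait_recording(gait_sim_params(duration_s = 0.4, seed = 5))
  H <- rec$image_height_px
  ct1 <- calibrate_track(rec$track, rec$calibration, image_height_px = H)
  flipped <- eaequant:::new_pose_track(rec$track$x_px, H - rec$track$y_px,
                                       rec$track$likelihood, rec$track$fps)
  ct2 <- calibrate_track(flipped, rec$calibration, image_height_px = H)
  # flipping pixel rows mirrors heights: y2 = H * coef - y1
  expect_equal(ct2$y_cm, H * rec$calibration$coefficient - ct1$y_cm,
               tolerance = 1e-10)
})

test_that("a landmark valid in under half the frames is rejected", {
  x_px <- matrix(100, 20, 6, dimnames = list(NULL, KINEMATIC_LANDMARKS))
  lik <- matrix(1, 20, 6, dimnames = list(NULL, KINEMATIC_LANDMARKS))
  lik[1:12, "knee"] <- 0.2
  cal <- compute_calibration(rbind(c(0, 0), c(700, 0), c(700, 400), c(0, 400)))
  track <- eaequant:::new_pose_track(x_px, x_px, lik, fps = 250)
  expect_error(calibrate_track(track, cal, image_height_px = 600),
               "tracking quality insufficient.*knee")
})

test_that("5% seeded dropouts are recovered close to the true trajectory", {
  sd_t <- 0.02
  rec <- gen_gait_recording(gait_sim_params(duration_s = 2, seed = 17,
                                            tracking_noise_sd_cm = sd_t,
                                            dropout_rate = 0.05))
  ct <- calibrate_track(rec$track, rec$calibration,
                        image_height_px = rec$image_height_px)
  dropped <- rec$track$likelihood < 0.9
  expect_gt(sum(dropped), 100)
  dev <- c(abs(ct$x_cm - rec$truth$x_cm)[dropped],
           abs(ct$y_cm - rec$truth$y_cm)[dropped])
  # interpolation error at dropouts sits at the tracking-noise floor, far
  # below the injected junk amplitude (~0.8 cm = 40 SD)
  expect_lt(sqrt(mean(dev^2)), 2 * sd_t)
  expect_lt(max(dev), 0.1 * 0.8)
})
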