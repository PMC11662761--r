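# Independent oracles and small fixture builders used across the suite.

# Brute-force Mann-Whitney one-tailed p by complete enumeration of all
# choose(n + m, n) group assignments of the pooled values (midranks doubled
# to integers so subset sums are exact).
oracle_mwu_p <- function(a, b, alternative = "a_less") {
  pooled <- c(a, b)
  N <- length(pooled)
  n <- length(a)
  r2 <- as.integer(round(2 * rank(pooled)))
  obs <- sum(r2[seq_len(n)])
  sums <- utils::combn(N, n, FUN = function(i) sum(r2[i]))
  if (alternative == "a_less") mean(sums <= obs) else mean(sums >= obs)
}

# Per-label pixel-count g-ratio, written independently of gratio_records.
oracle_g <- function(axon_mask, myelin_mask, id) {
  na <- 0L
  nm <- 0L
  for (v in as.vector(axon_mask)) if (v == id) na <- na + 1L
  for (v in as.vector(myelin_mask)) if (v == id) nm <- nm + 1L
  sqrt(na / (na + nm))
}

# Build a calibrated track directly from named landmark coordinate matrices
# (each an n x 2 matrix of cm coordinates).
make_calibrated_track <- function(coords, fps = 250) {
  lms <- eaequant::KINEMATIC_LANDMARKS
  n <- nrow(coords[[1L]])
  x <- y <- matrix(NA_real_, n, length(lms), dimnames = list(NULL, lms))
  for (lm in lms) {
    x[, lm] <- coords[[lm]][, 1L]
    y[, lm] <- coords[[lm]][, 2L]
  }
  structure(list(frames = n, fps = fps, landmarks = lms, x_cm = x, y_cm = y),
            class = "calibrated_track")
}

# A constant-pose calibrated track (all six landmarks fixed), n frames.
constant_pose_track <- function(hip = c(0, 1), knee = c(0, 0), ankle = c(1, 0),
                                n = 4, fps = 250) {
  coords <- list(iliac_crest = c(-1, 3), hip = hip, knee = knee, ankle = ankle,
                 mtp = c(2, 0), toe = c(3, 0))
  make_calibrated_track(lapply(coords, function(p)
    matrix(rep(p, each = n), n, 2)), fps = fps)
}

# A representative_cycle object from explicit joint curves.
make_cycle <- function(hip, knee = hip, ankle = hip) {
  stopifnot(length(hip) %% 2 == 0)
  structure(list(n_phase = length(hip) %/% 2L, n_cycles_averaged = 1L,
                 phase_order = "stance_swing",
                 hip_deg = hip, knee_deg = knee, ankle_deg = ankle),
            class = "representative_cycle")
}

# A joint_angle_series + phase_segmentation pair built from per-cycle curves:
# `cycles` is a list of lists with elements stance and swing (vectors per
# joint are shared across joints for simplicity unless given).
make_series_with_cycles <- function(stance_curves, swing_curves, fps = 250) {
  series <- numeric(0)
  rows <- list()
  pos <- 1L
  for (i in seq_along(stance_curves)) {
    st <- stance_curves[[i]]
    sw <- swing_curves[[i]]
    rows[[i]] <- data.frame(stance_start = pos, stance_end = pos + length(st),
                            swing_start = pos + length(st),
                            swing_end = pos + length(st) + length(sw))
    series <- c(series, st, sw)
    pos <- pos + length(st) + length(sw)
  }
  ang <- structure(list(frames = length(series), fps = fps,
                        hip_deg = series, knee_deg = series, ankle_deg = series,
                        toe_y_cm = series * 0, ankle_y_cm = series * 0),
                   class = "joint_angle_series")
  seg <- structure(list(cycles = do.call(rbind, rows), orientation = "+x",
                        params = eaequant::phase_params()),
                   class = "phase_segmentation")
  list(angles = ang, seg = seg)
}

# Run the full gait pipeline on a generated recording.
gait_pipeline <- function(rec, ...) {
  ct <- eaequant::calibrate_track(rec$track, rec$calibration,
                                  image_height_px = rec$image_height_px, ...)
  ang <- eaequant::joint_angle_series(ct)
  seg <- eaequant::detect_phases(ct)
  list(ct = ct, ang = ang, seg = seg,
       rc = eaequant::representative_cycle(ang, seg))
}

# Small uniform image_with_masks: left half GM at gm, right half WM at wm.
uniform_eyfp_image <- function(gm = 100, wm = 125, width = 40, height = 20) {
  img <- matrix(gm, height, width)
  gm_mask <- wm_mask <- matrix(FALSE, height, width)
  gm_mask[, seq_len(width / 2)] <- TRUE
  wm_mask[, (width / 2 + 1):width] <- TRUE
  img[wm_mask] <- wm
  eaequant::image_with_masks(img, wm_mask, gm_mask, healthy_wm_mask = wm_mask)
}
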