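# Joint angles, swing/stance segmentation, representative step cycles, and
# the average-angle / RMS-difference gait metrics.

interior_angle_deg <- function(ax, ay, bx, by, cx, cy) {
  ux <- ax - bx; uy <- ay - by
  vx <- cx - bx; vy <- cy - by
  nu <- sqrt(ux^2 + uy^2)
  nv <- sqrt(vx^2 + vy^2)
  cosang <- (ux * vx + uy * vy) / (nu * nv)
  out <- rad2deg(acos(pmin(1, pmax(-1, cosang))))
  out[nu == 0 | nv == 0] <- NA_real_
  out
}

#' Compute per-frame interior joint angles from a calibrated track
#'
#' Interior angles at the hip (iliac crest-hip-knee), knee (hip-knee-ankle)
#' and ankle (knee-ankle-MTP) are computed in every frame as the arc-cosine
#' of the normalized dot product of the two joint segment vectors, in degrees
#' within \[0, 180\]. Frames where two adjacent landmarks coincide yield an
#' undefined angle; these are interpolated from neighbouring frames, but if
#' more than 10% of a joint's frames are undefined the series is rejected.
#'
#' @param track a `calibrated_track` from [calibrate_track()].
#' @return A `joint_angle_series`: per-frame `hip_deg`, `knee_deg`,
#'   `ankle_deg` plus the toe and ankle heights in cm.
#' @export
joint_angle_series <- function(track) {
  stopifnot(inherits(track, "calibrated_track"))
  x <- track$x_cm; y <- track$y_cm
  ang <- function(a, b, c)
    interior_angle_deg(x[, a], y[, a], x[, b], y[, b], x[, c], y[, c])
  joints <- list(
    hip_deg = ang("iliac_crest", "hip", "knee"),
    knee_deg = ang("hip", "knee", "ankle"),
    ankle_deg = ang("knee", "ankle", "mtp"))
  for (j in names(joints)) {
    bad <- !is.finite(joints[[j]])
    if (mean(bad) > 0.10)
      stop(sprintf("degenerate geometry in %.0f%% of frames for %s",
                   100 * mean(bad), j))
    if (any(bad)) joints[[j]] <- fill_gaps(joints[[j]], !bad)
  }
  structure(c(list(frames = track$frames, fps = track$fps), joints,
              list(toe_y_cm = y[, "toe"], ankle_y_cm = y[, "ankle"])),
            class = "joint_angle_series")
}

#' Phase-detection parameters
#'
#' @param smooth_window moving-average window (frames, odd) applied to the
#'   toe x coordinate before differentiation. Default 7 (28 ms at 250
#'   frames/s; wider windows smear the sharp velocity reversal at foot
#'   contact and bias phase boundaries).
#' @param v_min hysteresis threshold on toe horizontal velocity in cm/s;
#'   frames with |v| below it inherit the previous phase label. Default 0.5.
#' @param min_phase minimum phase duration in frames; shorter runs are merged
#'   into their neighbours. Default 10.
#' @return A `phase_params` list.
#' @export
phase_params <- function(smooth_window = 7, v_min = 0.5, min_phase = 10) {
  if (!is_scalar_num(smooth_window) || smooth_window < 1 || smooth_window %% 2 != 1)
    stop("smooth_window must be an odd positive integer")
  if (!is_scalar_num(v_min) || v_min <= 0) stop("v_min must be > 0")
  if (!is_scalar_num(min_phase) || min_phase < 1) stop("min_phase must be >= 1")
  structure(list(smooth_window = as.integer(smooth_window), v_min = v_min,
                 min_phase = as.integer(min_phase)), class = "phase_params")
}

#' Detect swing and stance phases from toe velocity
#'
#' On a treadmill the belt carries the stance foot rearward while the swing
#' foot is brought forward, so with the animal facing +x the smoothed toe
#' horizontal velocity is negative during stance and positive during swing.
#' Frames with velocity inside the `±v_min` dead band inherit the previous
#' label; runs shorter than `min_phase` are merged into their neighbours.
#' Only complete stance-to-swing pairs flanked by valid phases on both sides
#' are emitted, so partial cycles at the recording edges are discarded.
#' Animal orientation is auto-detected from the sign of the median smoothed
#' toe velocity (stance occupies the majority of the cycle) and the x axis is
#' mirrored when the animal faces -x.
#'
#' @param track a `calibrated_track`.
#' @param params a [phase_params()] list.
#' @param orientation `"auto"` (default), `"+x"`, or `"-x"`.
#' @return A `phase_segmentation` whose `cycles` data frame holds half-open
#'   frame intervals `(stance_start, stance_end, swing_start, swing_end)`,
#'   with `stance_end == swing_start`.
#' @export
detect_phases <- function(track, params = phase_params(), orientation = "auto") {
  stopifnot(inherits(track, "calibrated_track"))
  if (!inherits(params, "phase_params")) params <- do.call(phase_params, params)
  n <- track$frames
  if (n <= 2L * params$min_phase)
    stop("track too short for phase detection (need > 2 * min_phase frames)")

  x <- track$x_cm[, "toe"]
  sm <- moving_average(x, params$smooth_window)
  v <- central_velocity(sm, track$fps)
  orientation <- match.arg(orientation, c("auto", "+x", "-x"))
  if (orientation == "auto")
    orientation <- if (stats::median(v) <= 0) "+x" else "-x"
  if (orientation == "-x") v <- -v

  lab <- rep(0L, n)
  lab[v < -params$v_min] <- 1L # stance
  lab[v > params$v_min] <- 2L # swing
  first <- which(lab != 0L)[1L]
  empty <- function() {
    warning("no complete step cycles detected")
    structure(list(cycles = data.frame(stance_start = integer(), stance_end = integer(),
                                       swing_start = integer(), swing_end = integer()),
                   orientation = orientation, params = params),
              class = "phase_segmentation")
  }
  if (is.na(first)) return(empty())
  lab[seq_len(first)] <- lab[first]
  for (i in seq(2L, n)) if (lab[i] == 0L) lab[i] <- lab[i - 1L]

  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < params$min_phase)
    if (length(short) == 0L) break
    i <- short[1L]
    r$values[i] <- if (i == 1L) r$values[i + 1L] else r$values[i - 1L]
    lab <- inverse.rle(r)
  }
  r <- rle(lab)
  k <- length(r$lengths)
  if (k < 4L) return(empty())
  starts <- cumsum(c(1L, r$lengths[-k]))
  ends_excl <- starts + r$lengths
  rows <- list()
  for (i in seq(2L, k - 2L)) {
    if (r$values[i] == 1L && r$values[i + 1L] == 2L &&
        r$values[i - 1L] == 2L && r$values[i + 2L] == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        stance_start = starts[i], stance_end = ends_excl[i],
        swing_start = starts[i + 1L], swing_end = ends_excl[i + 1L])
    }
  }
  if (length(rows) == 0L) return(empty())
  structure(list(cycles = do.call(rbind, rows), orientation = orientation,
                 params = params),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> %d complete cycles (facing %s)\n",
              nrow(x$cycles), x$orientation))
  invisible(x)
}

#' Resample one phase onto a fixed number of samples
#'
#' Linear interpolation of the input onto `n` uniformly spaced points
#' spanning the first to last input sample inclusive, so the endpoints are
#' preserved exactly. This is the time normalization that puts every stance
#' (or swing) phase on a common 100-sample axis before averaging.
#'
#' @param values numeric vector for one phase (length >= 2).
#' @param n number of output samples (default 100).
#' @return Numeric vector of length `n`.
#' @export
normalize_phase <- function(values, n = 100) {
  if (length(values) < 2L) stop("phase must contain at least two samples")
  if (!is_scalar_num(n) || n < 2) stop("n must be >= 2")
  stats::approx(x = seq_along(values), y = values,
                xout = seq(1, length(values), length.out = n))$y
}

#' Build the representative step cycle of a recording
#'
#' Every detected stance phase is time-normalized to `n_phase` samples and
#' the normalized stances averaged pointwise; likewise for the swing phases.
#' The two mean phases are concatenated (stance first by default) into a
#' single `2 * n_phase`-sample representative step cycle per joint — 200
#' samples at the defaults.
#'
#' @param angles a [joint_angle_series()].
#' @param seg a [detect_phases()] segmentation with at least one cycle.
#' @param n_phase samples per phase (default 100).
#' @param phase_order `"stance_swing"` (default) or `"swing_stance"`.
#' @return A `representative_cycle` with per-joint curves of length
#'   `2 * n_phase` and the number of cycles averaged.
#' @export
representative_cycle <- function(angles, seg, n_phase = 100,
                                 phase_order = c("stance_swing", "swing_stance")) {
  stopifnot(inherits(angles, "joint_angle_series"),
            inherits(seg, "phase_segmentation"))
  phase_order <- match.arg(phase_order)
  cyc <- seg$cycles
  if (nrow(cyc) == 0L) stop("no complete step cycles")
  joints <- c("hip_deg", "knee_deg", "ankle_deg")
  out <- list(n_phase = as.integer(n_phase), n_cycles_averaged = nrow(cyc),
              phase_order = phase_order)
  for (j in joints) {
    series <- angles[[j]]
    stance <- vapply(seq_len(nrow(cyc)), function(i)
      normalize_phase(series[cyc$stance_start[i]:(cyc$stance_end[i] - 1L)], n_phase),
      numeric(n_phase))
    swing <- vapply(seq_len(nrow(cyc)), function(i)
      normalize_phase(series[cyc$swing_start[i]:(cyc$swing_end[i] - 1L)], n_phase),
      numeric(n_phase))
    m_st <- rowMeans(stance)
    m_sw <- rowMeans(swing)
    out[[j]] <- if (phase_order == "stance_swing") c(m_st, m_sw) else c(m_sw, m_st)
  }
  structure(out, class = "representative_cycle")
}

#' @export
print.representative_cycle <- function(x, ...) {
  cat(sprintf("<representative_cycle> %d samples (%s), %d cycles averaged\n",
              2L * x$n_phase, x$phase_order, x$n_cycles_averaged))
  invisible(x)
}

joint_curve <- function(cycle, joint) {
  joint <- match.arg(joint, c("hip", "knee", "ankle"))
  cycle[[paste0(joint, "_deg")]]
}

#' Average joint angle over a representative cycle
#'
#' Arithmetic mean of the `2 * n_phase` samples of the named joint's
#' representative-cycle curve, in degrees.
#'
#' @param cycle a [representative_cycle()].
#' @param joint one of `"hip"`, `"knee"`, `"ankle"`.
#' @return Mean angle in degrees.
#' @export
average_angle <- function(cycle, joint) {
  stopifnot(inherits(cycle, "representative_cycle"))
  mean(joint_curve(cycle, joint))
}

#' RMS difference between two representative cycles
#'
#' The joint-movement variability metric: the root mean squared frame-wise
#' difference between a recording's representative cycle and a reference
#' cycle (typically the same animal's pre-induction baseline), over all
#' `2 * n_phase` samples of the named joint. It is a scaled Euclidean metric
#' on the cycle vectors: symmetric, and satisfying the triangle inequality.
#'
#' @param cycle,reference [representative_cycle()] objects with equal
#'   `n_phase`.
#' @param joint one of `"hip"`, `"knee"`, `"ankle"`.
#' @return RMS difference in degrees.
#' @export
rms_difference <- function(cycle, reference, joint) {
  stopifnot(inherits(cycle, "representative_cycle"),
            inherits(reference, "representative_cycle"))
  if (cycle$n_phase != reference$n_phase)
    stop("cycles have mismatched n_phase")
  a <- joint_curve(cycle, joint)
  b <- joint_curve(reference, joint)
  sqrt(mean((a - b)^2))
}

#' Within-recording cycle-to-cycle RMS variability
#'
#' Alternative RMS mode: each individual cycle is normalized to the common
#' `2 * n_phase` axis and its RMS difference to the recording's own mean
#' cycle computed; the per-cycle values are averaged. Measures step-to-step
#' variability inside one recording rather than drift from a baseline.
#'
#' @inheritParams representative_cycle
#' @param joint one of `"hip"`, `"knee"`, `"ankle"`.
#' @return Mean per-cycle RMS difference in degrees.
#' @export
within_recording_rms <- function(angles, seg, joint, n_phase = 100) {
  stopifnot(inherits(angles, "joint_angle_series"),
            inherits(seg, "phase_segmentation"))
  joint <- match.arg(joint, c("hip", "knee", "ankle"))
  cyc <- seg$cycles
  if (nrow(cyc) == 0L) stop("no complete step cycles")
  series <- angles[[paste0(joint, "_deg")]]
  curves <- vapply(seq_len(nrow(cyc)), function(i) {
    c(normalize_phase(series[cyc$stance_start[i]:(cyc$stance_end[i] - 1L)], n_phase),
      normalize_phase(series[cyc$swing_start[i]:(cyc$swing_end[i] - 1L)], n_phase))
  }, numeric(2L * n_phase))
  m <- rowMeans(curves)
  mean(sqrt(colMeans((curves - m)^2)))
}

#' Duty factor of a segmentation
#'
#' Fraction of each complete cycle spent in stance, averaged over cycles.
#'
#' @param seg a [detect_phases()] segmentation.
#' @return Mean duty factor in (0, 1), or `NA` if no cycles.
#' @export
duty_factor <- function(seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  cyc <- seg$cycles
  if (nrow(cyc) == 0L) return(NA_real_)
  st <- cyc$stance_end - cyc$stance_start
  sw <- cyc$swing_end - cyc$swing_start
  mean(st / (st + sw))
}
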