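# Seeded generators for every input the pipeline consumes, with exported
# ground truth. Realism is secondary to verifiability: truth is defined at
# the level the pipeline measures (angle waveforms, phase boundaries, painted
# pixel fractions, rasterized areas, injected folds), not at the level of
# muscle dynamics or microscope optics.

#' Default hindlimb joint-angle waveforms
#'
#' Interior-angle waveforms (degrees) as Fourier series over the warped
#' cycle phase u (stance mapped to \[0, 0.5), swing to \[0.5, 1)):
#' `theta(u) = a0 + sum_k a[k] cos(2 pi k u) + sum_k b[k] sin(2 pi k u)`.
#' The default hip waveform is a triangle-like harmonic series (odd cosine
#' harmonics), giving steady hip extension through stance — the toe tracks
#' the belt rearward at near-constant speed — and a sharp reversal into
#' swing, as on a treadmill; knee and ankle carry smaller flexion
#' excursions.
#'
#' @return Named list of coefficient lists (`a0`, `a`, `b`) for hip, knee
#'   and ankle.
#' @export
gait_waveforms_default <- function() {
  tri <- c(1, 0, 1 / 9, 0, 1 / 25) # odd-harmonic triangle profile
  list(hip = list(a0 = 135, a = -25 * tri, b = 0),
       knee = list(a0 = 120, a = -12 * tri, b = c(-4, 0, 0)),
       ankle = list(a0 = 110, a = -15 * tri, b = c(3, 0, 0)))
}

eval_waveform <- function(w, u) {
  out <- rep(w$a0, length(u))
  a <- w$a
  b <- w$b
  for (k in seq_along(a))
    if (a[k] != 0) out <- out + a[k] * cos(2 * pi * k * u)
  for (k in seq_along(b))
    if (b[k] != 0) out <- out + b[k] * sin(2 * pi * k * u)
  out
}

# Map raw cycle phase to the warped phase used by the waveforms: stance
# occupies u in [0, 0.5), swing u in [0.5, 1), whatever the duty factor.
warp_phase <- function(phi, duty) {
  ifelse(phi < duty, 0.5 * phi / duty, 0.5 + 0.5 * (phi - duty) / (1 - duty))
}

#' Gait simulation parameters
#'
#' @param fps frame rate (default 250 frames/s).
#' @param duration_s recording length in seconds (default 4).
#' @param cadence_hz step cycles per second (default 2.5).
#' @param duty_factor stance fraction of the cycle in (0, 1) (default 0.6).
#' @param lengths named list of segment lengths in cm: `pelvis` (iliac
#'   crest to hip), `thigh`, `shank`, `foot` (ankle to MTP), `toe`.
#' @param waveforms per-joint Fourier coefficients, see
#'   [gait_waveforms_default()].
#' @param knee_offset_deg constant angle offset added to the knee waveform
#'   (EAE-like deficit; default 0).
#' @param cycle_noise_sd_deg SD of the per-cycle constant angle noise in
#'   degrees (default 0).
#' @param tracking_noise_sd_cm SD of per-frame tracking noise in cm
#'   (default 0).
#' @param dropout_rate fraction of frame-landmark observations replaced by
#'   low-likelihood junk coordinates (default 0).
#' @param coefficient_cm_px true camera calibration in cm per pixel
#'   (default 0.01).
#' @param image_width_px,image_height_px synthetic frame size (800 x 600).
#' @param seed integer seed.
#' @return A validated `gait_sim_params` list.
#' @export
gait_sim_params <- function(fps = 250, duration_s = 4, cadence_hz = 2.5,
                            duty_factor = 0.6,
                            lengths = list(pelvis = 0.8, thigh = 1.6,
                                           shank = 1.8, foot = 1.0, toe = 0.5),
                            waveforms = gait_waveforms_default(),
                            knee_offset_deg = 0, cycle_noise_sd_deg = 0,
                            tracking_noise_sd_cm = 0, dropout_rate = 0,
                            coefficient_cm_px = 0.01,
                            image_width_px = 800, image_height_px = 600,
                            seed = 1) {
  stopifnot(fps > 0, duration_s > 0, cadence_hz > 0,
            duty_factor > 0, duty_factor < 1,
            all(unlist(lengths) > 0),
            all(c("pelvis", "thigh", "shank", "foot", "toe") %in% names(lengths)),
            all(c("hip", "knee", "ankle") %in% names(waveforms)),
            cycle_noise_sd_deg >= 0, tracking_noise_sd_cm >= 0,
            dropout_rate >= 0, dropout_rate < 1, coefficient_cm_px > 0)
  structure(list(fps = fps, duration_s = duration_s, cadence_hz = cadence_hz,
                 duty_factor = duty_factor, lengths = lengths,
                 waveforms = waveforms, knee_offset_deg = knee_offset_deg,
                 cycle_noise_sd_deg = cycle_noise_sd_deg,
                 tracking_noise_sd_cm = tracking_noise_sd_cm,
                 dropout_rate = dropout_rate,
                 coefficient_cm_px = coefficient_cm_px,
                 image_width_px = image_width_px,
                 image_height_px = image_height_px, seed = seed),
            class = "gait_sim_params")
}

# Forward kinematics of the sagittal hindlimb chain from interior joint
# angles, with fixed rotation-sign conventions (animal facing +x, y up).
# Direction angles are standard math angles in degrees from the +x axis.
fk_hindlimb <- function(theta_hip, theta_knee, theta_ankle, lengths,
                        ic_x, ic_y, theta_mtp = 150, pelvis_dir_deg = 260) {
  step <- function(x, y, len, psi_deg) {
    list(x = x + len * cos(deg2rad(psi_deg)), y = y + len * sin(deg2rad(psi_deg)))
  }
  hip <- step(ic_x, ic_y, lengths$pelvis, pelvis_dir_deg)
  psi_up <- pelvis_dir_deg - 180                # direction hip -> iliac crest
  psi_thigh <- psi_up - theta_hip
  knee <- step(hip$x, hip$y, lengths$thigh, psi_thigh)
  psi_shank <- (psi_thigh + 180) + theta_knee
  ankle <- step(knee$x, knee$y, lengths$shank, psi_shank)
  psi_foot <- (psi_shank + 180) - theta_ankle
  mtp <- step(ankle$x, ankle$y, lengths$foot, psi_foot)
  psi_toe <- psi_foot + (180 - theta_mtp)
  toe <- step(mtp$x, mtp$y, lengths$toe, psi_toe)
  n <- length(theta_hip)
  x <- cbind(iliac_crest = rep(ic_x, length.out = n), hip = hip$x, knee = knee$x,
             ankle = ankle$x, mtp = mtp$x, toe = toe$x)
  y <- cbind(iliac_crest = rep(ic_y, length.out = n), hip = hip$y, knee = knee$y,
             ankle = ankle$y, mtp = mtp$y, toe = toe$y)
  list(x = x, y = y)
}

#' Generate a synthetic treadmill gait recording with ground truth
#'
#' Joint-angle waveforms (baseline Fourier series plus the knee offset and
#' per-cycle constant noise) drive a forward-kinematic hindlimb chain hung
#' from a quasi-fixed iliac crest (small vertical oscillation). The
#' construction is checked post hoc to satisfy the treadmill constraint —
#' toe horizontal velocity negative through stance, positive through swing —
#' and regenerated with a larger hip excursion if violated (fatal after 10
#' attempts). Pixel coordinates are produced by inverse-applying a known
#' calibration, then per-frame tracking noise and optional low-likelihood
#' dropouts are added.
#'
#' @param params a [gait_sim_params()] list.
#' @return List with `track` (a `pose_track`), `calibration` (the true
#'   [compute_calibration()] object), `marker_px` (the four calibration
#'   markers), `image_height_px`, and `truth`: phase boundaries per complete
#'   cycle (1-based half-open frame intervals), the per-frame true angles
#'   (including injected offset and cycle noise), true cm coordinates before
#'   tracking noise, duty factor, cadence, and the injected knee offset.
#' @export
gen_gait_recording <- function(params = gait_sim_params()) {
  stopifnot(inherits(params, "gait_sim_params"))
  with_seed(params$seed, {
    n <- round(params$duration_s * params$fps)
    tt <- (seq_len(n) - 1L) / params$fps
    phi_total <- tt * params$cadence_hz
    cyc <- floor(phi_total)
    phi <- phi_total - cyc
    u <- warp_phase(phi, params$duty_factor)

    n_cyc <- max(cyc) + 1L
    cyc_noise <- matrix(stats::rnorm(n_cyc * 3L, 0, params$cycle_noise_sd_deg),
                        n_cyc, 3L)
    wf <- params$waveforms
    ic_x <- 4.0
    ic_y <- 5.5 + 0.05 * sin(2 * pi * phi)

    pos <- NULL
    for (attempt in seq_len(10L)) {
      th_hip <- eval_waveform(wf$hip, u) + cyc_noise[cyc + 1L, 1L]
      th_knee <- eval_waveform(wf$knee, u) + params$knee_offset_deg +
        cyc_noise[cyc + 1L, 2L]
      th_ankle <- eval_waveform(wf$ankle, u) + cyc_noise[cyc + 1L, 3L]
      clamp <- function(x) pmin(175, pmax(5, x))
      th_hip <- clamp(th_hip); th_knee <- clamp(th_knee); th_ankle <- clamp(th_ankle)

      cand <- fk_hindlimb(th_hip, th_knee, th_ankle, params$lengths, ic_x, ic_y)
      v <- central_velocity(cand$x[, "toe"], params$fps)
      margin <- 5 * params$cadence_hz / params$fps # keep clear of boundaries
      st_core <- phi > margin & phi < params$duty_factor - margin
      sw_core <- phi > params$duty_factor + margin & phi < 1 - margin
      if (all(v[st_core] < 0) && all(v[sw_core] > 0)) {
        pos <- cand
        break
      }
      wf$hip$a <- wf$hip$a * 1.15 # widen hip excursion and retry
    }
    if (is.null(pos))
      stop("waveform/duty-factor combination cannot satisfy the stance-velocity constraint")

    coef <- params$coefficient_cm_px
    H <- params$image_height_px
    noise_x <- matrix(stats::rnorm(n * 6L, 0, params$tracking_noise_sd_cm), n, 6L)
    noise_y <- matrix(stats::rnorm(n * 6L, 0, params$tracking_noise_sd_cm), n, 6L)
    x_px <- (pos$x + noise_x) / coef
    y_px <- H - (pos$y + noise_y) / coef
    colnames(x_px) <- colnames(y_px) <- KINEMATIC_LANDMARKS
    likelihood <- matrix(1, n, 6L, dimnames = list(NULL, KINEMATIC_LANDMARKS))

    if (params$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * 6L) < params$dropout_rate, n, 6L)
      nd <- sum(drop)
      likelihood[drop] <- stats::runif(nd, 0, 0.5)
      x_px[drop] <- x_px[drop] + stats::runif(nd, -80, 80)
      y_px[drop] <- y_px[drop] + stats::runif(nd, -80, 80)
    }

    # Complete cycles fully inside the recording, as 1-based half-open spans.
    bounds <- list()
    for (c0 in 0:(n_cyc - 1L)) {
      idx <- which(cyc == c0)
      nxt <- which(cyc == c0 + 1L)
      in_stance <- phi[idx] < params$duty_factor
      if (length(nxt) == 0L || !any(in_stance) || all(in_stance)) next
      bounds[[length(bounds) + 1L]] <- data.frame(
        cycle = c0 + 1L,
        stance_start = idx[1L],
        stance_end = idx[which(!in_stance)[1L]],
        swing_start = idx[which(!in_stance)[1L]],
        swing_end = nxt[1L])
    }
    truth <- list(
      phase_bounds = if (length(bounds)) do.call(rbind, bounds) else NULL,
      duty_factor = params$duty_factor, cadence_hz = params$cadence_hz,
      knee_offset_deg = params$knee_offset_deg,
      angles_deg = cbind(hip = th_hip, knee = th_knee, ankle = th_ankle),
      x_cm = pos$x, y_cm = pos$y, waveforms = wf)

    # Calibration markers consistent with the track's pixel scale.
    w_px <- 7 / coef
    h_px <- 4 / coef
    marker_px <- rbind(c(50, 50), c(50 + w_px, 50),
                       c(50 + w_px, 50 + h_px), c(50, 50 + h_px))
    list(track = new_pose_track(x_px, y_px, likelihood, params$fps),
         calibration = compute_calibration(marker_px),
         marker_px = marker_px,
         image_height_px = H,
         truth = truth,
         params = params)
  })
}

#' Write a pose track as a three-header-row CSV
#'
#' Emits the scorer / bodyparts / coords dialect read back by
#' [read_pose_track()], with full coordinate precision.
#'
#' @param track a `pose_track`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gait_recording <- function(track, path) {
  stopifnot(inherits(track, "pose_track"))
  lms <- track$landmarks
  has_lik <- !is.null(track$likelihood)
  per <- if (has_lik) 3L else 2L
  header1 <- c("scorer", rep("synthetic", length(lms) * per))
  header2 <- c("bodyparts", rep(lms, each = per))
  header3 <- c("coords",
               rep(if (has_lik) c("x", "y", "likelihood") else c("x", "y"),
                   times = length(lms)))
  cols <- list()
  for (lm in lms) {
    cols[[paste0(lm, "_x")]] <- sprintf("%.10f", track$x_px[, lm])
    cols[[paste0(lm, "_y")]] <- sprintf("%.10f", track$y_px[, lm])
    if (has_lik)
      cols[[paste0(lm, "_lik")]] <- sprintf("%.6f", track$likelihood[, lm])
  }
  body <- do.call(cbind, c(list(as.character(seq_len(track$frames) - 1L)), cols))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header1, collapse = ","), con)
  writeLines(paste(header2, collapse = ","), con)
  writeLines(paste(header3, collapse = ","), con)
  utils::write.table(body, con, sep = ",", col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Generate a synthetic eYFP fluorescence section with ground truth
#'
#' The frame is split into a grey-matter band (left half), a lesioned
#' white-matter band and a healthy white-matter band (right quarter). GM
#' pixels sit at `gm_mean`, all WM pixels at `gm_mean * wm_healthy_ratio`,
#' and puncta are painted into the lesioned WM band at
#' `puncta_multiple` times the analytic threshold
#' (`wm_healthy_ratio * gm_mean * factor`), so the painted pixels — and only
#' they — are suprathreshold by construction at zero noise. `true_percent`
#' is computed from the painted pixel count.
#'
#' @param width,height image size in pixels (defaults 200 x 200).
#' @param gm_mean grey-matter intensity (default 100, arbitrary units).
#' @param wm_healthy_ratio healthy-WM / GM intensity ratio (default 1.25).
#' @param factor threshold multiplier the analysis will use (default 1.5).
#' @param puncta_multiple painted intensity as a multiple of the analytic
#'   threshold (default 2; must exceed 1).
#' @param target_fraction exact fraction of WM pixels to paint (takes
#'   precedence over `n_puncta`).
#' @param n_puncta,puncta_radius number and radius (px) of disk-shaped
#'   puncta painted when `target_fraction` is `NULL`.
#' @param noise_sd SD of additive Gaussian noise (same units as `gm_mean`).
#' @param seed integer seed.
#' @return List with `image` (an [image_with_masks()]), `true_percent`,
#'   `threshold` (analytic), and the parameters.
#' @export
gen_eyfp_image <- function(width = 200, height = 200, gm_mean = 100,
                           wm_healthy_ratio = 1.25, factor = 1.5,
                           puncta_multiple = 2, target_fraction = NULL,
                           n_puncta = 0, puncta_radius = 3,
                           noise_sd = 0, seed = 1) {
  stopifnot(gm_mean > 0, wm_healthy_ratio > 0, factor > 0, puncta_multiple > 1,
            noise_sd >= 0)
  with_seed(seed, {
    gm_cols <- seq_len(width %/% 2L)
    wm_cols <- seq(width %/% 2L + 1L, width)
    healthy_cols <- seq(width - width %/% 4L + 1L, width)
    lesion_cols <- setdiff(wm_cols, healthy_cols)

    img <- matrix(0, height, width)
    gm <- wm <- healthy <- matrix(FALSE, height, width)
    gm[, gm_cols] <- TRUE
    wm[, wm_cols] <- TRUE
    healthy[, healthy_cols] <- TRUE
    img[gm] <- gm_mean
    img[wm] <- gm_mean * wm_healthy_ratio

    threshold <- wm_healthy_ratio * gm_mean * factor
    lesion_idx <- as.vector(outer(seq_len(height), (lesion_cols - 1L) * height, `+`))

    painted <- integer(0)
    if (!is.null(target_fraction)) {
      stopifnot(target_fraction >= 0, target_fraction <= 1)
      k <- round(target_fraction * sum(wm))
      if (k > length(lesion_idx))
        stop("requested painted fraction exceeds lesioned white-matter capacity")
      painted <- sample(lesion_idx, k)
    } else if (n_puncta > 0) {
      mask <- matrix(FALSE, height, width)
      for (p in seq_len(n_puncta)) {
        cx <- sample(lesion_cols, 1L)
        cy <- sample(seq_len(height), 1L)
        rows <- pmax(1L, cy - puncta_radius):pmin(height, cy + puncta_radius)
        cols <- pmax(1L, cx - puncta_radius):pmin(width, cx + puncta_radius)
        for (co in cols) {
          dy <- rows - cy; dx <- co - cx
          hit <- rows[dy^2 + dx^2 <= puncta_radius^2]
          mask[hit, co] <- TRUE
        }
      }
      mask[, -lesion_cols] <- FALSE
      painted <- which(mask)
      if (length(painted) > sum(wm))
        stop("puncta exceed white-matter capacity")
    }
    img[painted] <- puncta_multiple * threshold
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(height * width, 0, noise_sd), height, width)

    list(image = image_with_masks(img, wm, gm, healthy),
         true_percent = 100 * length(painted) / sum(wm),
         threshold = threshold,
         n_painted_px = length(painted),
         seed = seed)
  })
}

# Rasterize one elliptical annulus into the label masks (by reference-ish:
# returns modified masks). Inner ellipse = axon, ring = myelin.
rasterize_annulus <- function(axon, myelin, cx, cy, a_in, b_in, a_out, b_out,
                              rot_deg, id) {
  h <- nrow(axon); w <- ncol(axon)
  r_max <- max(a_out, b_out)
  rows <- max(1L, floor(cy - r_max)):min(h, ceiling(cy + r_max))
  cols <- max(1L, floor(cx - r_max)):min(w, ceiling(cx + r_max))
  dy <- rows - cy
  dx <- cols - cx
  ca <- cos(deg2rad(rot_deg)); sa <- sin(deg2rad(rot_deg))
  X <- outer(dy * 0, dx) + matrix(dx, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(dy, length(rows), length(cols))
  Xr <- X * ca + Y * sa
  Yr <- -X * sa + Y * ca
  inside_out <- (Xr / a_out)^2 + (Yr / b_out)^2 <= 1
  inside_in <- (Xr / a_in)^2 + (Yr / b_in)^2 <= 1
  ax_local <- axon[rows, cols]
  my_local <- myelin[rows, cols]
  ax_local[inside_in] <- id
  my_local[inside_out & !inside_in] <- id
  axon[rows, cols] <- ax_local
  myelin[rows, cols] <- my_local
  list(axon = axon, myelin = myelin)
}

#' Generate a synthetic TEM axon field with exact ground truth
#'
#' Places non-overlapping elliptical annuli (axon lumen + myelin ring) in a
#' field. Each axon's target g-ratio sets the outer/inner scale
#' (`outer = inner / g`); the exported true g is recomputed from the
#' rasterized pixel counts, so the truth is exact under the area-equivalent
#' definition the analysis uses. A target g of 1 produces an unmyelinated
#' axon (empty ring).
#'
#' @param width,height field size in pixels (defaults 600 x 600).
#' @param n_axons number of axons to place (default 30).
#' @param pixel_size_um pixel edge in micrometres (default 0.02, i.e. 20 nm
#'   at TEM magnification).
#' @param radius_px range of inner semi-major axis in pixels (default
#'   c(12, 22)).
#' @param g_targets per-axon target g-ratios (recycled to `n_axons`); when
#'   `NULL`, drawn from an equal mixture of mature sheaths (around 0.70) and
#'   thin remyelinating sheaths (around 0.88).
#' @param ellipticity range of semi-minor/semi-major ratios (default
#'   c(0.75, 1)).
#' @param seed integer seed.
#' @param max_tries placement attempts per axon before giving up (fewer
#'   axons are placed with a warning).
#' @return List with `axon_mask`, `myelin_mask` (integer label matrices),
#'   `truth` (per-axon data frame: label, pixel counts, exact `g`,
#'   `target_g`), `pixel_size_um`, and `field_area_um2`.
#' @export
gen_axon_field <- function(width = 600, height = 600, n_axons = 30,
                           pixel_size_um = 0.02, radius_px = c(12, 22),
                           g_targets = NULL, ellipticity = c(0.75, 1),
                           seed = 1, max_tries = 400) {
  stopifnot(n_axons >= 1, pixel_size_um > 0, min(radius_px) >= 5)
  with_seed(seed, {
    if (is.null(g_targets)) {
      comp <- sample(c(0, 1), n_axons, replace = TRUE)
      g_targets <- ifelse(comp == 0,
                          stats::rnorm(n_axons, 0.70, 0.03),
                          stats::rnorm(n_axons, 0.88, 0.03))
      g_targets <- pmin(0.98, pmax(0.5, g_targets))
    } else {
      g_targets <- rep_len(g_targets, n_axons)
      stopifnot(all(g_targets > 0), all(g_targets <= 1))
    }
    axon <- matrix(0L, height, width)
    myelin <- matrix(0L, height, width)
    placed <- list()
    truth_rows <- list()
    id <- 0L
    for (i in seq_len(n_axons)) {
      g <- g_targets[i]
      a_in <- stats::runif(1, radius_px[1], radius_px[2])
      ecc <- stats::runif(1, ellipticity[1], ellipticity[2])
      b_in <- a_in * ecc
      a_out <- a_in / g
      b_out <- b_in / g
      r_out <- max(a_out, b_out)
      rot <- stats::runif(1, 0, 180)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- stats::runif(1, r_out + 3, width - r_out - 3)
        cy <- stats::runif(1, r_out + 3, height - r_out - 3)
        clear <- TRUE
        for (p in placed) {
          if ((cx - p$cx)^2 + (cy - p$cy)^2 < (r_out + p$r + 2)^2) {
            clear <- FALSE
            break
          }
        }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) next
      id <- id + 1L
      res <- rasterize_annulus(axon, myelin, cx, cy, a_in, b_in, a_out, b_out,
                               rot, id)
      axon <- res$axon
      myelin <- res$myelin
      placed[[length(placed) + 1L]] <- list(cx = cx, cy = cy, r = r_out)
      truth_rows[[id]] <- data.frame(label = id, target_g = g,
                                     cx = cx, cy = cy)
    }
    if (id < n_axons)
      warning(sprintf("placed %d of %d axons (field too crowded)", id, n_axons))
    truth <- do.call(rbind, truth_rows)
    a_px <- tabulate(axon[axon > 0], nbins = id)
    m_px <- tabulate(myelin[myelin > 0], nbins = id)
    truth$axon_area_px <- a_px[truth$label]
    truth$myelin_area_px <- m_px[truth$label]
    truth$g <- sqrt(truth$axon_area_px / (truth$axon_area_px + truth$myelin_area_px))
    list(axon_mask = axon, myelin_mask = myelin, truth = truth,
         pixel_size_um = pixel_size_um,
         field_area_um2 = width * height * pixel_size_um^2,
         seed = seed)
  })
}

#' Generate a synthetic EAE clinical-score cohort
#'
#' Piecewise ordinal disease trajectories: scores are zero until a per-animal
#' onset day, rise linearly to a per-animal peak at `peak_dpi`, then decline
#' at the group's recovery rate; daily observation noise is added, and the
#' latent trajectory is rounded to the 0.5 grid and clipped to \[0, 5\].
#' A faster post-peak decline in the treated group is the injected treatment
#' effect.
#'
#' @param n_per_group animals per group (default 10).
#' @param groups character vector of group labels.
#' @param recovery_rate_per_week post-peak score decline per week, one value
#'   per group (defaults 0.15 and 0.8).
#' @param onset_dpi integer range of onset days (default c(9, 12)).
#' @param peak_score range of peak scores (default c(2.5, 3.5)).
#' @param peak_dpi day of peak disease (default 16).
#' @param dpi days to emit (default 7:44, when scoring begins through study
#'   end).
#' @param noise_sd SD of daily observation noise on the latent score
#'   (default 0.15).
#' @param seed integer seed.
#' @return Data frame `animal_id`, `group`, `dpi`, `score`, with the
#'   per-animal onset/peak/rate parameters attached as attribute `"truth"`.
#' @export
gen_clinical_cohort <- function(n_per_group = 10,
                                groups = c("EAE_Veh", "EAE_IRX"),
                                recovery_rate_per_week = c(0.15, 0.8),
                                onset_dpi = c(9, 12), peak_score = c(2.5, 3.5),
                                peak_dpi = 16, dpi = 7:44, noise_sd = 0.15,
                                seed = 1) {
  stopifnot(n_per_group >= 1, length(recovery_rate_per_week) == length(groups))
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (gi in seq_along(groups)) {
      for (ai in seq_len(n_per_group)) {
        id <- sprintf("%s_%02d", groups[gi], ai)
        onset <- sample(seq(onset_dpi[1], onset_dpi[2]), 1L)
        peak <- stats::runif(1, peak_score[1], peak_score[2])
        rate <- recovery_rate_per_week[gi]
        latent <- vapply(dpi, function(d) {
          if (d < onset) return(0)
          if (d <= peak_dpi) return(peak * (d - onset) / max(1, peak_dpi - onset))
          max(0, peak - rate / 7 * (d - peak_dpi))
        }, numeric(1))
        obs <- latent + ifelse(dpi >= onset, stats::rnorm(length(dpi), 0, noise_sd), 0)
        score <- pmin(5, pmax(0, round(obs * 2) / 2))
        rows[[id]] <- data.frame(animal_id = id, group = groups[gi],
                                 dpi = dpi, score = score)
        truth[[id]] <- data.frame(animal_id = id, group = groups[gi],
                                  onset = onset, peak = peak, rate = rate)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- do.call(rbind, truth)
    out
  })
}

#' Generate a synthetic qPCR plate with known fold changes
#'
#' Builds a long-format Cq table with technical replicates. Per sample and
#' gene, `Cq = base_cq[gene] + sample_shift - log2(expression) + noise`:
#' sample-wide shifts emulate loading/efficiency differences (cancelled by
#' reference normalization), reference genes have expression 1 plus a
#' stability jitter, and target genes in non-control groups have expression
#' equal to their true fold.
#'
#' @param true_folds named numeric vector: per-target true fold change in
#'   the treated group(s) relative to control.
#' @param references reference gene names (>= 2).
#' @param groups group labels; the first entry of `control_group` must be
#'   among them.
#' @param control_group label of the calibrator group.
#' @param n_per_group samples per group (default 6).
#' @param n_replicates technical replicates per well (default 3).
#' @param base_cq_range range of per-gene base Cq (default c(18, 26)).
#' @param sample_shift_sd SD of the per-sample global Cq shift (default 0.3).
#' @param ref_stability_sd SD of reference-gene Cq jitter (default 0.05).
#' @param replicate_sd SD of per-replicate noise in cycles (default 0.05).
#' @param seed integer seed.
#' @return A [cq_table()] data frame with attributes `"true_folds"`,
#'   `"references"`, `"control_group"`.
#' @export
gen_qpcr_plate <- function(true_folds = c(target_up = 2, target_down = 0.5,
                                          target_null = 1),
                           references = c("ref1", "ref2"),
                           groups = c("control", "treated"),
                           control_group = "control",
                           n_per_group = 6, n_replicates = 3,
                           base_cq_range = c(18, 26), sample_shift_sd = 0.3,
                           ref_stability_sd = 0.05, replicate_sd = 0.05,
                           seed = 1) {
  stopifnot(length(true_folds) >= 1, !is.null(names(true_folds)),
            length(references) >= 2, control_group %in% groups,
            all(true_folds > 0))
  with_seed(seed, {
    genes <- c(names(true_folds), references)
    base_cq <- stats::setNames(stats::runif(length(genes), base_cq_range[1],
                                            base_cq_range[2]), genes)
    rows <- list()
    for (g in groups) {
      for (s in seq_len(n_per_group)) {
        sid <- sprintf("%s_%02d", g, s)
        shift <- stats::rnorm(1, 0, sample_shift_sd)
        for (gene in genes) {
          expr <- if (gene %in% references) {
            2^(stats::rnorm(1, 0, ref_stability_sd))
          } else if (g == control_group) 1 else unname(true_folds[gene])
          well_cq <- base_cq[gene] + shift - log2(expr)
          for (r in seq_len(n_replicates)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sid, group = g, gene = gene, replicate = r,
              cq = well_cq + stats::rnorm(1, 0, replicate_sd))
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "true_folds") <- true_folds
    attr(out, "references") <- references
    attr(out, "control_group") <- control_group
    cq_table(out)
  })
}
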