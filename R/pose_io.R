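# Reading pose-estimation tracks and converting pixels to treadmill-frame cm.

#' Canonical hindlimb landmark names, proximal to distal
#'
#' The six sagittal-plane landmarks tracked on the right hindlimb: iliac
#' crest, hip, knee, ankle, metatarsophalangeal joint (MTP), and toe.
#'
#' @format Character vector of length 6.
#' @export
KINEMATIC_LANDMARKS <- c("iliac_crest", "hip", "knee", "ankle", "mtp", "toe")

normalize_bodypart <- function(x) {
  x <- gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
  gsub("^_|_$", "", x)
}

new_pose_track <- function(x_px, y_px, likelihood, fps) {
  stopifnot(is.matrix(x_px), is.matrix(y_px),
            identical(dim(x_px), dim(y_px)),
            identical(colnames(x_px), KINEMATIC_LANDMARKS))
  if (!is.null(likelihood)) {
    stopifnot(identical(dim(likelihood), dim(x_px)))
    if (any(likelihood < 0 | likelihood > 1, na.rm = TRUE))
      stop("likelihood values must lie in [0, 1]")
  }
  if (!is_scalar_num(fps) || fps <= 0) stop("fps must be a positive number")
  structure(list(frames = nrow(x_px), fps = fps,
                 landmarks = KINEMATIC_LANDMARKS,
                 x_px = x_px, y_px = y_px, likelihood = likelihood),
            class = "pose_track")
}

#' Read a pose-estimation CSV track
#'
#' Parses the three-header-row CSV dialect emitted by markerless
#' pose-estimation software (scorer / bodyparts / coords rows, then one row
#' per video frame with x, y and optionally likelihood columns per landmark).
#' Bodypart names are matched case-insensitively onto the six canonical
#' landmark names in [KINEMATIC_LANDMARKS].
#'
#' @param path path to the CSV file.
#' @param fps recording frame rate in frames per second (default 250).
#' @return A `pose_track` object: per-frame pixel coordinates (`x_px`,
#'   `y_px`, frames x 6 matrices) and, when present in the file, a
#'   `likelihood` matrix of per-frame tracking confidences in \[0, 1\].
#' @export
read_pose_track <- function(path, fps = 250) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("pose file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "character",
                    check.names = FALSE),
    error = function(e) stop("empty or unreadable pose file: ", path))
  if (nrow(raw) < 4L)
    stop("pose file has no data rows (need 3 header rows + data): ", path)

  bodyparts <- normalize_bodypart(as.character(raw[2L, -1L]))
  coords <- tolower(trimws(as.character(raw[3L, -1L])))
  data <- raw[-(1:3), -1L, drop = FALSE]

  read_col <- function(j) {
    cell <- data[[j]]
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric cell '%s' at data row %d of %s",
                   cell[bad[1L]], bad[1L], path))
    v
  }

  n <- nrow(data)
  x_px <- y_px <- lik <- matrix(NA_real_, n, length(KINEMATIC_LANDMARKS),
                                dimnames = list(NULL, KINEMATIC_LANDMARKS))
  have_lik <- TRUE
  for (lm in KINEMATIC_LANDMARKS) {
    jx <- which(bodyparts == lm & coords == "x")
    jy <- which(bodyparts == lm & coords == "y")
    if (length(jx) != 1L || length(jy) != 1L)
      stop(sprintf("landmark '%s' not found in %s", lm, path))
    x_px[, lm] <- read_col(jx)
    y_px[, lm] <- read_col(jy)
    jl <- which(bodyparts == lm & coords == "likelihood")
    if (length(jl) == 1L) lik[, lm] <- read_col(jl) else have_lik <- FALSE
  }
  new_pose_track(x_px, y_px, if (have_lik) lik else NULL, fps)
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames @ %g fps, landmarks: %s\n",
              x$frames, x$fps, paste(x$landmarks, collapse = ", ")))
  invisible(x)
}

#' Compute a pixel-to-centimetre calibration from four rectangle markers
#'
#' The calibration scene contains four markers at the corners of an
#' axis-aligned rectangle of known physical size (4 cm high by 7 cm wide in
#' the treadmill setup). Corners are matched by lexicographic sorting of the
#' marker coordinates; rotated rectangles are rejected. The horizontal and
#' vertical cm/px scales are averaged into a single conversion coefficient;
#' if they disagree by more than `anisotropy_tol` (relative), calibration
#' fails rather than silently averaging incompatible scales.
#'
#' @param marker_px 4 x 2 matrix (or data.frame) of marker pixel coordinates.
#' @param rect_width_cm,rect_height_cm true rectangle dimensions in cm.
#' @param anisotropy_tol maximum allowed `|scale_x - scale_y| / mean(scale)`.
#' @return A `calibration` object with elements `coefficient` (cm per pixel),
#'   `anisotropy`, `scale_x`, `scale_y`, and the rectangle dimensions.
#' @export
compute_calibration <- function(marker_px, rect_width_cm = 7,
                                rect_height_cm = 4, anisotropy_tol = 0.05) {
  m <- as.matrix(marker_px)
  if (!is.numeric(m) || nrow(m) != 4L || ncol(m) != 2L || any(!is.finite(m)))
    stop("marker_px must be four finite (x, y) pixel points")
  if (!is_scalar_num(rect_width_cm) || rect_width_cm <= 0 ||
      !is_scalar_num(rect_height_cm) || rect_height_cm <= 0)
    stop("rectangle dimensions must be positive")

  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  left <- m[1:2, , drop = FALSE]
  right <- m[3:4, , drop = FALSE]
  width_px <- mean(right[, 1L]) - mean(left[, 1L])
  h_left <- abs(diff(left[, 2L]))
  h_right <- abs(diff(right[, 2L]))
  height_px <- mean(c(h_left, h_right))
  if (width_px <= 0 || height_px <= 0)
    stop("degenerate calibration rectangle (zero width or height)")

  span <- max(width_px, height_px)
  if (abs(diff(left[, 1L])) > 0.02 * span ||
      abs(diff(right[, 1L])) > 0.02 * span ||
      abs(h_left - h_right) > 0.02 * span)
    stop("calibration markers do not form an axis-aligned rectangle")

  scale_x <- rect_width_cm / width_px
  scale_y <- rect_height_cm / height_px
  coefficient <- mean(c(scale_x, scale_y))
  anisotropy <- abs(scale_x - scale_y) / coefficient
  if (anisotropy > anisotropy_tol)
    stop(sprintf(paste0("calibration anisotropy %.3f exceeds tolerance %.3f; ",
                        "check marker placement"), anisotropy, anisotropy_tol))
  structure(list(coefficient = coefficient, anisotropy = anisotropy,
                 scale_x = scale_x, scale_y = scale_y,
                 rect_width_cm = rect_width_cm, rect_height_cm = rect_height_cm),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.6f cm/px (anisotropy %.4f)\n",
              x$coefficient, x$anisotropy))
  invisible(x)
}

#' Read or write a calibration YAML file
#'
#' The calibration file stores the four marker pixel coordinates, the true
#' rectangle dimensions and the frame height in pixels (needed for the y-axis
#' flip when calibrating tracks).
#'
#' @param path YAML file path.
#' @return `read_calibration_file()` returns a list with elements
#'   `calibration` (a [compute_calibration()] result) and `image_height_px`.
#' @export
read_calibration_file <- function(path) {
  y <- yaml::read_yaml(path)
  m <- do.call(rbind, lapply(y$marker_px, as.numeric))
  list(calibration = compute_calibration(
         m, rect_width_cm = y$rect_width_cm, rect_height_cm = y$rect_height_cm,
         anisotropy_tol = if (is.null(y$anisotropy_tol)) 0.05 else y$anisotropy_tol),
       image_height_px = as.numeric(y$image_height_px))
}

#' @rdname read_calibration_file
#' @param marker_px 4 x 2 matrix of marker pixel coordinates.
#' @param rect_width_cm,rect_height_cm true rectangle dimensions in cm.
#' @param image_height_px frame height in pixels.
#' @export
write_calibration_file <- function(path, marker_px, rect_width_cm = 7,
                                   rect_height_cm = 4, image_height_px = 600) {
  m <- as.matrix(marker_px)
  yaml::write_yaml(list(
    marker_px = lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])),
    rect_width_cm = rect_width_cm, rect_height_cm = rect_height_cm,
    image_height_px = image_height_px), path)
  invisible(path)
}

#' Convert a pixel track to treadmill-frame centimetre coordinates
#'
#' Frames where a landmark's likelihood falls below `likelihood_min` are
#' treated as tracking dropouts: their coordinates are replaced by linear
#' interpolation between the nearest valid neighbours (edge gaps extend the
#' nearest valid value). The y axis is flipped so that y increases upward
#' (`y_cm = (image_height_px - y_px) * coefficient`), putting the origin at
#' the lower-left of the image.
#'
#' @param track a `pose_track` from [read_pose_track()].
#' @param cal a `calibration` from [compute_calibration()].
#' @param likelihood_min confidence gate in \[0, 1); frames below it are
#'   interpolated. Default 0.9.
#' @param image_height_px frame height in pixels, for the y flip.
#' @return A `calibrated_track` with `x_cm` and `y_cm` matrices (frames x 6),
#'   all values finite.
#' @export
calibrate_track <- function(track, cal, likelihood_min = 0.9, image_height_px) {
  stopifnot(inherits(track, "pose_track"), inherits(cal, "calibration"))
  if (!is_scalar_num(likelihood_min) || likelihood_min < 0 || likelihood_min >= 1)
    stop("likelihood_min must lie in [0, 1)")
  if (!is_scalar_num(image_height_px) || image_height_px <= 0)
    stop("image_height_px must be positive")

  n <- track$frames
  x_cm <- y_cm <- matrix(NA_real_, n, length(track$landmarks),
                         dimnames = list(NULL, track$landmarks))
  for (lm in track$landmarks) {
    valid <- is.finite(track$x_px[, lm]) & is.finite(track$y_px[, lm])
    if (!is.null(track$likelihood))
      valid <- valid & track$likelihood[, lm] >= likelihood_min
    if (mean(valid) < 0.5)
      stop(sprintf(
        "tracking quality insufficient: landmark '%s' valid in %.0f%% of frames",
        lm, 100 * mean(valid)))
    xf <- fill_gaps(track$x_px[, lm], valid)
    yf <- fill_gaps(track$y_px[, lm], valid)
    x_cm[, lm] <- xf * cal$coefficient
    y_cm[, lm] <- (image_height_px - yf) * cal$coefficient
  }
  structure(list(frames = n, fps = track$fps, landmarks = track$landmarks,
                 x_cm = x_cm, y_cm = y_cm),
            class = "calibrated_track")
}

#' @export
print.calibrated_track <- function(x, ...) {
  cat(sprintf("<calibrated_track> %d frames @ %g fps (cm, y-up)\n",
              x$frames, x$fps))
  invisible(x)
}
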