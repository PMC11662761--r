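# Quantification of axonal transection (punctate eYFP fluorescence),
# white-matter loss (EC/NR staining), and remyelination (g-ratios).

#' Bundle a greyscale image with its region masks
#'
#' @param intensity 2-D numeric matrix of fluorescence intensities (arbitrary
#'   linear units).
#' @param wm_mask,gm_mask logical matrices marking total white matter and
#'   grey matter; must be disjoint and non-empty.
#' @param healthy_wm_mask logical matrix marking visually healthy white
#'   matter; must be a subset of `wm_mask`. Optional for operations that do
#'   not need it.
#' @param pixel_size_um physical pixel size in micrometres (optional).
#' @return An `image_with_masks` object.
#' @export
image_with_masks <- function(intensity, wm_mask, gm_mask,
                             healthy_wm_mask = NULL, pixel_size_um = NULL) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  as_mask <- function(m, name) {
    if (is.numeric(m)) m <- m > 0.5
    if (!is.logical(m) || !identical(dim(m), dim(intensity)))
      stop(name, " must be a logical mask with the same shape as the image")
    m
  }
  wm_mask <- as_mask(wm_mask, "wm_mask")
  gm_mask <- as_mask(gm_mask, "gm_mask")
  if (!any(wm_mask)) stop("wm_mask is empty")
  if (!any(gm_mask)) stop("gm_mask is empty")
  if (any(wm_mask & gm_mask)) stop("wm_mask and gm_mask overlap")
  if (!is.null(healthy_wm_mask)) {
    healthy_wm_mask <- as_mask(healthy_wm_mask, "healthy_wm_mask")
    if (!any(healthy_wm_mask)) stop("healthy_wm_mask is empty")
    if (any(healthy_wm_mask & !wm_mask))
      stop("healthy_wm_mask must be a subset of wm_mask")
  }
  structure(list(intensity = intensity, wm_mask = wm_mask, gm_mask = gm_mask,
                 healthy_wm_mask = healthy_wm_mask,
                 pixel_size_um = pixel_size_um),
            class = "image_with_masks")
}

#' Cohort standardized ratio of healthy white- to grey-matter fluorescence
#'
#' For each image the mean pixel intensity over the healthy-appearing white
#' matter is divided by the mean over grey matter; the per-image ratios are
#' averaged across the cohort. Grey-matter fluorescence is unaffected by
#' disease or treatment, so this ratio anchors per-image thresholds against
#' stochastic section-to-section variation in overall brightness.
#'
#' @param images list of [image_with_masks()] objects, each with a
#'   `healthy_wm_mask`.
#' @return Dimensionless standardized ratio (scalar).
#' @export
eyfp_standardized_ratio <- function(images) {
  if (inherits(images, "image_with_masks")) images <- list(images)
  if (length(images) == 0L) stop("need at least one image")
  ratios <- vapply(seq_along(images), function(i) {
    im <- images[[i]]
    stopifnot(inherits(im, "image_with_masks"))
    if (is.null(im$healthy_wm_mask))
      stop("image ", i, " has no healthy_wm_mask")
    gm <- mean(im$intensity[im$gm_mask])
    if (gm == 0) stop("image ", i, " has zero grey-matter mean intensity")
    mean(im$intensity[im$healthy_wm_mask]) / gm
  }, numeric(1))
  mean(ratios)
}

#' Percent-area axonal transection from suprathreshold eYFP fluorescence
#'
#' The per-image threshold is the standardized ratio times the image's own
#' grey-matter mean intensity times `factor` (1.5 by default). The percent
#' area of white-matter pixels with strictly suprathreshold fluorescence over
#' the total white-matter area measures punctate eYFP accumulation, i.e.
#' axonal transection. Because the threshold scales with the grey-matter
#' mean, the result is invariant to global rescaling of image intensities.
#'
#' @param image an [image_with_masks()].
#' @param ratio cohort standardized ratio from [eyfp_standardized_ratio()].
#' @param factor threshold multiplier (default 1.5).
#' @return One-row data frame: `gm_mean`, `threshold`, `percent_transection`.
#' @export
eyfp_percent_transection <- function(image, ratio, factor = 1.5) {
  stopifnot(inherits(image, "image_with_masks"))
  if (!is_scalar_num(ratio) || ratio <= 0) stop("ratio must be > 0")
  if (!is_scalar_num(factor) || factor <= 0) stop("factor must be > 0")
  if (!any(image$wm_mask)) stop("wm_mask is empty")
  gm_mean <- mean(image$intensity[image$gm_mask])
  threshold <- ratio * gm_mean * factor
  wm <- image$intensity[image$wm_mask]
  data.frame(gm_mean = gm_mean, threshold = threshold,
             percent_transection = 100 * mean(wm > threshold))
}

#' Percent white-matter loss from EC/NR staining
#'
#' Eriochrome Cyanine stains intact myelin blue; Neutral Red counterstain
#' exposes demyelinated regions. A white-matter pixel is NR-positive when its
#' red/blue channel ratio exceeds `red_blue_ratio_min`; the NR-positive
#' fraction of the white-matter mask is the percent white-matter loss.
#'
#' @param rgb numeric array `h x w x 3` with channels red, green, blue.
#' @param wm_mask logical `h x w` white-matter mask (non-empty).
#' @param red_blue_ratio_min NR positivity cutoff on red/(blue + 1e-6)
#'   (default 1.2).
#' @return Percent of white-matter area that is NR-positive, in \[0, 100\].
#' @export
nr_percent_wm_loss <- function(rgb, wm_mask, red_blue_ratio_min = 1.2) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("rgb must be a three-channel (h x w x 3) image")
  if (is.numeric(wm_mask)) wm_mask <- wm_mask > 0.5
  if (!identical(dim(wm_mask), dim(rgb)[1:2]))
    stop("wm_mask shape does not match the image")
  if (!any(wm_mask)) stop("wm_mask is empty")
  r <- rgb[, , 1L][wm_mask]
  b <- rgb[, , 3L][wm_mask]
  100 * mean(r / (b + 1e-6) > red_blue_ratio_min)
}

#' Per-axon areas and area-equivalent g-ratios from segmentation masks
#'
#' Consumes the axon and myelin label masks produced by an external
#' segmentation tool (same integer id labels the axon lumen and its myelin
#' sheath). Areas are pixel counts times `pixel_size_um^2` and the g-ratio is
#' the area-equivalent form `g = sqrt(A_axon / (A_axon + A_myelin))`, robust
#' to non-circular fiber profiles. Objects touching the image border (area
#' underestimated) or with axon area below `min_axon_area_px` (segmentation
#' specks) are excluded. Myelin labels without a matching axon are skipped
#' with a warning.
#'
#' @param axon_mask,myelin_mask integer label matrices of identical shape;
#'   0 = background.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param min_axon_area_px minimum axon area in pixels (default 10).
#' @param g_cutoff g-ratio above which a myelinated axon is flagged
#'   remyelinating (default 0.8, strict inequality).
#' @return Data frame with one row per retained axon: `label`,
#'   `axon_area_um2`, `myelin_area_um2`, `g`, `myelinated`, `remyelinating`.
#' @export
gratio_records <- function(axon_mask, myelin_mask, pixel_size_um = 1,
                           min_axon_area_px = 10, g_cutoff = 0.8) {
  if (!identical(dim(axon_mask), dim(myelin_mask)))
    stop("axon and myelin masks have different shapes")
  if (!is_scalar_num(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  axon_mask <- round(axon_mask)
  myelin_mask <- round(myelin_mask)

  axon_ids <- sort(unique(axon_mask[axon_mask > 0]))
  myelin_ids <- sort(unique(myelin_mask[myelin_mask > 0]))
  orphans <- setdiff(myelin_ids, axon_ids)
  if (length(orphans) > 0L)
    warning("myelin labels without a matching axon skipped: ",
            paste(orphans, collapse = ", "))
  if (length(axon_ids) == 0L)
    return(data.frame(label = integer(), axon_area_um2 = numeric(),
                      myelin_area_um2 = numeric(), g = numeric(),
                      myelinated = logical(), remyelinating = logical()))

  nr <- nrow(axon_mask); nc <- ncol(axon_mask)
  border_ids <- unique(c(
    axon_mask[c(1L, nr), ], axon_mask[, c(1L, nc)],
    myelin_mask[c(1L, nr), ], myelin_mask[, c(1L, nc)]))
  border_ids <- border_ids[border_ids > 0]

  max_id <- max(axon_ids, myelin_ids)
  a_px <- tabulate(axon_mask[axon_mask > 0], nbins = max_id)
  m_px <- tabulate(myelin_mask[myelin_mask > 0], nbins = max_id)

  keep <- setdiff(axon_ids, border_ids)
  keep <- keep[a_px[keep] >= min_axon_area_px]
  if (length(keep) == 0L)
    return(data.frame(label = integer(), axon_area_um2 = numeric(),
                      myelin_area_um2 = numeric(), g = numeric(),
                      myelinated = logical(), remyelinating = logical()))

  aa <- a_px[keep]; mm <- m_px[keep]
  g <- sqrt(aa / (aa + mm))
  myelinated <- mm > 0
  data.frame(label = keep,
             axon_area_um2 = aa * pixel_size_um^2,
             myelin_area_um2 = mm * pixel_size_um^2,
             g = g,
             myelinated = myelinated,
             remyelinating = myelinated & g > g_cutoff)
}

#' Summarise remyelination over a field of axons
#'
#' Myelinated axons with g-ratio strictly above `g_cutoff` (0.8 by default,
#' following the thin-sheath criterion for remyelinating axons in EAE) are
#' counted as remyelinating. The density is reported per unit field area and
#' the percentage relative either to all retained axons (default) or to
#' myelinated axons only.
#'
#' @param records data frame from [gratio_records()].
#' @param field_area_um2 analysed field area in square micrometres.
#' @param g_cutoff classification cutoff in (0, 1), strict (default 0.8).
#' @param percent_denominator `"all"` (default) or `"myelinated"`.
#' @return One-row data frame: `n_axons`, `n_myelinated`, `n_remyelinating`,
#'   `density_remyelinating` (axons/um^2), `percent_remyelinating`.
#' @export
remyelination_summary <- function(records, field_area_um2,
                                  g_cutoff = 0.8,
                                  percent_denominator = c("all", "myelinated")) {
  percent_denominator <- match.arg(percent_denominator)
  if (!is_scalar_num(field_area_um2) || field_area_um2 <= 0)
    stop("field_area_um2 must be > 0")
  if (!is_scalar_num(g_cutoff) || g_cutoff <= 0 || g_cutoff >= 1)
    stop("g_cutoff must lie strictly between 0 and 1")
  if (nrow(records) == 0L) {
    warning("no axon records; returning zero summary")
    return(data.frame(n_axons = 0L, n_myelinated = 0L, n_remyelinating = 0L,
                      density_remyelinating = 0, percent_remyelinating = 0))
  }
  remy <- records$myelinated & records$g > g_cutoff
  n_axons <- nrow(records)
  n_myelinated <- sum(records$myelinated)
  n_remy <- sum(remy)
  denom <- if (percent_denominator == "all") n_axons else n_myelinated
  data.frame(n_axons = n_axons, n_myelinated = n_myelinated,
             n_remyelinating = n_remy,
             density_remyelinating = n_remy / field_area_um2,
             percent_remyelinating = if (denom > 0) 100 * n_remy / denom else 0)
}
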