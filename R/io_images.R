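# Image file round-trips for the pipeline: greyscale intensity (float TIFF,
# values scaled into [0, 1] — the eYFP and NR analyses are invariant to
# global intensity scale), boolean masks (PNG), and integer label masks
# (16-bit TIFF, ids round-trip exactly for ids < 65536).

#' Read and write greyscale intensity images
#'
#' @param path TIFF or PNG file path.
#' @return `read_intensity_image()` returns a numeric matrix (first channel
#'   of multi-channel files).
#' @export
read_intensity_image <- function(path) {
  img <- read_any_image(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

read_any_image <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    stop("unsupported image format: ", path)
  }
}

#' @rdname read_intensity_image
#' @param x numeric matrix of intensities (any non-negative scale; written
#'   rescaled into \[0, 1\]).
#' @export
write_intensity_image <- function(x, path) {
  stopifnot(is.matrix(x))
  x <- x / max(x, 1e-12)
  x[x < 0] <- 0
  x[x > 1] <- 1
  tiff::writeTIFF(x, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read and write boolean region masks as PNG
#'
#' @param path PNG file path.
#' @return `read_mask_image()` returns a logical matrix.
#' @export
read_mask_image <- function(path) {
  read_intensity_image(path) > 0.5
}

#' @rdname read_mask_image
#' @param mask logical matrix.
#' @export
write_mask_image <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read and write integer label masks as 16-bit TIFF
#'
#' Labels are stored as `id / 65535`; ids below 65536 round-trip exactly.
#'
#' @param path TIFF file path.
#' @return `read_label_image()` returns an integer matrix.
#' @export
read_label_image <- function(path) {
  img <- read_intensity_image(path)
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' @rdname read_label_image
#' @param labels integer matrix of object ids (0 = background, max 65535).
#' @export
write_label_image <- function(labels, path) {
  stopifnot(max(labels) <= 65535)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read and write RGB images as PNG
#'
#' @param path PNG file path.
#' @return `read_rgb_image()` returns an `h x w x 3` array in \[0, 1\].
#' @export
read_rgb_image <- function(path) {
  img <- read_any_image(path)
  if (length(dim(img)) != 3L || dim(img)[3L] < 3L)
    stop("not a three-channel image: ", path)
  img[, , 1:3]
}

#' @rdname read_rgb_image
#' @param rgb `h x w x 3` numeric array in \[0, 1\].
#' @export
write_rgb_image <- function(rgb, path) {
  rgb[rgb < 0] <- 0
  rgb[rgb > 1] <- 1
  png::writePNG(rgb, path)
  invisible(path)
}
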