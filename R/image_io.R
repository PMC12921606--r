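#' Calibrated single-channel image
#'
#' Container for one 2D grayscale fluorescence image together with its
#' spatial calibration. Intensities are stored as non-negative numerics on
#' the original integer scale of the source file (0..255 for 8-bit,
#' 0..65535 for 16-bit).
#'
#' @param pixels Numeric matrix of intensities, at least 2 x 2, all values
#'   finite and >= 0. Rows are image rows (y), columns are image columns (x).
#' @param pixel_size_um Physical edge length of one pixel in micrometers
#'   (> 0).
#' @param timepoint_label Free-text label of the timepoint, e.g. `"START"`
#'   or `"24h"`.
#' @param bit_depth Sample depth of the source data, 8 or 16. If `NULL`,
#'   inferred from the maximum intensity.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, timepoint_label = "",
                             bit_depth = NULL) {
  pixels <- as.matrix(pixels)
  # plain double matrix: drop any decoder metadata so that value identity
  # is bit-exact across a save/load round trip
  pixels <- matrix(as.numeric(pixels), nrow(pixels), ncol(pixels))
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must have at least 2 rows and 2 columns")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("all intensities must be finite and >= 0")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (is.null(bit_depth)) bit_depth <- if (max(pixels) > 255) 16L else 8L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         timepoint_label = as.character(timepoint_label),
         bit_depth = bit_depth),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf(
    "calibrated_image '%s': %d x %d px, %.4g um/px, %d-bit, range [%g, %g]\n",
    x$timepoint_label, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
    x$bit_depth, min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Reduce a decoded raster to one informative channel. An image with a
# channel dimension is accepted only if exactly one channel contains any
# signal; otherwise it is rejected as not single-channel.
.collapse_channels <- function(arr, path) {
  if (length(dim(arr)) == 2L) return(arr)
  if (length(dim(arr)) == 3L) {
    nz <- apply(arr, 3, function(ch) any(ch != 0))
    if (sum(nz) == 1L) return(arr[, , which(nz)])
    stop("'", path, "' is not single-channel (",
         sum(nz), " channels carry signal)")
  }
  stop("'", path, "' has unsupported dimensionality")
}

.png_header <- function(path) {
  hdr <- readBin(path, "raw", 26L)
  list(bit_depth = as.integer(hdr[25]), color_type = as.integer(hdr[26]))
}

#' Load a calibrated grayscale image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG file, preserving intensities
#' bit-exactly. A multi-channel file is accepted only when exactly one
#' channel carries signal (the others are identically zero).
#'
#' @param path Path to a `.tif`, `.tiff` or `.png` file.
#' @param pixel_size_um Micrometers per pixel edge.
#' @param timepoint_label Label for the timepoint; defaults to the file stem.
#' @return A [calibrated_image()].
#' @export
load_image <- function(path, pixel_size_um, timepoint_label = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  ext <- tolower(tools::file_ext(path))
  if (is.null(timepoint_label))
    timepoint_label <- tools::file_path_sans_ext(basename(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
    px <- .collapse_channels(unclass(raw), path)
    # multi-channel reads come back scaled to [0, 1] even with as.is
    if (!isTRUE(all.equal(px, round(px))))
      px <- round(px * (2^bits - 1))
  } else if (ext == "png") {
    hdr <- .png_header(path)
    bits <- hdr$bit_depth
    if (!bits %in% c(8L, 16L))
      stop("'", path, "': only 8- and 16-bit PNG are supported")
    raw <- png::readPNG(path)
    px <- .collapse_channels(raw, path)
    px <- round(px * (2^bits - 1))
  } else {
    stop("unsupported image format '", ext, "' (use TIFF or PNG)")
  }
  if (length(px) == 0L) stop("'", path, "' decodes to a zero-sized image")
  calibrated_image(px, pixel_size_um, timepoint_label, bit_depth = bits)
}

#' Time-series dataset of one spheroid
#'
#' Bundles the START image (taken immediately after embedding in the
#' extracellular matrix) with the images of later timepoints. All images
#' must share the pixel calibration; shapes may differ, as every image is
#' processed independently.
#'
#' @param start A [calibrated_image()] for the START timepoint.
#' @param followups List of [calibrated_image()] objects (possibly empty).
#' @return An object of class `spheroid_dataset` with elements `start`,
#'   `followups` and `pixel_size_um`.
#' @export
spheroid_dataset <- function(start, followups = list()) {
  stopifnot(inherits(start, "calibrated_image"))
  if (!is.list(followups) ||
      !all(vapply(followups, inherits, logical(1), "calibrated_image")))
    stop("followups must be a list of calibrated_image objects")
  ps <- vapply(followups, `[[`, numeric(1), "pixel_size_um")
  if (length(ps) && any(ps != start$pixel_size_um))
    stop("all images must share the same pixel_size_um")
  structure(list(start = start, followups = followups,
                 pixel_size_um = start$pixel_size_um),
            class = "spheroid_dataset")
}

#' @export
print.spheroid_dataset <- function(x, ...) {
  cat(sprintf("spheroid_dataset: START '%s' + %d followup(s), %.4g um/px\n",
              x$start$timepoint_label, length(x$followups), x$pixel_size_um))
  invisible(x)
}

# All images of a dataset as one list, START first.
dataset_images <- function(dataset) {
  c(list(dataset$start), dataset$followups)
}

#' Load a START + followups dataset from files
#'
#' @param start_path Path of the START image.
#' @param followup_paths Character vector of later-timepoint image paths,
#'   in chronological order (may be empty).
#' @param pixel_size_um Micrometers per pixel, shared by all images.
#' @param labels Optional character vector of timepoint labels, one per
#'   image (START first); defaults to the file stems.
#' @return A [spheroid_dataset()].
#' @export
load_dataset <- function(start_path, followup_paths = character(),
                         pixel_size_um, labels = NULL) {
  paths <- c(start_path, followup_paths)
  if (any(normalizePath(followup_paths, mustWork = FALSE) ==
          normalizePath(start_path, mustWork = FALSE)))
    stop("START image duplicated among the followups")
  if (!is.null(labels) && length(labels) != length(paths))
    stop("labels must have one entry per image (START first)")
  imgs <- lapply(seq_along(paths), function(i)
    load_image(paths[i], pixel_size_um,
               timepoint_label = if (is.null(labels)) NULL else labels[i]))
  spheroid_dataset(imgs[[1L]], imgs[-1L])
}

# Mask pixels having at least one 4-neighbor outside the mask; pixels
# beyond the image border count as background, so a mask touching the
# border is boundary there.
mask_boundary <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- grid
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up    <- pad[1:nr, 2:(nc + 1L)]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left  <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  inner & !(up & down & left & right)
}

#' Write an overlay image of mask boundary and detected objects
#'
#' Renders the grayscale image (scaled by its bit depth) to RGB, paints the
#' mask boundary red and the pixels of the detected objects green, and
#' writes the result as PNG or TIFF depending on the file extension. The
#' output is deterministic for fixed inputs and none of the inputs are
#' modified.
#'
#' @param image A [calibrated_image()].
#' @param mask A [spheroid_mask()] of the same shape.
#' @param objects List of detected objects (as returned by
#'   [detect_objects()]); may be empty.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, the path.
#' @export
write_overlay <- function(image, mask, objects = list(), path) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(mask, "spheroid_mask"))
  if (!all(dim(image$pixels) == dim(mask$grid)))
    stop("image and mask shapes differ")
  base <- pmin(image$pixels / (2^image$bit_depth - 1), 1)
  arr <- array(base, dim = c(dim(base), 3L))
  bd <- mask_boundary(mask$grid)
  if (any(bd)) {
    arr[, , 1][bd] <- 1; arr[, , 2][bd] <- 0; arr[, , 3][bd] <- 0
  }
  for (ob in objects) {
    idx <- ob$pixels  # n x 2 matrix of (row, col)
    arr[, , 1][idx] <- 0; arr[, , 2][idx] <- 1; arr[, , 3][idx] <- 0
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(arr, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(arr, path)
  else stop("unsupported overlay format '", ext, "'")
  invisible(path)
}

#' Write a binary mask as an 8-bit image (0/255)
#'
#' @param mask A [spheroid_mask()].
#' @param path Output path (`.png`, `.tif` or `.tiff`).
#' @return Invisibly, the path.
#' @export
write_mask_image <- function(mask, path) {
  stopifnot(inherits(mask, "spheroid_mask"))
  m <- matrix(as.numeric(mask$grid), nrow(mask$grid))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(m, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(m, path)
  else stop("unsupported mask format '", ext, "'")
  invisible(path)
}

#' Write a calibrated image to a 16- or 8-bit grayscale TIFF
#'
#' Inverse of [load_image()]: intensities are preserved bit-exactly.
#'
#' @param image A [calibrated_image()].
#' @param path Output `.tif`/`.tiff` path.
#' @return Invisibly, the path.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  tiff::writeTIFF(image$pixels / (2^image$bit_depth - 1), path,
                  bits.per.sample = image$bit_depth)
  invisible(path)
}
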