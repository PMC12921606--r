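#' Detection parameters for invading objects
#'
#' @param dynamic Prominence criterion of the extended-maxima transform,
#'   expressed as a fraction of the observed image intensity range, in
#'   `(0, 1]`. Default 0.001.
#' @param artifact_radius_um Radius (micrometers) of the disk used for
#'   artifact exclusion; objects able to contain the disk are flagged as
#'   artifacts. 0 (the default) disables exclusion.
#' @param range_from `"image"` (default) measures the intensity range as
#'   `max - min` of the actual pixel values; `"bit_depth"` uses the full
#'   theoretical range of the source bit depth instead.
#' @return An object of class `emax_params`.
#' @export
emax_params <- function(dynamic = 0.001, artifact_radius_um = 0,
                        range_from = c("image", "bit_depth")) {
  if (!is.numeric(dynamic) || length(dynamic) != 1L ||
      !is.finite(dynamic) || dynamic <= 0 || dynamic > 1)
    stop("EMax dynamic must be in (0, 1]")
  if (!is.numeric(artifact_radius_um) || length(artifact_radius_um) != 1L ||
      !is.finite(artifact_radius_um) || artifact_radius_um < 0)
    stop("artifact_radius_um must be >= 0")
  structure(list(dynamic = dynamic,
                 artifact_radius_um = artifact_radius_um,
                 range_from = match.arg(range_from)),
            class = "emax_params")
}

#' Extended-maxima transform (EMax)
#'
#' Detects the connected groups of local intensity maxima whose prominence
#' over the surrounding saddle level is at least
#' `h = dynamic * intensity range`. Because the criterion is relative to a
#' reconstruction of the image from itself, detection is insensitive to
#' smooth background variation and to adding a constant to all intensities.
#'
#' Implemented as the regional maxima (8-connectivity) of the h-maxima
#' transform, i.e. of the morphological reconstruction by dilation of
#' `image - h` under `image`. A flat image yields no components, and a
#' component covering the entire image is discarded, since it marks no
#' localized maximum.
#'
#' @param image A [calibrated_image()].
#' @param dynamic Fraction of the intensity range in `(0, 1]`.
#' @param range_from See [emax_params()].
#' @return Integer label matrix; 0 = background, components numbered from 1
#'   in raster order of their first pixel.
#' @export
extended_maxima <- function(image, dynamic, range_from = "image") {
  stopifnot(inherits(image, "calibrated_image"))
  if (dynamic <= 0 || dynamic > 1) stop("EMax dynamic must be in (0, 1]")
  px <- image$pixels
  rng <- if (identical(range_from, "bit_depth")) 2^image$bit_depth - 1
         else max(px) - min(px)
  if (rng == 0) return(matrix(0L, nrow(px), ncol(px)))
  h <- dynamic * rng
  rec <- cpp_reconstruct_dilate(px - h, px)
  rmax <- cpp_regional_maxima(rec)
  lab <- cpp_label_components(rmax)
  if (max(lab) == 1L && all(lab == 1L))
    lab[] <- 0L
  lab
}

# Internal constructor for a detected object; measurement fields are filled
# by measure_objects().
new_detected_object <- function(label, pixels) {
  structure(list(label = label, pixels = pixels,
                 excluded_as_artifact = FALSE),
            class = "detected_object")
}

#' Objects lying entirely outside the spheroid mask
#'
#' Components of an extended-maxima label grid are reported as invading
#' objects only if none of their pixels lies inside the mask; components
#' touching or straddling the mask belong to the core and are dropped
#' entirely (clipping would corrupt the shape descriptors).
#'
#' @param label_grid Integer label matrix from [extended_maxima()].
#' @param mask A [spheroid_mask()] of the same shape.
#' @return List of `detected_object`s (geometry fields unfilled), labeled
#'   1..k in raster order.
#' @export
objects_outside_mask <- function(label_grid, mask) {
  stopifnot(inherits(mask, "spheroid_mask"))
  if (!all(dim(label_grid) == dim(mask$grid)))
    stop("label grid and mask shapes differ")
  nlab <- max(label_grid)
  if (nlab == 0L) return(list())
  inside <- tabulate(label_grid[mask$grid & label_grid > 0L], nbins = nlab)
  keep <- which(inside == 0L)
  objs <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    pix <- which(label_grid == keep[i], arr.ind = TRUE)
    # raster order within the object, for reproducible reporting
    pix <- pix[order(pix[, 1L], pix[, 2L]), , drop = FALSE]
    objs[[i]] <- new_detected_object(i, pix)
  }
  objs
}

# TRUE iff the object's pixel set can contain a digital disk of radius r_px:
# the erosion of the pixel set by the disk structuring element is non-empty.
# The bounding-box crop is padded by the radius so image borders and
# unrelated pixels cannot influence the erosion.
can_contain_disk <- function(pixels, r_px) {
  r_px <- as.integer(r_px)
  if (r_px < 1L) r_px <- 1L
  rr <- pixels[, 1L]; cc <- pixels[, 2L]
  pad <- r_px + 1L
  h <- diff(range(rr)) + 1L + 2L * pad
  w <- diff(range(cc)) + 1L + 2L * pad
  crop <- matrix(0, h, w)
  crop[cbind(rr - min(rr) + 1L + pad, cc - min(cc) + 1L + pad)] <- 1
  er <- EBImage::erode(crop, disk_kernel(r_px))
  any(er > 0)
}

#' Flag oversized artifacts among detected objects
#'
#' An object is excluded as an artifact (air bubble, debris, background
#' fluctuation) iff it can contain a digital disk of the specified radius,
#' i.e. the morphological erosion of its pixel set by that disk is
#' non-empty. Excluded objects keep their `excluded_as_artifact` flag and
#' remain in the detailed table, but are removed from all counts and
#' summaries.
#'
#' @param objects List of `detected_object`s.
#' @param artifact_radius_um Disk radius in micrometers; 0 disables
#'   exclusion. The pixel radius is `round(artifact_radius_um /
#'   pixel_size_um)` with a minimum of 1 pixel.
#' @param pixel_size_um Micrometers per pixel.
#' @return The object list with `excluded_as_artifact` set.
#' @export
exclude_artifacts <- function(objects, artifact_radius_um, pixel_size_um) {
  if (artifact_radius_um == 0 || length(objects) == 0L) return(objects)
  r_px <- max(1L, as.integer(round(artifact_radius_um / pixel_size_um)))
  lapply(objects, function(ob) {
    ob$excluded_as_artifact <- can_contain_disk(ob$pixels, r_px)
    ob
  })
}

#' Detect invading objects outside the spheroid mask
#'
#' Full detection pipeline for one image: extended-maxima transform,
#' restriction to components entirely outside the mask, artifact exclusion,
#' and per-object measurement (geometry, shape descriptors and distance to
#' the mask boundary). Deterministic for fixed inputs.
#'
#' @param image A [calibrated_image()].
#' @param mask A [spheroid_mask()] of the same shape.
#' @param params An [emax_params()].
#' @param distance_from `"centroid"` (default) or `"edge"`; see
#'   [distance_to_boundary()].
#' @param roi Optional detection region as `c(rmin, rmax, cmin, cmax)`
#'   (1-based rows/columns); components with any pixel outside the region
#'   are dropped.
#' @return List of measured `detected_object`s (artifacts included, with
#'   their flag set).
#' @export
detect_objects <- function(image, mask, params = emax_params(),
                           distance_from = c("centroid", "edge"),
                           roi = NULL) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(mask, "spheroid_mask"),
            inherits(params, "emax_params"))
  distance_from <- match.arg(distance_from)
  lab <- extended_maxima(image, params$dynamic, params$range_from)
  objs <- objects_outside_mask(lab, mask)
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4L)
    objs <- Filter(function(ob) {
      all(ob$pixels[, 1L] >= roi[1L] & ob$pixels[, 1L] <= roi[2L] &
          ob$pixels[, 2L] >= roi[3L] & ob$pixels[, 2L] <= roi[4L])
    }, objs)
    for (i in seq_along(objs)) objs[[i]]$label <- i
  }
  objs <- exclude_artifacts(objs, params$artifact_radius_um,
                            image$pixel_size_um)
  measure_objects(objs, mask, image$pixel_size_um,
                  distance_from = distance_from)
}
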